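# Synthetic lipidomes and growth curves with known ground truth, emulating
# the statistical structure of quantitative yeast shotgun lipidomics under
# medium and proteotoxic-stress effects: ~20 classes in 4 categories,
# chain-resolved glycerophospholipids drawn from a chain pool (C10:0-C18:1)
# with a tunable pairing-selectivity rule, multiplicative class-level
# condition effects, lognormal replicate noise, and exponential OD600
# curves.

default_class_composition <- function() {
  c(Erg = 10,
    Cer = 0.5, IPC = 2, MIPC = 1, "M(IP)2C" = 0.5,
    CL = 1, PA = 2, PC = 18, PE = 12, PI = 10, PS = 4, DAG = 2,
    "CDP-DAG" = 0.5, LPA = 0.2, LPC = 0.5, LPE = 0.5, LPI = 0.3, LPS = 0.2,
    TAG = 26, EE = 8.8)
}

default_chain_pool <- function() {
  list(
    YPD = c("10:0" = 0.05, "12:0" = 0.08, "14:0" = 0.04, "16:0" = 0.26,
            "16:1" = 0.27, "18:0" = 0.07, "18:1" = 0.23),
    SCD = c("10:0" = 0.02, "12:0" = 0.04, "14:0" = 0.03, "16:0" = 0.24,
            "16:1" = 0.32, "18:0" = 0.06, "18:1" = 0.29)
  )
}

# Fixed within-class species templates for classes outside the two-chain
# MGL sub-category; sphingolipids are sum-composition with 2-4 hydroxyls.
default_species_templates <- function() {
  list(
    Erg = c("Erg" = 1),
    Cer = c("Cer 34:1;2" = 0.7, "Cer 36:1;2" = 0.3),
    IPC = c("IPC 44:0;2" = 0.6, "IPC 44:0;3" = 0.25, "IPC 44:0;4" = 0.15),
    MIPC = c("MIPC 44:0;2" = 0.7, "MIPC 44:0;3" = 0.3),
    "M(IP)2C" = c("M(IP)2C 44:0;2" = 1),
    CL = c("CL 68:4" = 0.6, "CL 70:4" = 0.4),
    "CDP-DAG" = c("CDP-DAG 32:1" = 1),
    LPA = c("LPA 16:1" = 1), LPC = c("LPC 16:1" = 1),
    LPE = c("LPE 16:1" = 1), LPI = c("LPI 16:0" = 1),
    LPS = c("LPS 16:1" = 1),
    TAG = c("TAG 48:1" = 0.4, "TAG 50:2" = 0.35, "TAG 52:3" = 0.25),
    EE = c("EE 16:1" = 0.6, "EE 18:1" = 0.4)
  )
}

#' Configuration for the synthetic lipidome generator
#'
#' Defaults emulate a yeast lipidome experiment with four conditions
#' (YPD/SCD medium, untreated/DTT) and n = 3 replicates: a baseline class
#' composition spanning ~20 classes in 4 categories, medium-specific acyl
#' chain pools over C10:0-C18:1, a two-fold PA increase under DTT in rich
#' medium, a ~30% PA decrease under DTT in synthetic medium, higher storage
#' lipids in synthetic medium, and a pairing selectivity of 0.95 for
#' saturated medium chains.
#'
#' @param conditions Tibble of `medium`/`treatment` combinations to
#'   generate.
#' @param class_composition Named baseline class mol% vector; normalized to
#'   sum to 100.
#' @param condition_effects Named list keyed `"<medium>:<treatment>"` of
#'   named fold-change vectors. Targeted classes are multiplied by their
#'   fold and the remaining classes rescaled so the condition composition
#'   still sums to 100 — the injected fold change is therefore exact in
#'   mol%.
#' @param chain_pool Named list per medium of chain-label frequency vectors
#'   (each normalized to sum to 1).
#' @param pairing_selectivity Probability `s` that a drawn saturated medium
#'   chain (10:0/12:0) is partnered with a saturated long chain
#'   (16:0/18:0); the remaining mass goes to the other non-medium chains in
#'   pool proportion. `NULL` selects independent pairing (the second chain
#'   is always an independent pool draw).
#' @param replicate_noise_sigma Lognormal sigma applied multiplicatively to
#'   every species amount.
#' @param n_replicates Replicates per condition.
#' @param n_molecules Molecules drawn per two-chain glycerolipid class per
#'   sample; controls the sampling depth of the pairing structure.
#' @param total_pmol Total lipid amount per sample.
#' @param seed Integer seed; the generator is fully reproducible per seed.
#' @return A validated config list of class `"lipidome_config"`.
#' @export
lipidome_config <- function(
    conditions = tidyr::expand_grid(medium = c("YPD", "SCD"),
                                    treatment = c("none", "DTT")),
    class_composition = default_class_composition(),
    condition_effects = list(
      "YPD:DTT" = c(PA = 2),
      "SCD:none" = c(TAG = 1.3, EE = 1.3),
      "SCD:DTT" = c(TAG = 1.3, EE = 1.3, PA = 0.7)
    ),
    chain_pool = default_chain_pool(),
    pairing_selectivity = 0.95,
    replicate_noise_sigma = 0.10,
    n_replicates = 3,
    n_molecules = 2000,
    total_pmol = 1000,
    seed = 1L) {
  if (is.null(names(class_composition)) || any(class_composition < 0)) {
    stop("invalid field 'class_composition': must be a named non-negative ",
         "vector", call. = FALSE)
  }
  category_of(names(class_composition))  # validates class names
  class_composition <- 100 * class_composition / sum(class_composition)
  for (med in unique(conditions$medium)) {
    if (!med %in% names(chain_pool)) {
      stop("invalid field 'chain_pool': no pool for medium '", med, "'",
           call. = FALSE)
    }
    chain_pool[[med]] <- chain_pool[[med]] / sum(chain_pool[[med]])
  }
  if (!is.null(pairing_selectivity) &&
      (pairing_selectivity < 0 || pairing_selectivity > 1)) {
    stop("invalid field 'pairing_selectivity': must be in [0, 1]",
         call. = FALSE)
  }
  if (replicate_noise_sigma < 0) {
    stop("invalid field 'replicate_noise_sigma': must be >= 0",
         call. = FALSE)
  }
  if (n_replicates < 1) {
    stop("invalid field 'n_replicates': must be >= 1", call. = FALSE)
  }
  if (n_molecules < 1 || total_pmol <= 0) {
    stop("invalid field 'n_molecules'/'total_pmol': must be positive",
         call. = FALSE)
  }
  structure(list(conditions = tibble::as_tibble(conditions),
                 class_composition = class_composition,
                 condition_effects = condition_effects,
                 chain_pool = chain_pool,
                 pairing_selectivity = pairing_selectivity,
                 replicate_noise_sigma = replicate_noise_sigma,
                 n_replicates = n_replicates, n_molecules = n_molecules,
                 total_pmol = total_pmol, seed = seed),
            class = "lipidome_config")
}

# Condition composition: targeted classes multiplied by their fold, the
# rest rescaled so the total stays 100 (injected folds are exact in mol%).
condition_composition <- function(cfg, medium, treatment) {
  comp <- cfg$class_composition
  eff <- cfg$condition_effects[[paste0(medium, ":", treatment)]]
  if (is.null(eff)) return(comp)
  unknown <- setdiff(names(eff), names(comp))
  if (length(unknown) > 0) {
    stop("condition effect targets unknown class(es): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  comp[names(eff)] <- comp[names(eff)] * eff
  rest <- setdiff(names(comp), names(eff))
  comp[rest] <- comp[rest] * (100 - sum(comp[names(eff)])) / sum(comp[rest])
  comp
}

medium_saturated_chains <- function() c("10:0", "12:0")
saturated_long_chains <- function() c("16:0", "18:0")

# Partner distribution for a first-drawn chain x under pool p and
# selectivity s (NULL = independent). Chain sets absent from the pool
# contribute nothing; when a medium chain has no non-medium, non-saturated
# partner mass available, all its partner mass goes to the saturated long
# chains.
partner_distribution <- function(x, pool, s) {
  if (is.null(s)) return(pool)
  med <- intersect(medium_saturated_chains(), names(pool))
  satl <- intersect(saturated_long_chains(), names(pool))
  d <- stats::setNames(numeric(length(pool)), names(pool))
  if (x %in% med) {
    rest <- setdiff(names(pool), c(med, satl))
    if (length(satl) > 0) d[satl] <- s * pool[satl] / sum(pool[satl])
    if (length(rest) > 0 && sum(pool[rest]) > 0) {
      d[rest] <- (1 - s) * pool[rest] / sum(pool[rest])
    } else if (length(satl) > 0) {
      d[satl] <- pool[satl] / sum(pool[satl])
    } else {
      stop("chain pool has medium chains but no saturated long chains ",
           "to pair them with", call. = FALSE)
    }
  } else {
    rest <- setdiff(names(pool), med)
    d[rest] <- pool[rest] / sum(pool[rest])
  }
  d
}

# Expected chain-occurrence frequencies implied by the pairing rule:
# the average of the first-draw pool and the mixture of partner
# distributions. Equals the pool itself under independent pairing.
implied_occurrence_frequencies <- function(pool, s) {
  second <- Reduce(`+`, lapply(names(pool), function(x) {
    pool[x] * partner_distribution(x, pool, s)
  }))
  (pool + second) / 2
}

#' Generate a synthetic lipidome with known ground truth
#'
#' For every condition and replicate, class amounts follow the condition
#' composition; two-chain glycerolipid classes (PA, PC, PE, PI, PS, DAG)
#' are assembled molecule by molecule — the first chain drawn from the
#' medium's chain pool, the second via the pairing-selectivity rule — and
#' all other classes use fixed within-class species templates
#' (sphingolipids at sum-composition level with 2-4 hydroxylations).
#' Lognormal noise multiplies every species amount. Output is byte-identical
#' across calls with the same config.
#'
#' @param cfg A [lipidome_config()].
#' @return A list with `table` (a lipidome tibble as from
#'   [lipidome_table()]) and `truth`, a record of the exact generating
#'   parameters: per-condition class mol% (`class_mol_pct`), chain pools,
#'   implied chain-occurrence frequencies (`chain_occurrence_freq`),
#'   `pairing_selectivity`, `condition_effects`, noise sigma, and sampling
#'   depth.
#' @export
generate_lipidome <- function(cfg = lipidome_config()) {
  stopifnot(inherits(cfg, "lipidome_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  templates <- default_species_templates()
  sub <- mgl_subcategory()
  rows <- list()
  truth_comp <- list()

  for (ci in seq_len(nrow(cfg$conditions))) {
    medium <- cfg$conditions$medium[ci]
    treatment <- cfg$conditions$treatment[ci]
    comp <- condition_composition(cfg, medium, treatment)
    truth_comp[[paste0(medium, ":", treatment)]] <- comp
    pool <- cfg$chain_pool[[medium]]

    for (rep_i in seq_len(cfg$n_replicates)) {
      sample_id <- paste(medium, treatment, rep_i, sep = "_")
      for (cls in names(comp)) {
        class_amt <- cfg$total_pmol * comp[[cls]] / 100
        if (class_amt <= 0) next
        if (cls %in% sub) {
          chain1 <- sample(names(pool), cfg$n_molecules, replace = TRUE,
                           prob = pool)
          chain2 <- character(cfg$n_molecules)
          for (x in unique(chain1)) {
            idx <- which(chain1 == x)
            d <- partner_distribution(x, pool, cfg$pairing_selectivity)
            chain2[idx] <- sample(names(d), length(idx), replace = TRUE,
                                  prob = d)
          }
          rk <- sort_chain_labels(names(pool))
          swap <- match(chain1, rk) < match(chain2, rk)
          hi <- ifelse(swap, chain2, chain1)
          lo <- ifelse(swap, chain1, chain2)
          counts <- table(paste0(cls, " ", hi, "/", lo))
          amounts <- class_amt * as.numeric(counts) / cfg$n_molecules
          rows[[length(rows) + 1]] <- tibble::tibble(
            sample_id = sample_id, lipid = names(counts),
            amount_pmol = amounts)
        } else {
          tmpl <- templates[[cls]]
          rows[[length(rows) + 1]] <- tibble::tibble(
            sample_id = sample_id, lipid = names(tmpl),
            amount_pmol = class_amt * as.numeric(tmpl))
        }
      }
    }
  }

  data <- dplyr::bind_rows(rows)
  if (cfg$replicate_noise_sigma > 0) {
    data$amount_pmol <- data$amount_pmol *
      exp(stats::rnorm(nrow(data), 0, cfg$replicate_noise_sigma))
  }
  metadata <- tidyr::expand_grid(cfg$conditions,
                                 replicate = seq_len(cfg$n_replicates))
  metadata <- tibble::tibble(
    sample_id = paste(metadata$medium, metadata$treatment,
                      metadata$replicate, sep = "_"),
    strain = "WT", medium = metadata$medium,
    treatment = metadata$treatment, replicate = metadata$replicate)

  truth <- list(
    class_mol_pct = truth_comp,
    chain_pool = cfg$chain_pool,
    chain_occurrence_freq = lapply(
      cfg$chain_pool, implied_occurrence_frequencies,
      s = cfg$pairing_selectivity),
    pairing_selectivity = cfg$pairing_selectivity,
    condition_effects = cfg$condition_effects,
    replicate_noise_sigma = cfg$replicate_noise_sigma,
    n_replicates = cfg$n_replicates, n_molecules = cfg$n_molecules,
    total_pmol = cfg$total_pmol, seed = cfg$seed)

  list(table = lipidome_table(data, metadata), truth = truth)
}

#' Configuration for the synthetic growth-curve generator
#'
#' @param od0 Initial OD600.
#' @param doubling_time True doubling time in minutes (86 is typical of
#'   unstressed yeast in rich medium, 107 in synthetic medium).
#' @param times Sampling times in minutes (increasing).
#' @param noise_sigma Lognormal sigma of multiplicative OD noise.
#' @param stress_onset_time Optional time (min) at which growth slows.
#' @param post_onset_doubling Doubling time after `stress_onset_time`
#'   (required when an onset is set); the curve is continuous at the onset.
#' @param seed Integer seed.
#' @return A validated config list of class `"growth_config"`.
#' @export
growth_config <- function(od0 = 0.1, doubling_time = 86,
                          times = seq(0, 480, by = 20), noise_sigma = 0.02,
                          stress_onset_time = NULL,
                          post_onset_doubling = NULL, seed = 1L) {
  if (od0 <= 0) stop("invalid field 'od0': must be > 0", call. = FALSE)
  if (doubling_time <= 0) {
    stop("invalid field 'doubling_time': must be > 0", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("invalid field 'times': must be strictly increasing",
         call. = FALSE)
  }
  if (noise_sigma < 0) {
    stop("invalid field 'noise_sigma': must be >= 0", call. = FALSE)
  }
  if (!is.null(stress_onset_time) &&
      (is.null(post_onset_doubling) || post_onset_doubling <= 0)) {
    stop("invalid field 'post_onset_doubling': must be > 0 when ",
         "'stress_onset_time' is set", call. = FALSE)
  }
  structure(list(od0 = od0, doubling_time = doubling_time, times = times,
                 noise_sigma = noise_sigma,
                 stress_onset_time = stress_onset_time,
                 post_onset_doubling = post_onset_doubling, seed = seed),
            class = "growth_config")
}

#' Generate a synthetic OD600 growth curve
#'
#' OD(t) = OD0 * 2^(t / T_d), switching continuously to the post-onset
#' doubling time at `stress_onset_time` when set, with multiplicative
#' lognormal noise. Reproducible per seed.
#'
#' @param cfg A [growth_config()].
#' @return A tibble with `time_min`, `od600` (noisy) and `od600_true`.
#' @export
generate_growth <- function(cfg = growth_config()) {
  stopifnot(inherits(cfg, "growth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  t <- cfg$times
  if (is.null(cfg$stress_onset_time)) {
    od_true <- cfg$od0 * 2^(t / cfg$doubling_time)
  } else {
    t0 <- cfg$stress_onset_time
    od_onset <- cfg$od0 * 2^(t0 / cfg$doubling_time)
    od_true <- ifelse(t <= t0,
                      cfg$od0 * 2^(t / cfg$doubling_time),
                      od_onset * 2^((t - t0) / cfg$post_onset_doubling))
  }
  noise <- if (cfg$noise_sigma > 0) {
    exp(stats::rnorm(length(t), 0, cfg$noise_sigma))
  } else 1
  tibble::tibble(time_min = t, od600 = od_true * noise,
                 od600_true = od_true)
}
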