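# Group summaries, stress-vs-control differences with error propagation,
# unpaired t-tests with significance tiers, species-level PCA, exponential
# growth fitting.

#' Significance tier from a p value
#'
#' Strict thresholds: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' otherwise `ns`.
#'
#' @param p Numeric vector of p values.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

# Complete a feature profile over the full sample x key grid with 0 mol%
# (non-detection is an effective zero).
complete_profile <- function(profile) {
  tidyr::complete(profile, .data$sample_id, .data$key,
                  fill = list(mol_pct = 0))
}

#' Per-group mean and SD of a feature profile
#'
#' Joins sample metadata to a feature profile, completes absent
#' (sample, key) combinations with 0 mol%, and returns the arithmetic mean
#' and sample SD (n - 1 denominator) per feature key per group. SD is NA
#' when a group has a single replicate.
#'
#' @param profile A feature-profile tibble (`sample_id`, `key`, `mol_pct`).
#' @param metadata Sample metadata keyed by `sample_id`.
#' @param group_vars Character vector of metadata columns defining groups
#'   (e.g. `c("medium", "treatment")`).
#' @return Tibble with the grouping columns, `key`, `mean`, `sd`, `n`.
#' @export
group_summary <- function(profile, metadata, group_vars) {
  df <- dplyr::left_join(complete_profile(profile),
                         tibble::as_tibble(metadata), by = "sample_id")
  dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(c(group_vars, "key")))),
    mean = mean(.data$mol_pct),
    sd = stats::sd(.data$mol_pct),
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' Difference of group means with propagated SD
#'
#' For each feature key, `delta = mean_a - mean_b` and
#' `delta_sd = sqrt(sd_a^2 + sd_b^2)` — the root-sum-of-squares propagation
#' for a difference of independent means.
#'
#' @param a,b Group-summary tibbles with columns `key`, `mean`, `sd`, `n`
#'   (e.g. one group each from [group_summary()]); `a` is conventionally
#'   the stressed group and `b` the control.
#' @return Tibble with `key`, `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`,
#'   `n_b`, `delta`, `delta_sd`. Keys absent from one side enter with
#'   mean 0 and SD 0.
#' @export
diff_with_propagation <- function(a, b) {
  keep <- c("key", "mean", "sd", "n")
  joined <- dplyr::full_join(
    stats::setNames(a[keep], c("key", "mean_a", "sd_a", "n_a")),
    stats::setNames(b[keep], c("key", "mean_b", "sd_b", "n_b")),
    by = "key"
  )
  for (col in c("mean_a", "sd_a", "mean_b", "sd_b")) {
    joined[[col]][is.na(joined[[col]])] <- 0
  }
  dplyr::mutate(joined,
                delta = .data$mean_a - .data$mean_b,
                delta_sd = sqrt(.data$sd_a^2 + .data$sd_b^2))
}

#' Unpaired two-sample t-test with significance tiers
#'
#' Pooled-variance Student t by default (two-tailed p from the t
#' distribution with `n_a + n_b - 2` degrees of freedom); Welch's
#' unequal-variance form with `var_equal = FALSE`. Degenerate zero-variance
#' input is handled explicitly: equal means give p = 1, unequal means give
#' p = 0 with `degenerate = TRUE`.
#'
#' @param a,b Numeric vectors of replicate values (each of length >= 2).
#' @param var_equal Use the pooled-variance Student t (default TRUE).
#' @return A list with `t`, `df`, `p`, `tier` and `degenerate`.
#' @export
#' @examples
#' two_sample_t(c(11, 12, 13), c(1, 2, 3))
two_sample_t <- function(a, b, var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("need >= 2 replicates per group", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  dm <- mean(a) - mean(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se == 0) {
    if (dm == 0) {
      return(list(t = 0, df = df, p = 1, tier = "ns", degenerate = TRUE))
    }
    return(list(t = sign(dm) * Inf, df = df, p = 0, tier = "***",
                degenerate = TRUE))
  }
  t <- dm / se
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, tier = significance_tier(p),
       degenerate = FALSE)
}

#' Stress-versus-control comparison of a feature profile
#'
#' For every feature key, computes per-group mean ± SD, the difference with
#' propagated SD (group `level_a` minus baseline `level_b`), and an
#' unpaired two-tailed t-test with significance tier.
#'
#' @inheritParams group_summary
#' @param group_var Metadata column defining the contrast (e.g.
#'   `"treatment"`).
#' @param level_a Stressed/test level of `group_var`.
#' @param level_b Baseline level (e.g. `"none"`).
#' @param var_equal Passed to [two_sample_t()].
#' @param p_adjust Multiple-testing correction across feature keys:
#'   `"none"` (default; per-feature stars as is conventional in targeted
#'   lipidomics reporting) or `"BH"` (Benjamini-Hochberg), which adds a
#'   `p_adj` column. Tiers are always derived from the unadjusted p.
#' @return Tibble with `key`, group means/SDs/n, `delta`, `delta_sd`, `t`,
#'   `p`, `tier` (and `p_adj` when requested).
#' @export
compare_groups <- function(profile, metadata, group_var, level_a, level_b,
                           var_equal = TRUE,
                           p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  metadata <- tibble::as_tibble(metadata)
  df <- dplyr::left_join(complete_profile(profile), metadata,
                         by = "sample_id")
  df <- df[df[[group_var]] %in% c(level_a, level_b), , drop = FALSE]
  summ <- group_summary(profile,
                        metadata[metadata[[group_var]] %in%
                                   c(level_a, level_b), , drop = FALSE],
                        group_var)
  out <- diff_with_propagation(summ[summ[[group_var]] == level_a, ],
                               summ[summ[[group_var]] == level_b, ])
  tests <- lapply(out$key, function(k) {
    va <- df$mol_pct[df$key == k & df[[group_var]] == level_a]
    vb <- df$mol_pct[df$key == k & df[[group_var]] == level_b]
    two_sample_t(va, vb, var_equal = var_equal)
  })
  out$t <- vapply(tests, `[[`, numeric(1), "t")
  out$p <- vapply(tests, `[[`, numeric(1), "p")
  out$tier <- vapply(tests, `[[`, character(1), "tier")
  if (p_adjust == "BH") out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}

#' Principal component analysis of lipid species abundances
#'
#' PCA of the samples-by-species mol% matrix (species aligned across
#' samples, absent = 0), mean-centered by default and optionally scaled to
#' unit variance. Component signs are fixed by convention: the
#' largest-magnitude loading of each component is made positive, so results
#' are deterministic.
#'
#' @param table A lipidome tibble carrying a `mol_pct` column (see
#'   [normalize_mol_percent()]), or a numeric samples-by-species matrix.
#' @param scaling `"center"` (default) or `"center_unit_variance"`.
#'   Unit-variance scaling drops zero-variance species.
#' @return A list of class `"lipidome_pca"`: `scores` (tibble, `sample_id`
#'   plus `PC1`, `PC2`, ...), `loadings` (species x component matrix),
#'   `explained_variance` (fractions, non-increasing) and `scaling`.
#' @export
pca_species <- function(table,
                        scaling = c("center", "center_unit_variance")) {
  scaling <- match.arg(scaling)
  m <- if (is.matrix(table)) table else lipidome_matrix(table, "mol_pct")
  if (nrow(m) < 3) stop("PCA needs >= 3 samples", call. = FALSE)
  v <- apply(m, 2, stats::var)
  if (all(v == 0)) stop("constant matrix: no variance to decompose",
                        call. = FALSE)
  if (scaling == "center_unit_variance") m <- m[, v > 0, drop = FALSE]
  pc <- stats::prcomp(m, center = TRUE,
                      scale. = scaling == "center_unit_variance")
  # sign convention: largest-|loading| positive per component
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  structure(
    list(scores = dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                                   tibble::as_tibble(pc$x)),
         loadings = pc$rotation,
         explained_variance = pc$sdev^2 / sum(pc$sdev^2),
         scaling = scaling),
    class = "lipidome_pca"
  )
}

#' Fit an exponential (Malthusian) growth curve
#'
#' Fits OD(t) = OD0 * exp(k t) by nonlinear least squares on the
#' untransformed optical densities, using only points inside the OD600
#' window (0.2 to 2.5 by default, the range over which batch growth is
#' exponential); the doubling time is ln(2)/k. A log-linear regression
#' seeds the nonlinear fit and is available as `method = "loglinear"` for
#' cross-checking.
#'
#' @param time_min Numeric vector of times (minutes).
#' @param od600 Numeric vector of optical densities.
#' @param od_window Two-element OD600 inclusion window `c(lo, hi)`, or NULL
#'   to use all points.
#' @param method `"nls"` (default) or `"loglinear"`.
#' @return A list of class `"growth_fit"`: `od0`, `k` (1/min),
#'   `doubling_time` (min), `n_points`, `od_window`, `method`,
#'   `resid_sd`, and `flag` (`"ok"` or `"non_positive_rate"`).
#' @export
#' @examples
#' t <- seq(0, 300, by = 15)
#' fit_growth(t, 0.1 * 2^(t / 90))$doubling_time  # 90
fit_growth <- function(time_min, od600, od_window = c(0.2, 2.5),
                       method = c("nls", "loglinear")) {
  method <- match.arg(method)
  stopifnot(length(time_min) == length(od600))
  keep <- if (is.null(od_window)) rep(TRUE, length(od600)) else
    od600 >= od_window[1] & od600 <= od_window[2]
  t <- time_min[keep]; od <- od600[keep]
  if (length(t) < 3) {
    stop("need >= 3 data points inside the OD window", call. = FALSE)
  }
  if (any(od <= 0)) stop("OD600 values must be positive", call. = FALSE)
  ll <- stats::lm(log(od) ~ t)
  k0 <- unname(stats::coef(ll)[2])
  od00 <- exp(unname(stats::coef(ll)[1]))
  if (method == "loglinear") {
    k <- k0; od0 <- od00
    resid_sd <- stats::sd(od - od0 * exp(k * t))
  } else {
    fit <- minpack.lm::nlsLM(od ~ od0 * exp(k * t),
                             start = list(od0 = od00, k = k0),
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200))
    cf <- stats::coef(fit)
    od0 <- unname(cf["od0"]); k <- unname(cf["k"])
    resid_sd <- stats::sd(stats::residuals(fit))
  }
  structure(
    list(od0 = od0, k = k,
         doubling_time = if (k > 0) log(2) / k else NA_real_,
         n_points = length(t), od_window = od_window, method = method,
         resid_sd = resid_sd,
         flag = if (k > 0) "ok" else "non_positive_rate"),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Exponential growth fit (", x$method, "): OD0 = ",
      signif(x$od0, 4), ", k = ", signif(x$k, 4), " /min, doubling time = ",
      signif(x$doubling_time, 4), " min (", x$n_points, " points)\n",
      sep = "")
  invisible(x)
}
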