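# Acyl-chain pairing: joint pair-abundance matrix and per-chain conditional
# partner distributions over the two-chain MGL sub-category. These matrices
# quantify the selectivity with which saturated medium chains (10:0, 12:0)
# pair with saturated long chains (16:0, 18:0) in asymmetric lipids.

#' Acyl-chain pairing matrices
#'
#' Pools all chain-resolved two-chain species of the given classes (over all
#' samples in `table`) and computes, for unordered chain pairs \{x, y\}:
#' \describe{
#'   \item{joint}{`joint[x, y]` = mol% of the sub-category amount carried by
#'     species with chain pair \{x, y\}; symmetric, with each pair's mass
#'     counted once so that the upper triangle plus diagonal sums to 100.}
#'   \item{conditional}{`conditional[x, y]` = percentage of x-chain
#'     occurrences whose partner chain is y; each row with nonzero usage
#'     sums to 100. A molecule of an x/x species contributes two
#'     x-occurrences, each partnered with x.}
#' }
#' Unresolved species in scope are excluded and counted in `n_excluded`.
#'
#' @param table A lipidome tibble (amounts in pmol).
#' @param classes Classes to pool (default the two-chain MGL sub-category
#'   PA, PC, PE, PI, PS, DAG).
#' @return An object of class `"pairing_matrix"`: a list with `chains`
#'   (ordered labels), `joint` and `conditional` matrices, `occurrence`
#'   (per-chain occurrence totals, pmol of chain occurrences), `total`
#'   (sub-category amount, pmol), `zero_rows` (chains with no occurrences)
#'   and `n_excluded`.
#' @export
#' @examples
#' tab <- lipidome_table(
#'   data.frame(sample_id = "S1",
#'              lipid = c("PC 16:0/16:0", "PC 16:0/12:0", "PC 18:1/16:1"),
#'              amount_pmol = c(2, 1, 1)),
#'   data.frame(sample_id = "S1"))
#' pm <- pairing_matrices(tab)
#' pm$conditional["16:0", ]
pairing_matrices <- function(table, classes = mgl_subcategory()) {
  pairs <- chain_pair_rows(table, classes)
  chains <- sort_chain_labels(unique(c(pairs$chain_a, pairs$chain_b)))
  k <- length(chains)
  total <- sum(pairs$amount_pmol)
  if (total <= 0) stop("total sub-category amount is zero", call. = FALSE)

  # unordered pair-amount accumulator A{x,y}, stored in upper triangle
  A <- matrix(0, k, k, dimnames = list(chains, chains))
  ia <- match(pairs$chain_a, chains)
  ib <- match(pairs$chain_b, chains)
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  for (r in seq_along(lo)) {
    A[lo[r], hi[r]] <- A[lo[r], hi[r]] + pairs$amount_pmol[r]
  }

  joint <- 100 * (A + t(A) - diag(diag(A), k)) / total  # symmetric view
  Asym <- A + t(A) - diag(diag(A), k)                   # A{x,y} both ways

  # occurrence totals: O(x) = 2 A{x,x} + sum_{y != x} A{x,y}
  occurrence <- diag(Asym) + rowSums(Asym)
  names(occurrence) <- chains

  partner <- Asym
  diag(partner) <- 2 * diag(A)
  conditional <- matrix(0, k, k, dimnames = list(chains, chains))
  nz <- occurrence > 0
  conditional[nz, ] <- 100 * partner[nz, , drop = FALSE] / occurrence[nz]

  structure(
    list(chains = chains, joint = joint, conditional = conditional,
         occurrence = occurrence, total = total,
         zero_rows = chains[!nz],
         n_excluded = attr(pairs, "n_excluded")),
    class = "pairing_matrix"
  )
}

#' @export
print.pairing_matrix <- function(x, ...) {
  cat("Acyl-chain pairing over", length(x$chains), "chains;",
      "total", format(x$total), "pmol\n")
  cat("Joint pair abundance (mol% of sub-category):\n")
  print(round(x$joint, 2))
  cat("Conditional partner distribution (% per chain occurrence):\n")
  print(round(x$conditional, 2))
  invisible(x)
}

#' Pairing matrices as tidy tibbles
#'
#' @param pm A `pairing_matrix`.
#' @return A tibble with columns `chain_x`, `chain_y`, `joint_pct`,
#'   `conditional_pct` (one row per ordered chain pair).
#' @export
tidy_pairing <- function(pm) {
  grid <- expand.grid(chain_x = pm$chains, chain_y = pm$chains,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    chain_x = grid$chain_x, chain_y = grid$chain_y,
    joint_pct = pm$joint[cbind(grid$chain_x, grid$chain_y)],
    conditional_pct = pm$conditional[cbind(grid$chain_x, grid$chain_y)]
  )
}

#' Pairing selectivity of saturated medium chains
#'
#' Summarizes how the pooled medium saturated chains (by default 10:0 and
#' 12:0) distribute their partner chains between saturated long chains
#' (16:0, 18:0), unsaturated long chains (16:1, 18:1) and anything else.
#' The scalar `selectivity` is the percentage of medium-chain occurrences
#' partnered with a saturated long chain — near 100 for lipidomes dominated
#' by asymmetric saturated/saturated pairing, and near the saturated-long
#' usage share under independent pairing.
#'
#' @param pm A `pairing_matrix` from [pairing_matrices()].
#' @param medium_chains,saturated_long,unsaturated_long Chain label sets;
#'   labels absent from `pm$chains` contribute zero.
#' @return A list with `selectivity` (percent), `partner_pct` (named vector
#'   over `saturated_long`, `unsaturated_long`, `other`),
#'   `medium_occurrence` (pooled pmol of medium-chain occurrences) and
#'   `defined` (FALSE when no medium-chain occurrences exist, in which case
#'   percentages are NA).
#' @export
pairing_selectivity <- function(pm,
                                medium_chains = c("10:0", "12:0"),
                                saturated_long = c("16:0", "18:0"),
                                unsaturated_long = c("16:1", "18:1")) {
  stopifnot(inherits(pm, "pairing_matrix"))
  med <- intersect(medium_chains, pm$chains)
  occ <- pm$occurrence[med]
  total_med <- sum(occ)
  if (length(med) == 0 || total_med <= 0) {
    return(list(selectivity = NA_real_,
                partner_pct = c(saturated_long = NA_real_,
                                unsaturated_long = NA_real_,
                                other = NA_real_),
                medium_occurrence = 0, defined = FALSE))
  }
  # occurrence-weighted pooled partner distribution of the medium chains
  partner_counts <- colSums(pm$conditional[med, , drop = FALSE] * occ / 100)
  share <- function(set) {
    100 * sum(partner_counts[intersect(set, pm$chains)]) / total_med
  }
  pct_sat <- share(saturated_long)
  pct_unsat <- share(unsaturated_long)
  list(selectivity = pct_sat,
       partner_pct = c(saturated_long = pct_sat,
                       unsaturated_long = pct_unsat,
                       other = 100 - pct_sat - pct_unsat),
       medium_occurrence = total_med, defined = TRUE)
}
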