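# Compositional feature profiles: class/category composition, species
# profiles, total chain length, total double bonds, chain usage, sphingolipid
# species profiles. Every profile is a tidy (sample_id, key, mol_pct) tibble
# whose values sum to 100 per sample.

new_feature_profile <- function(df, kind, scope) {
  df <- dplyr::arrange(df, .data$sample_id)
  attr(df, "feature_kind") <- kind
  attr(df, "scope") <- scope
  df
}

# Normalize `amount_pmol` to mol% of the per-sample total of `table`,
# summed over `key`.
profile_by_key <- function(table, key, kind, scope) {
  if (nrow(table) == 0) stop("no species in scope for ", kind, call. = FALSE)
  out <- dplyr::summarise(
    dplyr::group_by(table, .data$sample_id, key = {{ key }}),
    amount = sum(.data$amount_pmol), .groups = "drop_last"
  )
  out <- dplyr::mutate(out, mol_pct = 100 * .data$amount /
                         sum(.data$amount))
  out <- dplyr::ungroup(out)
  new_feature_profile(out[, c("sample_id", "key", "mol_pct")], kind, scope)
}

#' Lipid class composition in mol% of all quantified lipids
#'
#' Per sample, the summed abundance of each lipid class as mol% of the whole
#' lipidome. Classes are ordered by category (sterols, sphingolipids,
#' membrane glycerolipids, storage lipids) then registry order.
#'
#' @param table A lipidome tibble (amounts in pmol).
#' @return A feature-profile tibble (`sample_id`, `key` = class, `mol_pct`).
#' @export
class_composition <- function(table) {
  p <- profile_by_key(table, .data$lipid_class, "class_composition",
                      "all_lipids")
  p$key <- factor(p$key, levels = lipid_classes()$lipid_class)
  p <- dplyr::arrange(p, .data$sample_id, .data$key)
  p$key <- as.character(p$key)
  p
}

#' Lipid category composition in mol% of all quantified lipids
#' @inheritParams class_composition
#' @return A feature-profile tibble (`key` = category).
#' @export
category_composition <- function(table) {
  profile_by_key(table, .data$category, "category_composition", "all_lipids")
}

#' Species profile within one lipid class
#'
#' Per sample, each member species of `lipid_class` as mol% of the class
#' total (e.g. the PA profile).
#'
#' @inheritParams class_composition
#' @param lipid_class A single recognized class name.
#' @return A feature-profile tibble (`key` = canonical species name).
#' @export
species_profile <- function(table, lipid_class) {
  stopifnot(length(lipid_class) == 1)
  category_of(lipid_class)  # validates the class name
  sub <- table[table$lipid_class == lipid_class, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("class '", lipid_class, "' not present in table", call. = FALSE)
  }
  profile_by_key(sub, .data$species, "species_profile",
                 paste0("class:", lipid_class))
}

#' Total acyl-chain length profile of two-chain membrane glycerolipids
#'
#' Per sample, the distribution of the summed carbon count of both fatty
#' acyl chains (e.g. 26, 28, ..., 36) as mol% of the two-chain MGL
#' sub-category (PA, PC, PE, PI, PS, DAG). Defined for chain-resolved and
#' sum-composition species alike, since both carry a total carbon count.
#'
#' @inheritParams class_composition
#' @param classes Classes forming the denominator (default the two-chain
#'   MGL sub-category).
#' @return A feature-profile tibble (`key` = total carbons, integer).
#' @export
total_length_profile <- function(table, classes = mgl_subcategory()) {
  sub <- table[table$lipid_class %in% classes, , drop = FALSE]
  p <- profile_by_key(sub, .data$total_c, "total_length", "mgl_subcategory")
  dplyr::arrange(p, .data$sample_id, .data$key)
}

#' Total double-bond profile of two-chain membrane glycerolipids
#'
#' As [total_length_profile()], keyed by the summed double-bond count of
#' both acyl chains.
#'
#' @inheritParams total_length_profile
#' @return A feature-profile tibble (`key` = total double bonds, integer).
#' @export
total_double_bond_profile <- function(table, classes = mgl_subcategory()) {
  sub <- table[table$lipid_class %in% classes, , drop = FALSE]
  p <- profile_by_key(sub, .data$total_db, "total_double_bonds",
                      "mgl_subcategory")
  dplyr::arrange(p, .data$sample_id, .data$key)
}

# Expand chain-resolved two-chain species to one row per (sample, species)
# with both chain labels; hydroxylation is ignored in chain labels. Returns
# the expanded tibble with attribute `n_excluded` (unresolved rows dropped).
chain_pair_rows <- function(table, classes) {
  sub <- table[table$lipid_class %in% classes, , drop = FALSE]
  if (nrow(sub) == 0) stop("no species in scope", call. = FALSE)
  resolved <- sub$resolved & sub$n_chains == 2L
  n_excluded <- sum(!resolved)
  sub <- sub[resolved, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("no chain-resolved two-chain species in scope", call. = FALSE)
  }
  labs <- t(vapply(sub$chains, function(ch) {
    c(chain_label(ch$carbons[1], ch$double_bonds[1]),
      chain_label(ch$carbons[2], ch$double_bonds[2]))
  }, character(2)))
  out <- tibble::tibble(sample_id = sub$sample_id, species = sub$species,
                        amount_pmol = sub$amount_pmol,
                        chain_a = labs[, 1], chain_b = labs[, 2])
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Acyl-chain usage of two-chain glycerolipids
#'
#' Per sample, the fraction of chain occurrences carried by each chain label
#' (e.g. `"16:0"`), in mol% of all chain occurrences in scope. Each molecule
#' of an x/y species contributes one occurrence of x and one of y (two of x
#' when x = y). Only chain-resolved species enter; the number of excluded
#' unresolved rows is recorded in attribute `n_excluded`.
#'
#' @inheritParams class_composition
#' @param scope Either `"subcategory"` (the pooled two-chain MGL
#'   sub-category) or a single two-chain class name.
#' @return A feature-profile tibble (`key` = chain label).
#' @export
chain_usage <- function(table, scope = "subcategory") {
  classes <- if (identical(scope, "subcategory")) mgl_subcategory() else scope
  pairs <- chain_pair_rows(table, classes)
  long <- tidyr::pivot_longer(pairs, c("chain_a", "chain_b"),
                              values_to = "chain")
  p <- profile_by_key(
    dplyr::rename(long[, c("sample_id", "chain", "amount_pmol")],
                  key_chain = "chain"),
    .data$key_chain, "chain_usage",
    if (identical(scope, "subcategory")) "mgl_subcategory"
    else paste0("class:", scope)
  )
  p <- p[order(p$sample_id, match(p$key, sort_chain_labels(unique(p$key)))), ]
  attr(p, "n_excluded") <- attr(pairs, "n_excluded")
  p
}

#' Sphingolipid species profile in mol% of the category
#'
#' Per sample, every sphingolipid species (keyed by class plus sum
#' composition including hydroxylation count, e.g. `"IPC 44:0;2"`) as mol%
#' of the total sphingolipid amount.
#'
#' @inheritParams class_composition
#' @return A feature-profile tibble (`key` = canonical species name).
#' @export
sl_species_profile <- function(table) {
  sub <- table[table$category == "sphingolipids", , drop = FALSE]
  if (nrow(sub) == 0) stop("no sphingolipid species in table", call. = FALSE)
  profile_by_key(sub, .data$species, "sl_species_profile", "sphingolipids")
}
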