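# Lipidome table construction, identification filters, mol% normalization.

#' Build a lipidome table from species amounts and sample metadata
#'
#' The central object of the pipeline: a long tibble with one row per
#' (sample, species), amounts in pmol, every lipid name parsed, and sample
#' metadata joined. Two names that canonicalize to the same species (e.g.
#' `"PC 16:0/12:0"` and `"PC 12:0/16:0"`) are rejected as duplicates.
#'
#' @param data Tibble/data.frame with columns `sample_id`, `lipid`,
#'   `amount_pmol` and optionally `snr`, `signal_intensity`,
#'   `blank_intensity`.
#' @param metadata Tibble/data.frame keyed by `sample_id` with columns such
#'   as `strain`, `medium`, `treatment`, `replicate`.
#' @return A tibble with the parsed species columns of
#'   [parse_species_name()], `amount_pmol`, any filter columns, and the
#'   metadata columns.
#' @export
lipidome_table <- function(data, metadata) {
  data <- tibble::as_tibble(data)
  metadata <- tibble::as_tibble(metadata)
  required <- c("sample_id", "lipid", "amount_pmol")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("data is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"sample_id" %in% names(metadata)) {
    stop("metadata is missing required column 'sample_id'", call. = FALSE)
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("metadata sample_id values must be unique", call. = FALSE)
  }
  if (any(data$amount_pmol < 0, na.rm = TRUE)) {
    stop("amount_pmol must be non-negative", call. = FALSE)
  }
  orphans <- setdiff(unique(data$sample_id), metadata$sample_id)
  if (length(orphans) > 0) {
    stop("sample(s) absent from metadata: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }

  parsed <- parse_species_name(data$lipid)
  out <- dplyr::bind_cols(
    data["sample_id"],
    parsed[, c("species", "lipid_class", "category", "resolved", "n_chains",
               "total_c", "total_db", "total_oh", "chains")],
    data[setdiff(names(data), c("sample_id", "lipid"))]
  )
  dup <- duplicated(out[, c("sample_id", "species")])
  if (any(dup)) {
    stop("duplicate (sample_id, species) pair(s): ",
         paste(unique(paste(out$sample_id[dup], out$species[dup])),
               collapse = "; "), call. = FALSE)
  }
  dplyr::left_join(out, metadata, by = "sample_id")
}

#' Read a lipidome from long-form CSV/TSV files
#'
#' Reads a long species-amount table (`sample_id,lipid,amount_pmol` plus
#' optional `snr`, `signal_intensity`, `blank_intensity`) and a metadata
#' table (`sample_id,strain,medium,treatment,replicate`), parses every lipid
#' name, and validates the join. The delimiter is taken from the file
#' extension (`.tsv`/`.txt` for tab, otherwise comma).
#'
#' @param file Path to the species-amount table.
#' @param metadata_file Path to the sample metadata table.
#' @return A lipidome tibble; see [lipidome_table()].
#' @export
read_lipidome <- function(file, metadata_file) {
  read_any <- function(path) {
    if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
      readr::read_tsv(path, show_col_types = FALSE)
    } else {
      readr::read_csv(path, show_col_types = FALSE)
    }
  }
  lipidome_table(read_any(file), read_any(metadata_file))
}

#' Write a lipidome table back to long-form CSV
#'
#' Writes the species-amount part (canonical names under `lipid`) and the
#' metadata part to two CSV files that [read_lipidome()] reads back to an
#' identical object.
#'
#' @param table A lipidome tibble.
#' @param file,metadata_file Output paths.
#' @param meta_cols Metadata columns to write (default: the conventional
#'   design columns present in `table`).
#' @return Invisibly, `table`.
#' @export
write_lipidome <- function(table, file, metadata_file,
                           meta_cols = intersect(
                             c("strain", "medium", "treatment", "replicate"),
                             names(table))) {
  value_cols <- intersect(c("amount_pmol", "snr", "signal_intensity",
                            "blank_intensity"), names(table))
  long <- tibble::tibble(sample_id = table$sample_id, lipid = table$species)
  long <- dplyr::bind_cols(long, table[value_cols])
  readr::write_csv(long, file)
  meta <- dplyr::distinct(table[, c("sample_id", meta_cols)])
  readr::write_csv(meta, metadata_file)
  invisible(table)
}

#' Apply lipid-identification quality filters
#'
#' Retains only rows with a signal-to-noise ratio strictly above `snr_min`
#' and a signal intensity strictly above `blank_fold_min` times the blank
#' intensity, mirroring the upstream identification criteria of shotgun
#' lipidomics pipelines (SNR > 5 and five-fold over blank by default). Rows
#' lacking a filter column pass that filter unexamined, so pre-filtered
#' input without the columns is returned unchanged.
#'
#' @param table A lipidome tibble.
#' @param snr_min Minimum signal-to-noise ratio (strict; default 5).
#' @param blank_fold_min Minimum fold-change over blank (strict; default 5).
#' @return The filtered tibble, with a `filter_report` attribute (a tibble
#'   of rows examined/kept/removed per criterion); see [filter_report()].
#' @export
apply_identification_filters <- function(table, snr_min = 5,
                                         blank_fold_min = 5) {
  if (snr_min < 0 || blank_fold_min < 0) {
    stop("filter thresholds must be non-negative", call. = FALSE)
  }
  n <- nrow(table)
  keep_snr <- rep(TRUE, n)
  if ("snr" %in% names(table)) {
    keep_snr <- is.na(table$snr) | table$snr > snr_min
  }
  keep_blank <- rep(TRUE, n)
  if (all(c("signal_intensity", "blank_intensity") %in% names(table))) {
    have <- !is.na(table$signal_intensity) & !is.na(table$blank_intensity)
    keep_blank[have] <- table$signal_intensity[have] >
      blank_fold_min * table$blank_intensity[have]
  }
  report <- tibble::tibble(
    criterion = c("snr", "blank_fold"),
    threshold = c(snr_min, blank_fold_min),
    removed = c(sum(!keep_snr), sum(keep_snr & !keep_blank)),
    kept = c(sum(keep_snr), sum(keep_snr & keep_blank))
  )
  out <- table[keep_snr & keep_blank, , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the filter report of a filtered lipidome table
#' @param table A tibble returned by [apply_identification_filters()].
#' @return The filter-report tibble, or NULL if none is attached.
#' @export
filter_report <- function(table) attr(table, "filter_report")

#' Normalize amounts to mol%
#'
#' Converts pmol amounts to molar percentages within a stated denominator:
#' all quantified lipids of the sample (`scope = "all"`), the species'
#' lipid category (`"category"`), or its lipid class (`"class"`). Within
#' each (sample, group) the resulting `mol_pct` sums to exactly 100.
#'
#' @param table A lipidome tibble.
#' @param scope Normalization denominator.
#' @return `table` with a `mol_pct` column added (any previous one is
#'   replaced) and attribute `mol_scope` recording the scope.
#' @export
normalize_mol_percent <- function(table,
                                  scope = c("all", "category", "class")) {
  scope <- match.arg(scope)
  group_cols <- switch(scope,
    all = "sample_id",
    category = c("sample_id", "category"),
    class = c("sample_id", "lipid_class")
  )
  out <- dplyr::mutate(
    dplyr::group_by(table, dplyr::across(dplyr::all_of(group_cols))),
    .group_total = sum(.data$amount_pmol)
  )
  out <- dplyr::ungroup(out)
  if (any(out$.group_total <= 0)) {
    bad <- dplyr::distinct(out[out$.group_total <= 0, group_cols])
    stop("zero total amount in scope '", scope, "' for: ",
         paste(apply(bad, 1, paste, collapse = "/"), collapse = ", "),
         call. = FALSE)
  }
  out$mol_pct <- 100 * out$amount_pmol / out$.group_total
  out$.group_total <- NULL
  attr(out, "mol_scope") <- scope
  out
}

#' Cast a lipidome to a samples-by-species matrix
#'
#' Aligns species across samples (absent species contribute 0, the
#' effective-zero convention for shotgun non-detection) and returns a
#' numeric matrix with samples as rows, suitable for PCA.
#'
#' @param table A lipidome tibble.
#' @param value Column to populate the matrix with (`"amount_pmol"` or
#'   `"mol_pct"`).
#' @return Numeric matrix, rownames = sample ids, colnames = species.
#' @export
lipidome_matrix <- function(table, value = "mol_pct") {
  if (!value %in% names(table)) {
    stop("column '", value, "' not present; run normalize_mol_percent() ",
         "first for mol_pct", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    table[, c("sample_id", "species", value)],
    names_from = "species", values_from = dplyr::all_of(value),
    values_fill = 0
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}
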