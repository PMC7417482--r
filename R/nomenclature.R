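# Shorthand lipid nomenclature: class registry, parser, renderer.

#' Lipid class registry
#'
#' The lipid classes recognized by the pipeline, their category and acyl-chain
#' arity. The four categories partition the class set: sterols (Erg),
#' sphingolipids (Cer, IPC, MIPC, M(IP)2C), membrane glycerolipids (all
#' glycerophospholipids plus DAG) and storage lipids (TAG and ergosteryl
#' esters).
#'
#' @return A tibble with columns `lipid_class`, `category` and `arity`
#'   (number of acyl chains; 0 for the sterol backbone class Erg).
#' @export
#' @examples
#' lipid_classes()
lipid_classes <- function() {
  tibble::tribble(
    ~lipid_class, ~category,                ~arity,
    "Erg",        "sterols",                0L,
    "Cer",        "sphingolipids",          2L,
    "IPC",        "sphingolipids",          2L,
    "MIPC",       "sphingolipids",          2L,
    "M(IP)2C",    "sphingolipids",          2L,
    "CL",         "membrane_glycerolipids", 4L,
    "PA",         "membrane_glycerolipids", 2L,
    "PC",         "membrane_glycerolipids", 2L,
    "PE",         "membrane_glycerolipids", 2L,
    "PG",         "membrane_glycerolipids", 2L,
    "PI",         "membrane_glycerolipids", 2L,
    "PS",         "membrane_glycerolipids", 2L,
    "DAG",        "membrane_glycerolipids", 2L,
    "CDP-DAG",    "membrane_glycerolipids", 2L,
    "LPA",        "membrane_glycerolipids", 1L,
    "LPC",        "membrane_glycerolipids", 1L,
    "LPE",        "membrane_glycerolipids", 1L,
    "LPI",        "membrane_glycerolipids", 1L,
    "LPS",        "membrane_glycerolipids", 1L,
    "TAG",        "storage_lipids",         3L,
    "EE",         "storage_lipids",         1L
  )
}

#' Classes with exactly two acyl chains used for chain-level analyses
#'
#' The membrane-glycerolipid sub-category used for total-length, double-bond,
#' chain-usage and pairing analyses: PA, PC, PE, PI, PS and DAG. All members
#' carry exactly two fatty acyl chains, so per-chain bookkeeping is
#' well-defined.
#'
#' @return Character vector of class names.
#' @export
mgl_subcategory <- function() c("PA", "PC", "PE", "PI", "PS", "DAG")

#' Map lipid classes to their category
#'
#' @param lipid_class Character vector of class names (e.g. `"PA"`, `"TAG"`).
#' @return Character vector of category names, one of `"sterols"`,
#'   `"sphingolipids"`, `"membrane_glycerolipids"`, `"storage_lipids"`.
#' @export
#' @examples
#' category_of(c("PA", "EE", "M(IP)2C"))
category_of <- function(lipid_class) {
  reg <- lipid_classes()
  idx <- match(lipid_class, reg$lipid_class)
  if (anyNA(idx)) {
    bad <- unique(lipid_class[is.na(idx)])
    stop("unknown lipid class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  reg$category[idx]
}

# Parse one chain token "C:DB[;OH]" (also accepting "," before OH).
# Returns c(carbons, double_bonds, hydroxyls) or signals with the token.
parse_chain_token <- function(token, context) {
  m <- regmatches(token, regexec("^([0-9]+):([0-9]+)(?:[;,]([0-9]+))?$", token))[[1]]
  if (length(m) == 0) {
    stop("malformed chain token '", token, "' in '", context, "'", call. = FALSE)
  }
  carbons <- as.integer(m[2])
  db <- as.integer(m[3])
  oh <- if (m[4] == "") 0L else as.integer(m[4])
  if (carbons < 2) {
    stop("invalid chain '", token, "' in '", context,
         "': carbons must be >= 2", call. = FALSE)
  }
  if (db >= carbons) {
    stop("invalid chain '", token, "' in '", context,
         "': double bonds must be < carbons", call. = FALSE)
  }
  c(carbons = carbons, double_bonds = db, hydroxyls = oh)
}

parse_one_species <- function(name) {
  reg <- lipid_classes()
  token <- trimws(name)
  if (!nzchar(token)) stop("empty species name", call. = FALSE)
  sp <- regmatches(token, regexpr(" ", token), invert = TRUE)[[1]]
  cls <- sp[1]
  idx <- match(cls, reg$lipid_class)
  if (is.na(idx)) {
    stop("unknown lipid class token '", cls, "' in '", name, "'", call. = FALSE)
  }
  arity <- reg$arity[idx]

  if (length(sp) == 1) {
    if (arity != 0L) {
      stop("species '", name, "' lacks a chain/composition part", call. = FALSE)
    }
    return(list(lipid_class = cls, chains = NULL, resolved = TRUE,
                total_c = 0L, total_db = 0L, total_oh = 0L, n_chains = 0L))
  }
  if (arity == 0L) {
    stop("class '", cls, "' takes no chain part, got '", name, "'",
         call. = FALSE)
  }

  toks <- strsplit(sp[2], "/", fixed = TRUE)[[1]]
  if (length(toks) == arity) {
    chains <- t(vapply(toks, parse_chain_token, numeric(3), context = name))
    # canonical order: descending carbons, then double bonds, then hydroxyls
    ord <- order(-chains[, 1], -chains[, 2], -chains[, 3])
    chains <- chains[ord, , drop = FALSE]
    tot <- colSums(chains)
    list(lipid_class = cls,
         chains = tibble::tibble(carbons = as.integer(chains[, 1]),
                                 double_bonds = as.integer(chains[, 2]),
                                 hydroxyls = as.integer(chains[, 3])),
         resolved = TRUE,
         total_c = as.integer(tot[1]), total_db = as.integer(tot[2]),
         total_oh = as.integer(tot[3]), n_chains = arity)
  } else if (length(toks) == 1L) {
    tot <- parse_chain_token(toks[1], context = name)
    list(lipid_class = cls, chains = NULL, resolved = FALSE,
         total_c = as.integer(tot[1]), total_db = as.integer(tot[2]),
         total_oh = as.integer(tot[3]), n_chains = arity)
  } else {
    stop("species '", name, "' has ", length(toks), " chains but class '",
         cls, "' takes ", arity, call. = FALSE)
  }
}

#' Parse shorthand lipid species names
#'
#' Parses names of the form `"<CLASS> <chain>[/<chain>...]"` (chain-resolved,
#' e.g. `"PC 17:0/14:1"`) or `"<CLASS> <C>:<DB>[;OH]"` (sum composition, e.g.
#' `"IPC 44:0;2"`). Both `";"` and `","` are accepted as the hydroxylation
#' separator. Chains are stored in canonical order (descending carbons, then
#' double bonds); sn-position is not distinguished, so `"PC 16:0/12:0"` and
#' `"PC 12:0/16:0"` denote the same species.
#'
#' @param name Character vector of shorthand names.
#' @return A tibble with one row per input name: `name` (as given), `species`
#'   (canonical rendering), `lipid_class`, `category`, `resolved` (TRUE when
#'   individual chains are known), `n_chains` (class arity), `total_c`,
#'   `total_db`, `total_oh` (sum composition), and `chains`, a list column of
#'   per-chain tibbles (`carbons`, `double_bonds`, `hydroxyls`; NULL when
#'   unresolved).
#' @export
#' @examples
#' parse_species_name(c("PC 17:0/14:1", "IPC 44:0;2", "TAG 17:0/17:0/17:0"))
parse_species_name <- function(name) {
  stopifnot(is.character(name), length(name) >= 1)
  parsed <- lapply(name, parse_one_species)
  out <- tibble::tibble(
    name = name,
    lipid_class = vapply(parsed, `[[`, character(1), "lipid_class"),
    resolved = vapply(parsed, `[[`, logical(1), "resolved"),
    n_chains = vapply(parsed, `[[`, integer(1), "n_chains"),
    total_c = vapply(parsed, `[[`, integer(1), "total_c"),
    total_db = vapply(parsed, `[[`, integer(1), "total_db"),
    total_oh = vapply(parsed, `[[`, integer(1), "total_oh"),
    chains = lapply(parsed, `[[`, "chains")
  )
  out$category <- category_of(out$lipid_class)
  out$species <- render_species_name(out)
  out[, c("name", "species", "lipid_class", "category", "resolved",
          "n_chains", "total_c", "total_db", "total_oh", "chains")]
}

format_chain <- function(carbons, double_bonds, hydroxyls = 0L) {
  base <- paste0(carbons, ":", double_bonds)
  ifelse(hydroxyls > 0, paste0(base, ";", hydroxyls), base)
}

#' Render parsed species to canonical shorthand text
#'
#' Inverse of [parse_species_name()]: emits `";"` as the hydroxylation
#' separator and chains in canonical (descending) order, so that
#' `parse_species_name(render_species_name(s))` reproduces `s`.
#'
#' @param species A tibble as returned by [parse_species_name()] (columns
#'   `lipid_class`, `resolved`, `total_c`, `total_db`, `total_oh`, `chains`).
#' @return Character vector of canonical names.
#' @export
#' @examples
#' s <- parse_species_name("PC 14:1/17:0")
#' render_species_name(s)  # "PC 17:0/14:1"
render_species_name <- function(species) {
  vapply(seq_len(nrow(species)), function(i) {
    cls <- species$lipid_class[i]
    ch <- species$chains[[i]]
    if (species$resolved[i]) {
      if (is.null(ch) || nrow(ch) == 0) return(cls)  # Erg
      paste(cls, paste(format_chain(ch$carbons, ch$double_bonds,
                                    ch$hydroxyls), collapse = "/"))
    } else {
      paste(cls, format_chain(species$total_c[i], species$total_db[i],
                              species$total_oh[i]))
    }
  }, character(1))
}

# Chain labels ("16:0") for arity-2 chain-level analyses; hydroxylation is
# ignored (glycerolipid chains in this study carry none).
chain_label <- function(carbons, double_bonds) paste0(carbons, ":", double_bonds)

# Sort chain labels numerically by carbons then double bonds.
sort_chain_labels <- function(labels) {
  parts <- strsplit(labels, ":", fixed = TRUE)
  c_n <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  db <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  labels[order(c_n, db)]
}
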