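# Shared fixture builders and independent brute-force oracles.

# Build a one-sample lipidome table from species names and amounts.
toy_lipidome <- function(lipid, amount_pmol, sample_id = "S1",
                         metadata = NULL) {
  data <- data.frame(sample_id = sample_id, lipid = lipid,
                     amount_pmol = amount_pmol)
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = unique(sample_id))
  }
  lipidome_table(data, metadata)
}

# Independent mol% oracle: plain base-R split/sum, no dplyr.
oracle_mol_pct <- function(amounts, keys) {
  sums <- tapply(amounts, keys, sum)
  stats::setNames(100 * as.numeric(sums) / sum(amounts), names(sums))
}

# Independent pairing oracle: loop over species rows given explicit chain
# pairs, accumulating unordered-pair amounts and per-chain occurrence
# "mass" in named vectors. Returns joint and conditional matrices.
oracle_pairing <- function(chain_a, chain_b, amount) {
  chains <- sort(unique(c(chain_a, chain_b)))
  k <- length(chains)
  joint <- matrix(0, k, k, dimnames = list(chains, chains))
  occ <- stats::setNames(numeric(k), chains)
  partner <- matrix(0, k, k, dimnames = list(chains, chains))
  for (i in seq_along(amount)) {
    x <- chain_a[i]; y <- chain_b[i]; a <- amount[i]
    joint[x, y] <- joint[x, y] + a
    if (x != y) joint[y, x] <- joint[y, x] + a
    # each molecule: one occurrence of x partnered with y and vice versa;
    # an x/x molecule contributes two x-occurrences partnered with x
    occ[x] <- occ[x] + a
    occ[y] <- occ[y] + a
    if (x == y) {
      partner[x, x] <- partner[x, x] + 2 * a
    } else {
      partner[x, y] <- partner[x, y] + a
      partner[y, x] <- partner[y, x] + a
    }
  }
  total <- sum(amount)
  conditional <- matrix(0, k, k, dimnames = list(chains, chains))
  for (x in chains) {
    if (occ[x] > 0) conditional[x, ] <- 100 * partner[x, ] / occ[x]
  }
  list(joint = 100 * joint / total, conditional = conditional,
       occurrence = occ)
}

# Random valid chain-resolved or sum-composition species for round-trip
# property tests.
random_species <- function(n) {
  reg <- lipid_classes()
  reg <- reg[reg$arity > 0, ]
  out <- character(n)
  for (i in seq_len(n)) {
    row <- reg[sample(nrow(reg), 1), ]
    if (runif(1) < 0.5) {  # chain-resolved
      chains <- vapply(seq_len(row$arity), function(j) {
        cc <- sample(10:18, 1)
        paste0(cc, ":", sample(0:min(2, cc - 1), 1))
      }, character(1))
      out[i] <- paste(row$lipid_class, paste(chains, collapse = "/"))
    } else {  # sum composition, sometimes hydroxylated
      cc <- sample(30:50, 1)
      oh <- sample(0:3, 1)
      out[i] <- paste0(row$lipid_class, " ", cc, ":", sample(0:3, 1),
                       if (oh > 0) paste0(";", oh) else "")
    }
  }
  out
}

expect_sums_to_100 <- function(profile, tol = 1e-9) {
  sums <- tapply(profile$mol_pct, profile$sample_id, sum)
  expect_true(all(abs(sums - 100) < 100 * tol))
}
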