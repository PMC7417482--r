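# A 10-species, 2-sample fixture used for oracle-equivalence checks.
feature_fixture <- function() {
  lip <- c("PA 16:0/16:1", "PA 12:0/16:0", "PC 16:0/12:0", "PC 18:1/16:1",
           "PE 16:0/18:1", "DAG 16:0/16:0", "TAG 48:1", "IPC 44:0;2",
           "IPC 44:0;3", "Erg")
  toy_lipidome(
    lipid = rep(lip, 2),
    amount_pmol = c(5, 3, 20, 10, 12, 2, 30, 6, 2, 10,
                    4, 2, 25, 12, 10, 1, 28, 5, 3, 10),
    sample_id = rep(c("S1", "S2"), each = 10),
    metadata = data.frame(sample_id = c("S1", "S2")))
}

test_that("class and category composition match a brute-force group-by", {
  tab <- feature_fixture()
  mp <- normalize_mol_percent(tab, "all")
  cc <- class_composition(mp)
  expect_sums_to_100(cc)
  for (s in c("S1", "S2")) {
    sub <- tab[tab$sample_id == s, ]
    truth <- oracle_mol_pct(sub$amount_pmol, sub$lipid_class)
    got <- cc$mol_pct[cc$sample_id == s]
    names(got) <- cc$key[cc$sample_id == s]
    expect_equal(got[names(truth)], truth[names(truth)], tolerance = 1e-12)
  }
  # classes come out grouped by category order
  expect_equal(cc$key[cc$sample_id == "S1"][1], "Erg")

  cat_p <- category_composition(mp)
  expect_sums_to_100(cat_p)
  sub <- tab[tab$sample_id == "S1", ]
  truth <- oracle_mol_pct(sub$amount_pmol, sub$category)
  got <- cat_p$mol_pct[cat_p$sample_id == "S1"]
  names(got) <- cat_p$key[cat_p$sample_id == "S1"]
  expect_equal(got[names(truth)], truth, tolerance = 1e-12)

  # single-class sample: 100 mol%
  single <- normalize_mol_percent(toy_lipidome("PA 16:0/16:1", 3), "all")
  expect_equal(class_composition(single)$mol_pct, 100)
})

test_that("species profiles are mol% of the class", {
  tab <- toy_lipidome(c("PA 16:0/16:1", "PA 12:0/16:0", "PA 16:0/18:1",
                        "PC 16:0/12:0"),
                      c(2, 1, 1, 10))
  sp <- species_profile(tab, "PA")
  expect_sums_to_100(sp)
  expect_equal(sort(sp$mol_pct, decreasing = TRUE), c(50, 25, 25))
  expect_equal(species_profile(tab, "PC")$mol_pct, 100)
  expect_error(species_profile(tab, "PE"), "PE")
  expect_error(species_profile(tab, "FOO"), "unknown")
})

test_that("length and double-bond histograms tally total C and DB", {
  tab <- feature_fixture()
  tl <- total_length_profile(tab)
  expect_sums_to_100(tl)
  sub <- tab[tab$sample_id == "S1" & tab$lipid_class %in% mgl_subcategory(), ]
  truth <- oracle_mol_pct(sub$amount_pmol, sub$total_c)
  got <- tl$mol_pct[tl$sample_id == "S1"]
  names(got) <- tl$key[tl$sample_id == "S1"]
  expect_equal(got[names(truth)], truth, tolerance = 1e-12)
  # TAG/IPC/Erg never enter the MGL sub-category denominator
  expect_false(48 %in% tl$key)

  db <- total_double_bond_profile(tab)
  expect_sums_to_100(db)
  truth_db <- oracle_mol_pct(sub$amount_pmol, sub$total_db)
  got_db <- db$mol_pct[db$sample_id == "S1"]
  names(got_db) <- db$key[db$sample_id == "S1"]
  expect_equal(got_db[names(truth_db)], truth_db, tolerance = 1e-12)

  # trivial cases
  one <- toy_lipidome("PC 16:0/12:0", 5)
  expect_equal(total_length_profile(one)$key, 28)
  expect_equal(total_length_profile(one)$mol_pct, 100)
  expect_equal(total_double_bond_profile(one)$key, 0)
  two <- toy_lipidome(c("PC 16:0/16:0", "PC 16:0/18:1"), c(1, 1))
  expect_equal(total_length_profile(two)$mol_pct, c(50, 50))
  expect_equal(total_double_bond_profile(two)$mol_pct, c(50, 50))

  # invariance to chain resolution: collapsing to sum composition
  # changes nothing because only total C / total DB enter
  collapsed <- tab
  collapsed_names <- ifelse(
    collapsed$lipid_class %in% mgl_subcategory(),
    paste0(collapsed$lipid_class, " ", collapsed$total_c, ":",
           collapsed$total_db),
    collapsed$species)
  # rebuild (collapsing can merge species; re-aggregate amounts)
  df <- aggregate(amount_pmol ~ sample_id + lipid,
                  data.frame(sample_id = collapsed$sample_id,
                             lipid = collapsed_names,
                             amount_pmol = collapsed$amount_pmol), sum)
  tab2 <- lipidome_table(df, data.frame(sample_id = c("S1", "S2")))
  tl2 <- total_length_profile(tab2)
  expect_equal(tl2$mol_pct, tl$mol_pct, tolerance = 1e-12)
})

test_that("chain usage counts occurrences with multiplicity", {
  expect_equal(chain_usage(toy_lipidome("PA 16:0/16:0", 1))$mol_pct, 100)
  het <- chain_usage(toy_lipidome("PA 16:0/12:0", 1))
  expect_equal(het$mol_pct, c(50, 50))

  tab <- feature_fixture()
  cu <- chain_usage(tab)
  expect_sums_to_100(cu)
  # unresolved species in scope would be excluded and counted
  expect_equal(attr(cu, "n_excluded"), 0)

  # per-class scope
  cu_pa <- chain_usage(tab, scope = "PA")
  expect_sums_to_100(cu_pa)
  # S1 PA: 16:0/16:1 (5) + 12:0/16:0 (3): occurrences 16:0=8, 16:1=5, 12:0=3
  s1 <- cu_pa[cu_pa$sample_id == "S1", ]
  got <- stats::setNames(s1$mol_pct, s1$key)
  expect_equal(got[["16:0"]], 100 * 8 / 16)
  expect_equal(got[["16:1"]], 100 * 5 / 16)
  expect_equal(got[["12:0"]], 100 * 3 / 16)
})

test_that("sphingolipid species profile is mol% of the category", {
  tab <- toy_lipidome(c("IPC 44:0;3", "IPC 44:0;4", "PA 16:0/16:1"),
                      c(3, 1, 50))
  sl <- sl_species_profile(tab)
  expect_sums_to_100(sl)
  expect_equal(stats::setNames(sl$mol_pct, sl$key),
               c("IPC 44:0;3" = 75, "IPC 44:0;4" = 25))
  expect_error(sl_species_profile(toy_lipidome("PA 16:0/16:1", 1)),
               "sphingolipid")
})
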