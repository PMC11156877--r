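# Catalog classification and synthon-compatibility filtering.

thia_synthon <- function() builtin_reaction("aminothiatriazoles")$synthons[[1]]

test_that("cheap classification covers exactly BB50 and BB40", {
  expect_true(classify_cheap("BB50"))
  expect_true(classify_cheap("BB40"))
  expect_false(classify_cheap("BB30"))
  expect_false(classify_cheap("BB20"))
  expect_false(classify_cheap("BB10"))
  expect_error(classify_cheap("BB99"))
})

test_that("inclusion and exclusion SMARTS drive acceptance", {
  blocks <- bb_catalog(c("CN", "CC(N)=O", "CCO"),
                       c("b1", "b2", "b3"), rep("BB50", 3))
  hits <- filter_catalog(blocks, thia_synthon())
  # methylamine matches the amine synthon; acetamide is vetoed by !$(NC=O);
  # ethanol has no amine at all
  expect_identical(hits$vendor_id, "b1")
  expect_gte(length(hits$match_sites[[1]]), 1L)
})

test_that("the heavy-atom cap rejects oversized blocks", {
  big <- paste0("N", paste(rep("C", 41), collapse = ""))  # 42 heavy atoms
  ok <- paste0("N", paste(rep("C", 30), collapse = ""))
  blocks <- bb_catalog(c(big, ok), c("big", "ok"), c("BB50", "BB50"))
  hits <- filter_catalog(blocks, thia_synthon())
  expect_identical(hits$vendor_id, "ok")
  # the cap is a parameter
  hits40 <- filter_catalog(blocks, thia_synthon(), max_heavy_atoms = 45L)
  expect_setequal(hits40$vendor_id, c("big", "ok"))
})

test_that("filtering is monotone in the exclusion set", {
  blocks <- fixture_catalog("aminothiatriazoles", n = 8)
  syn <- thia_synthon()
  base <- filter_catalog(blocks, syn)
  # adding exclusions never grows the accepted set
  syn_more <- syn
  syn_more$exclusion_patterns <- c(syn$exclusion_patterns, "[OX2]")
  narrower <- filter_catalog(blocks, syn_more)
  expect_true(all(narrower$vendor_id %in% base$vendor_id))
  # and the global-exclusion argument behaves the same way
  narrower2 <- filter_catalog(blocks, syn, global_exclusions = "[CX4H3]")
  expect_true(all(narrower2$vendor_id %in% base$vendor_id))
  expect_lt(nrow(narrower2), nrow(base))
})

test_that("filtering preserves order and is invariant to duplication", {
  blocks <- fixture_catalog("aminothiatriazoles", n = 8)
  base <- filter_catalog(blocks, thia_synthon())
  expect_identical(base$vendor_id,
                   blocks$vendor_id[blocks$vendor_id %in% base$vendor_id])
  doubled <- rbind(blocks, blocks)
  class(doubled) <- class(blocks)
  dedup <- filter_catalog(doubled[!duplicated(doubled$vendor_id), ],
                          thia_synthon())
  expect_identical(dedup$vendor_id, base$vendor_id)
})

test_that("unparseable SMILES are skipped, not fatal", {
  blocks <- bb_catalog(c("CN", "not_a_smiles"), c("ok", "bad"),
                       c("BB50", "BB50"))
  expect_message(hits <- filter_catalog(blocks, thia_synthon()),
                 "unparseable")
  expect_identical(hits$vendor_id, "ok")
})

test_that("salts are stripped to the largest organic fragment", {
  expect_identical(strip_salts("CCN.Cl"), smiles_canonical("CCN"))
  blocks <- bb_catalog("CCN.Cl", "salty", "BB50")
  hits <- filter_catalog(blocks, thia_synthon())
  expect_identical(nrow(hits), 1L)
})

test_that("symmetric anhydrides are flagged by the symmetric detector", {
  syn <- builtin_reaction("cycloadd22")$synthons[[1]]
  blocks <- bb_catalog(c("CC(=O)OC(C)=O", "CC(=O)OC(=O)CC"),
                       c("sym", "asym"), c("BB50", "BB50"))
  hits <- filter_catalog(blocks, syn,
                         builtin_reaction("cycloadd22")$global_exclusions)
  expect_identical(hits$symmetric, c(TRUE, TRUE))
  # the detector pattern matches any anhydride; both records carry sites
  expect_true(all(lengths(hits$match_sites) >= 1L))
})

test_that("precursor expansion produces the expected dioxinones", {
  pre <- builtin_reaction("betaketoimides")$synthons[[2]]
  expect_true(pre$is_precursor)
  got <- apply_precursor(oracle_precursor$acetoacetic$smiles,
                         pre$precursor_transform)
  expect_identical(smiles_inchikey(got), oracle_precursor$acetoacetic$inchikey)
  expect_identical(apply_precursor("OC(=O)c1ccccc1",
                                   pre$precursor_transform), character(0))
  # a molecule with two beta-keto-acid motifs yields both products
  got2 <- sort(smiles_inchikey(apply_precursor(
    oracle_precursor$double_motif$smiles, pre$precursor_transform)))
  expect_identical(got2, sort(oracle_precursor$double_motif$inchikeys))
})

test_that("a vendor id listed under several tiers keeps the cheapest", {
  blocks <- bb_catalog(c("CN", "CN", "CCN"), c("dup", "dup", "x"),
                       c("BB20", "BB40", "BB10"))
  expect_identical(blocks$tier[blocks$vendor_id == "dup"], "BB40")
  expect_identical(nrow(blocks), 2L)
})
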