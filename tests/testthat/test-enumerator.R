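# Enumeration bookkeeping: chunking, deduplication, provenance,
# purchasability, curation sampling.

test_that("one-component enumeration yields one product per reactive amine", {
  defn <- builtin_reaction("aminothiatriazoles")
  blocks <- generate_fixtures("primary_amine", 3, seed = 11)
  pools <- build_pools(defn, blocks)
  prods <- enumerate_products(defn, pools)
  expect_identical(nrow(prods), 3L)
  expect_true(all(startsWith(prods$product_id, "aminothiatriazoles_THIA_1_")))
  expect_true(all(is.na(prods$reagent_b)))
})

test_that("two-component enumeration matches the full cross-product", {
  defn <- builtin_reaction("aminotetrazoles")
  blocks <- rbind(generate_fixtures("primary_amine", 2, seed = 5),
                  generate_fixtures("isothiocyanate", 2, seed = 5))
  class(blocks) <- c("bb_catalog", "data.frame")
  pools <- build_pools(defn, blocks)
  prods <- enumerate_products(defn, pools)
  expect_identical(nrow(prods), 4L)  # 2 amines x 2 isothiocyanates
  expect_identical(anyDuplicated(prods$inchikey), 0L)
})

test_that("chunk size does not change the enumerated set", {
  defn <- builtin_reaction("cycloadd22")
  pools <- build_pools(defn, fixture_catalog("cycloadd22", n = 5))
  p1 <- enumerate_products(defn, pools,
                           enumeration_options(chunk_size = 1))
  p2 <- enumerate_products(defn, pools,
                           enumeration_options(chunk_size = 2000))
  expect_setequal(p1$inchikey, p2$inchikey)
})

test_that("symmetric reagents contribute each product once", {
  defn <- builtin_reaction("cycloadd22")
  blocks <- bb_catalog(c("CC(=O)OC(C)=O", "C=Cc1ccccc1"),
                       c("anh", "sty"), c("BB50", "BB50"))
  pools <- build_pools(defn, blocks)
  expect_true(pools$W22_A_ANH$symmetric[1])
  prods <- suppressWarnings(enumerate_products(defn, pools))
  expect_identical(nrow(prods), 1L)
  expect_identical(prods$inchikey, "UVGRBUMTKCGCPM-UHFFFAOYSA-N")
})

test_that("enumeration equals the brute-force oracle on every packaged reaction", {
  for (rid in c("aminothiatriazoles", "aminotetrazoles", "betaketoimides")) {
    defn <- builtin_reaction(rid)
    pools <- build_pools(defn, fixture_catalog(rid, n = 4))
    got <- suppressWarnings(enumerate_products(defn, pools))
    expect_identical(sort(unique(got$inchikey)),
                     brute_force_inchikeys(defn, pools),
                     label = rid)
  }
})

test_that("an empty required pool warns and yields nothing for the variant", {
  defn <- builtin_reaction("aminotetrazoles")
  blocks <- generate_fixtures("primary_amine", 3, seed = 1)
  pools <- build_pools(defn, blocks)   # no isothiocyanates at all
  expect_warning(prods <- enumerate_products(defn, pools), "empty pool")
  expect_identical(nrow(prods), 0L)
})

test_that("purchasability coding is exhaustive over tier pairs", {
  tiers <- bb_tiers()
  for (a in tiers) {
    for (b in tiers) {
      got <- assign_purchasability(c(a, b))
      want <- if (a == "BB50" && b == "BB50") "1"
        else if (all(c(a, b) %in% c("BB50", "BB40"))) "2"
        else "expensive"
      expect_identical(got, want, label = paste(a, b))
    }
    got1 <- assign_purchasability(a)
    expect_identical(got1, if (a == "BB50") "1"
                           else if (a == "BB40") "2" else "expensive")
  }
})

test_that("max_products caps the stream", {
  defn <- builtin_reaction("aminothiatriazoles")
  pools <- build_pools(defn, generate_fixtures("primary_amine", 6, seed = 2))
  prods <- enumerate_products(defn, pools,
                              enumeration_options(max_products = 3))
  expect_identical(nrow(prods), 3L)
})

test_that("curation sampling is a deterministic MaxMin pick", {
  defn <- builtin_reaction("aminothiatriazoles")
  blocks <- rbind(generate_fixtures("primary_amine", 6, seed = 2),
                  generate_fixtures("secondary_amine", 6, seed = 2))
  class(blocks) <- c("bb_catalog", "data.frame")
  prods <- enumerate_products(defn, build_pools(defn, blocks))
  expect_gte(nrow(prods), 8L)
  s1 <- curation_sample(prods, 4, seed = 9)
  s2 <- curation_sample(prods, 4, seed = 9)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 4L)
  # k = n returns everything; k > n warns and returns everything
  expect_identical(nrow(curation_sample(prods, nrow(prods))), nrow(prods))
  expect_warning(all_of_them <- curation_sample(prods, nrow(prods) + 5),
                 "exceeds")
  expect_identical(nrow(all_of_them), nrow(prods))
})

test_that("MaxMin never picks an exact duplicate while alternatives exist", {
  prods <- data.frame(
    smiles = c("CCO", "CCO", "c1ccccc1", "CCCCCCCC", "CC(=O)O"),
    stringsAsFactors = FALSE)
  picked <- curation_sample(prods, 4, seed = 1)
  expect_lte(sum(picked$smiles == "CCO"), 1L)
})

test_that("greedy MaxMin attains the exhaustive-optimal spread on a small set", {
  smis <- c("C", "CCCCCCCC", "c1ccccc1", "O=C(O)CCC(=O)O",
            "c1ccc2ccccc2c1", "CC(C)(C)C")
  fps <- lapply(smis, ecfp_bits)
  dist <- function(sel) {
    m <- Inf
    for (i in seq_along(sel)) for (j in seq_len(i - 1L)) {
      m <- min(m, 1 - fp_tanimoto(fps[[sel[i]]], fps[[sel[j]]]))
    }
    m
  }
  best <- max(apply(utils::combn(6, 3), 2, dist))
  greedy <- dist(maxmin_pick(fps, 3, seed = 1))
  expect_equal(greedy, best, tolerance = 1e-12)
})

test_that("global deduplication collapses identical compounds across calls", {
  defn <- builtin_reaction("aminothiatriazoles")
  pools <- build_pools(defn, generate_fixtures("primary_amine", 4, seed = 2))
  a <- enumerate_products(defn, pools)
  pooled <- rbind(a, a)
  expect_identical(nrow(dedup_products(pooled)), nrow(a))
})
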