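# Scaffold census/overlap, NPR shape analytics, identity partitions.

test_that("Bemis-Murcko scaffolds follow the ring-plus-linker definition", {
  expect_identical(murcko_scaffold("Cc1ccccc1"),
                   smiles_canonical("c1ccccc1"))
  # a scaffold is its own scaffold
  bz <- murcko_scaffold("c1ccccc1")
  expect_identical(murcko_scaffold(bz), bz)
  # acyclic molecules map to the empty sentinel
  expect_identical(murcko_scaffold("CCCCCC"), "")
  # side-chain carbonyls fall off; linker carbonyls stay
  expect_identical(murcko_scaffold("CC(=O)c1ccccc1"),
                   smiles_canonical("c1ccccc1"))
  expect_identical(murcko_scaffold("O=C(c1ccccc1)c1ccccc1"),
                   smiles_canonical("O=C(c1ccccc1)c1ccccc1"))
})

test_that("the scaffold census is order-invariant and tracks acyclics", {
  smis <- c("Cc1ccccc1", "CCc1ccccc1", "c1ccncc1", "CCCC", "CCCCC")
  s1 <- scaffold_summary(smis)
  s2 <- scaffold_summary(rev(smis))
  expect_identical(s1$scaffold_counts, s2$scaffold_counts)
  expect_identical(s1$n_compounds, 5L)
  expect_identical(s1$n_scaffolds, 3L)  # benzene, pyridine, "" sentinel
  expect_identical(s1$n_acyclic, 2L)
  expect_equal(s1$compounds_per_scaffold, 5 / 3)
})

test_that("scaffold overlap equals a brute-force set intersection", {
  a <- scaffold_summary(c("Cc1ccccc1", "c1ccncc1", "C1CCCCC1"))
  b <- scaffold_summary(c("CCc1ccccc1", "c1ccoc1"))
  ov <- scaffold_overlap(a, b)
  expect_identical(ov$shared,
                   length(intersect(names(a$scaffold_counts),
                                    names(b$scaffold_counts))))
  expect_identical(ov$shared, 1L)   # benzene
  same <- scaffold_overlap(a, a)
  expect_identical(same$shared, a$n_scaffolds)
  expect_identical(same$fraction_a, 1)
  disj <- scaffold_overlap(scaffold_summary("c1ccoc1"),
                           scaffold_summary("C1CCCCC1"))
  expect_identical(disj$shared, 0L)
})

test_that("idealized point masses hit the NPR triangle corners", {
  rod <- cbind(seq(-5, 5, length.out = 11), 0, 0)
  expect_equal(unname(npr_from_points(rod)),
               c(0, 1), tolerance = 1e-9)
  theta <- seq(0, 2 * pi, length.out = 13)[-13]
  disc <- cbind(cos(theta), sin(theta), 0)
  expect_equal(unname(npr_from_points(disc)),
               c(0.5, 0.5), tolerance = 1e-9)
  sphere <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(unname(npr_from_points(sphere)),
               c(1, 1), tolerance = 1e-9)
})

test_that("embedded fixture molecules satisfy the NPR triangle", {
  smis <- unique(c(generate_fixtures("aryl_sulfonamide", 5, seed = 2)$smiles,
                   generate_fixtures("amide", 10, seed = 2)$smiles,
                   generate_fixtures("olefin_1sub", 5, seed = 2)$smiles))
  n <- npr_shape(smis)
  expect_true(all(n$npr1 <= n$npr2 + 1e-6))
  expect_true(all(n$npr2 <= 1 + 1e-6))
  expect_true(all(n$npr1 + n$npr2 >= 1 - 1e-6))
})

test_that("shape binning conserves counts and respects the grid", {
  g1 <- bin_shapes(data.frame(npr1 = 0.3, npr2 = 0.8))
  expect_identical(sum(g1$grid), 1L)
  expect_identical(g1$nbins, 200L)
  gn <- bin_shapes(data.frame(npr1 = rep(0.3, 7), npr2 = rep(0.8, 7)))
  expect_identical(max(gn$grid), 7L)
  expect_identical(sum(gn$grid > 0L), 1L)
  # against an independent 2D histogram on a spread of points
  set.seed(1)
  npr2 <- runif(200, 0.5, 1)
  npr1 <- vapply(npr2, function(y) runif(1, 1 - y, y), numeric(1))
  g <- bin_shapes(data.frame(npr1, npr2), nbins = 20)
  ref <- table(cut(npr1, seq(0, 1, length.out = 21), include.lowest = TRUE),
               cut(npr2, seq(0.5, 1, length.out = 21), include.lowest = TRUE))
  expect_identical(sum(g$grid), 200L)
  expect_identical(as.vector(unclass(ref)), as.vector(g$grid))
  # out-of-triangle points clamp with a warning
  expect_warning(gb <- bin_shapes(data.frame(npr1 = 0.9, npr2 = 0.2)),
                 "clamped")
  expect_identical(sum(gb$grid), 1L)
})

test_that("partitioned identity lookup equals a linear scan", {
  # benzene: known standard InChIKey, 6 heavy atoms -> bucket "6/UH"
  bz <- smiles_inchikey("c1ccccc1")
  expect_identical(substr(bz, 1, 2), "UH")
  part <- build_partition(bz, 6L)
  expect_identical(names(part), "6/UH")
  expect_true(partition_lookup(part, bz, 6L))
  expect_false(partition_lookup(part, bz, 7L))
  expect_error(build_partition("BADKEY", 6L), "malformed")

  rand_key <- function(n) {
    paste0(
      vapply(seq_len(n), function(i)
        paste(sample(LETTERS, 14, TRUE), collapse = ""), character(1)),
      "-",
      vapply(seq_len(n), function(i)
        paste(sample(LETTERS, 10, TRUE), collapse = ""), character(1)),
      "-N")
  }
  set.seed(7)
  keys <- rand_key(2000)
  hac <- sample(5:40, 2000, TRUE)
  part <- build_partition(keys, hac)
  queries <- c(sample(seq_along(keys), 300),  # inserted
               rep(NA, 0))
  for (q in queries) {
    expect_true(partition_lookup(part, keys[q], hac[q]))
  }
  probes <- rand_key(300)
  probe_hac <- sample(5:40, 300, TRUE)
  for (i in seq_along(probes)) {
    linear <- any(keys == probes[i] & hac == probe_hac[i])
    expect_identical(partition_lookup(part, probes[i], probe_hac[i]),
                     linear)
  }
})

test_that("the partition store round-trips through the directory layout", {
  set.seed(3)
  keys <- smiles_inchikey(c("c1ccccc1", "CCO", "CC(=O)O", "c1ccncc1"))
  hac <- heavy_atom_count(c("c1ccccc1", "CCO", "CC(=O)O", "c1ccncc1"))
  part <- build_partition(keys, hac)
  dir <- withr::local_tempdir()
  write_partition_store(part, dir)
  part2 <- read_partition_store(dir)
  expect_identical(part2[order(names(part2))],
                   part[order(names(part))], ignore_attr = TRUE)
  expect_true(file.exists(file.path(dir, hac[1], "UH.txt")))
})
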