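# Reaction-definition parsing, validation, serialization and the packaged
# library.

test_that("a single-synthon reagents file parses into one definition", {
  text <- c("SYNTHON\tAM1\t[NX3;H2,H1;!$(NC=O)]",
            "TAG\tAM1\tAMINE_A")
  syn <- parse_synthon_file(text)
  expect_length(syn, 1L)
  expect_identical(syn[[1]]$synthon_id, "AM1")
  expect_identical(syn[[1]]$inclusion_patterns, "[NX3;H2,H1;!$(NC=O)]")
  expect_identical(syn[[1]]$reaction_tags, "AMINE_A")
  expect_false(syn[[1]]$is_precursor)
})

test_that("parser errors carry line numbers and reject unknown records", {
  expect_error(parse_synthon_file(c("SYNTHON\tA\tC(((", "TAG\tA\tX")),
               "line 1.*unparseable")
  expect_error(parse_synthon_file("FROBNICATE\tA\tC"), "unknown record")
  expect_error(parse_synthon_file(c("SYNTHON\tA\tC", "TAG\tA\tX",
                                    "EXCLUDE\tB\tC")), "undeclared")
  expect_error(parse_reaction_file("REACTION\tV1\tC>>CC"), "needs id")
})

test_that("a reactions file yields variants with component tags in order", {
  txt <- "REACTION\tV1\t[NX3;H2,H1;!$(NC=O):1]>>[N:1]C1=NN=NS1\tAMINE_A\tchain=0"
  v <- parse_reaction_file(txt)
  expect_length(v, 1L)
  expect_identical(v[[1]]$component_tags, "AMINE_A")
  expect_identical(unname(v[[1]]$annotations["chain"]), "0")
  expect_identical(parse_reaction_file(character(0)), list())
  # two reagent templates with a single tag: arity mismatch
  expect_error(parse_reaction_file(
    "REACTION\tV1\t[N:1].[O:2]>>[N:1][O:2]\tAMINE_A"), "component tag")
})

test_that("serialize/parse round-trips field by field", {
  for (rid in c("betaketoimides", "trucesmiles", "cycloadd42")) {
    defn <- builtin_reaction(rid)
    syn2 <- parse_synthon_file(serialize_synthons(
      defn$synthons, defn$global_exclusions))
    expect_equal(syn2, defn$synthons, ignore_attr = TRUE)
    expect_identical(attr(syn2, "global_exclusions"),
                     defn$global_exclusions)
    var2 <- parse_reaction_file(serialize_variants(defn$variants))
    expect_equal(var2, defn$variants)
  }
})

test_that("the packaged library has the documented composition", {
  lib <- builtin_library()
  expect_length(lib, 6L)
  expect_length(lib$trucesmiles$variants, 12L)
  expect_length(lib$cycloadd22$variants, 4L)
  expect_length(lib$cycloadd42$variants, 6L)
  # Truce-Smiles reagent classes: 2 conditions for reagent A, 6 for reagent B
  ids <- vapply(lib$trucesmiles$synthons, `[[`, character(1), "synthon_id")
  expect_length(grep("^TS_A_", ids), 2L)
  expect_length(grep("^TS_B_", ids), 6L)
  # precursor feeders for the dioxinone pool: free acid + 4 protections
  pre <- vapply(lib$betaketoimides$synthons, `[[`, logical(1),
                "is_precursor")
  expect_identical(sum(pre), 5L)
})

test_that("every packaged definition validates cleanly", {
  for (defn in builtin_library()) {
    rep <- validate_reaction(defn)
    expect_true(rep$ok, label = defn$reaction_id)
    expect_identical(sum(rep$issues$severity == "error"), 0L)
  }
})

test_that("validation flags unresolved tags and orphan product maps", {
  syn <- synthon_definition("S1", "[NX3;H2,H1]", reaction_tags = "A")
  v_ok <- reaction_variant("V1", "[NX3;H2,H1:1]>>[N:1]C", "A")
  defn <- reaction_definition("r", "r", list(syn), list(v_ok))
  expect_true(validate_reaction(defn)$ok)
  v_bad <- reaction_variant("V2", "[NX3;H2,H1:1]>>[N:1]C", "NOSUCH")
  defn2 <- reaction_definition("r", "r", list(syn), list(v_ok, v_bad))
  rep2 <- validate_reaction(defn2)
  expect_false(rep2$ok)
  expect_match(paste(rep2$issues$message, collapse = " "),
               "unresolved tag")
  # orphan product map is rejected at variant construction already
  expect_error(reaction_variant("V3", "[NX3:1]>>[N:1][C:9]C", "A"),
               "absent")
})

test_that("validation is pure and warns about unused synthons", {
  defn <- builtin_reaction("aminotetrazoles")
  expect_identical(validate_reaction(defn), validate_reaction(defn))
  extra <- synthon_definition("UNUSED", "[OX2H1]", reaction_tags = "ZZZ")
  defn$synthons <- c(defn$synthons, list(extra))
  rep <- validate_reaction(defn)
  expect_true(rep$ok)  # warning severity only
  expect_match(paste(rep$issues$message, collapse = " "),
               "not referenced")
})

test_that("duplicate synthon ids are rejected", {
  s <- synthon_definition("X", "[OX2H1]", reaction_tags = "T")
  v <- reaction_variant("V", "[OX2H1:1]>>[O:1]C", "T")
  expect_error(reaction_definition("r", "r", list(s, s), list(v)),
               "duplicate")
})
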