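# Deterministic synthetic building-block generator. Fixture chemistry is
# assembled from curated sub-fragment grammars per reagent class (small
# alkyl/aryl decorations on the class's core motif), so class membership is
# guaranteed by construction and verified against the packaged synthon
# SMARTS at generation time.

fixture_grammar <- function() {
  alkyl <- c("C", "CC", "CCC", "CCCC", "CCCCC", "CC(C)C", "CCC(C)C",
             "C1CCCCC1")
  list(
    primary_amine = c(paste0("N", alkyl), "NCc1ccccc1", "NCCc1ccccc1"),
    secondary_amine = c("CNC", "CNCC", "CCNCC", "CNCCC", "CCNCCC",
                        "CNCC(C)C", "C1CCNCC1", "C1CCNC1", "O1CCNCC1",
                        "CNCc1ccccc1", "CCNCc1ccccc1", "CNC1CCCCC1"),
    amide = c(paste0("NC(=O)", alkyl), "NC(=O)c1ccccc1",
              "NC(=O)Cc1ccccc1", paste0("CNC(=O)", alkyl[1:6])),
    # the printed isothiocyanate filter's !H primitive rejects attachment
    # carbons carrying exactly one hydrogen, so all cores attach via CH3/CH2
    isothiocyanate = c(paste0("S=C=N", setdiff(alkyl, "C1CCCCC1")),
                       "S=C=NCc1ccccc1", "S=C=NCC1CCCCC1"),
    acyl_halide_ewg = c(
      "O=C(Cl)CC#N", "O=C(Cl)CS(C)(=O)=O", "O=C(Cl)CC(C)=O",
      "O=C(Cl)CC(=O)OC", "O=C(Cl)CC(=O)OCC",
      "O=C(Cl)CCC#N", "O=C(Cl)CCC(C)=O", "O=C(Cl)CCC(=O)OC",
      "O=C(Cl)CCCC#N", "O=C(Cl)CCCC(=O)OC",
      "O=C(Cl)C(C)C#N", "O=C(Cl)C(CC)C#N", "O=C(Cl)C(C)C(C)=O",
      "O=C(Cl)CC(C)C#N", "O=C(Cl)CC(C)C(=O)OC",
      "O=C(Cl)CCC(C)C#N"),
    beta_keto_acid = paste0("OC(=O)CC(=O)", alkyl),
    beta_keto_ester = c(paste0("COC(=O)CC(=O)", alkyl[1:4]),
                        paste0("CCOC(=O)CC(=O)", alkyl[1:4]),
                        paste0("CC(C)(C)OC(=O)CC(=O)", alkyl[1:4]),
                        paste0("O=C(OCc1ccccc1)CC(=O)", alkyl[1:4])),
    dioxinone = paste0(alkyl, "C1=CC(=O)OC(C)(C)O1"),
    anhydride = c("CC(=O)OC(C)=O", "CCC(=O)OC(=O)CC",
                  "CCCC(=O)OC(=O)CCC", "CC(C)C(=O)OC(=O)C(C)C",
                  "CC(=O)OC(=O)CC", "CC(=O)OC(=O)CCC",
                  "CCCCC(=O)OC(=O)CCCC"),
    acyl_chloride = c("CC(=O)Cl", "CCC(=O)Cl", "CCCC(=O)Cl",
                      "CC(C)C(=O)Cl", "CC(C)CC(=O)Cl",
                      "C1CCCCC1C(=O)Cl", "c1ccccc1CC(=O)Cl"),
    olefin_1sub = c("C=Cc1ccccc1", "C=CC(=O)OC", "C=CC#N", "C=CC(C)=O",
                    "C=Cc1ccc(C)cc1", "C=CC(=O)OCC", "C=CC(=O)OC(C)C"),
    olefin_11sub = c("C=C(C)c1ccccc1", "C=C(C)C(=O)OC", "C=C(C)C#N",
                     "C=C(C)C(C)=O", "C=C(CC)C(=O)OC", "C=C(CC)C#N"),
    furan = c("c1ccoc1", "Cc1ccco1", "CCc1ccco1", "Cc1ccc(C)o1",
              "CCCc1ccco1", "CC(C)c1ccco1"),
    pyrrole = c("Cn1cccc1", "CCn1cccc1", "CCCn1cccc1", "CC(C)n1cccc1",
                "CCCCn1cccc1", "CCCCCn1cccc1", "CC(C)Cn1cccc1",
                "CCC(C)n1cccc1"),
    cyclopentadiene = c("C1=CC=CC1", "CC1=CC=CC1", "CCC1=CC=CC1",
                        "CC1=CC=C(C)C1", "CCC1=CC=C(C)C1",
                        "CCCC1=CC=CC1", "CC(C)C1=CC=CC1"),
    aryl_ZH = c("Oc1ccccc1", "Nc1ccccc1", "Sc1ccccc1", "Oc1ccc(C)cc1",
                "Nc1ccc(C)cc1", "Oc1cccc(C)c1", "Oc1ccc(CC)cc1",
                "Nc1cccc(CC)c1", "Oc1ccc2ccccc2c1", "Sc1ccc(C)cc1"),
    aryl_sulfonamide = c("NS(=O)(=O)c1ccccc1", "NS(=O)(=O)c1ccc(C)cc1",
                         "NS(=O)(=O)c1cccc(C)c1", "NS(=O)(=O)c1ccc(CC)cc1",
                         "NS(=O)(=O)c1ccc(C(C)C)cc1",
                         "NS(=O)(=O)c1ccc2ccccc2c1"))
}

# Which packaged reaction/synthon consumes each fixture class; used to
# verify class membership and the (pruned) global exclusions at generation
# time.
fixture_targets <- function() {
  list(
    primary_amine = list("aminothiatriazoles", "THIA_A"),
    secondary_amine = list("aminothiatriazoles", "THIA_A"),
    amide = list("betaketoimides", "BKI_B"),
    isothiocyanate = list("aminotetrazoles", "TET_B"),
    acyl_halide_ewg = list("trucesmiles",
                           c("TS_B_H0", "TS_B_H1", "TS_B_H2",
                             "TS_B_R0", "TS_B_R1", "TS_B_R2")),
    beta_keto_acid = list("betaketoimides", "BKI_A_PRE_ACID"),
    beta_keto_ester = list("betaketoimides",
                           c("BKI_A_PRE_TBU", "BKI_A_PRE_ME",
                             "BKI_A_PRE_ET", "BKI_A_PRE_BN")),
    dioxinone = list("betaketoimides", "BKI_A"),
    anhydride = list("cycloadd22", "W22_A_ANH"),
    acyl_chloride = list("cycloadd22", "W22_A_ACL"),
    olefin_1sub = list("cycloadd22", "W22_B_1"),
    olefin_11sub = list("cycloadd22", "W22_B_11"),
    furan = list("cycloadd42", "W42_B_FUR"),
    pyrrole = list("cycloadd42", "W42_B_PYR"),
    cyclopentadiene = list("cycloadd42", "W42_B_CP"),
    aryl_ZH = list("trucesmiles", "TS_A_ZH"),
    aryl_sulfonamide = list("trucesmiles", "TS_A_SULF"))
}

#' Fixture reagent classes
#'
#' @return character vector of the synthetic building-block classes the
#'   generator can emit, covering every reagent class the packaged
#'   reactions consume.
#' @export
fixture_classes <- function() names(fixture_grammar())

#' Generate a deterministic synthetic building-block catalog
#'
#' Emits `n` distinct building blocks of the requested class, with vendor
#' ids `FIX-<class>-<index>` and tiers drawn reproducibly from `tier_mix`.
#' Every block is verified at generation time to match at least one
#' inclusion SMARTS of the packaged synthon consuming the class and none of
#' that reaction's (pruned) global exclusions; violation is an error, never
#' a silent under-delivery.
#'
#' @param synthon_class one of [fixture_classes()].
#' @param n number of blocks (at most the size of the class grammar).
#' @param seed integer seed; fixed seed, identical output.
#' @param tier_mix named probability vector over [bb_tiers()]. The default
#'   is a balanced test mix, not a market-rate emulation.
#' @return a [bb_catalog()] data frame.
#' @export
#' @examples
#' generate_fixtures("primary_amine", 5, seed = 1)
generate_fixtures <- function(synthon_class, n, seed = 1L,
                              tier_mix = c(BB50 = 0.35, BB40 = 0.25,
                                           BB30 = 0.2, BB20 = 0.1,
                                           BB10 = 0.1)) {
  synthon_class <- match.arg(synthon_class, fixture_classes())
  stopifnot(n >= 0L, all(names(tier_mix) %in% bb_tiers()),
            length(tier_mix) >= 1L)
  if (n == 0L) {
    return(bb_catalog(character(0), character(0), character(0)))
  }
  pool <- fixture_grammar()[[synthon_class]]
  if (n > length(pool)) {
    stop("class '", synthon_class, "' can deliver at most ", length(pool),
         " distinct blocks (", n, " requested)", call. = FALSE)
  }
  target <- fixture_targets()[[synthon_class]]
  defn <- builtin_reaction(target[[1]])
  syns <- defn$synthons[vapply(defn$synthons, function(s)
    s$synthon_id %in% target[[2]], logical(1))]
  inclusions <- unlist(lapply(syns, `[[`, "inclusion_patterns"))
  inc_ok <- rowSums(smarts_screen(pool, inclusions)) > 0L
  glob_hit <- if (length(defn$global_exclusions)) {
    rowSums(smarts_screen(pool, unname(defn$global_exclusions))) > 0L
  } else rep(FALSE, length(pool))
  hac_ok <- heavy_atom_count(pool) <= 40L
  bad <- !inc_ok | glob_hit | !hac_ok
  if (any(bad)) {
    stop("fixture grammar for '", synthon_class,
         "' emits non-conforming block(s): ",
         paste(pool[bad], collapse = ", "), call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pick <- sort(sample.int(length(pool), n))
  tiers <- sample(names(tier_mix), n, replace = TRUE,
                  prob = as.numeric(tier_mix))
  bb_catalog(pool[pick],
             sprintf("FIX-%s-%03d", synthon_class, pick),
             tiers)
}
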