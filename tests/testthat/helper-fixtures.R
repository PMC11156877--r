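# Shared fixtures: reagent catalogs per packaged reaction and the frozen
# expected products of the worked transform examples. Expected values were
# computed with an independent reaction engine (RDKit RunReactants) and
# frozen as InChIKeys, which are toolkit-independent identities.

fixture_classes_for <- function(reaction_id) {
  switch(reaction_id,
    betaketoimides = c("dioxinone", "beta_keto_acid", "beta_keto_ester",
                       "amide"),
    aminothiatriazoles = c("primary_amine", "secondary_amine"),
    aminotetrazoles = c("primary_amine", "secondary_amine",
                        "isothiocyanate"),
    trucesmiles = c("aryl_ZH", "aryl_sulfonamide", "acyl_halide_ewg"),
    cycloadd22 = c("anhydride", "acyl_chloride", "olefin_1sub",
                   "olefin_11sub"),
    cycloadd42 = c("anhydride", "acyl_chloride", "furan", "pyrrole",
                   "cyclopentadiene"),
    stop("unknown reaction: ", reaction_id))
}

fixture_catalog <- function(reaction_id, n = 6, seed = 3) {
  cats <- lapply(fixture_classes_for(reaction_id), function(cl)
    generate_fixtures(cl, n, seed = seed))
  out <- do.call(rbind, cats)
  class(out) <- class(cats[[1]])
  out
}

# worked transform examples: list(transform SMILES..., reagents, inchikeys)
oracle_cases <- list(
  thia_dimethylamine = list(
    reagents = "CNC", variant = c("aminothiatriazoles", "THIA_1"),
    inchikey = "QGRHRTWAZAXAPK-UHFFFAOYSA-N"),
  thia_methylamine = list(
    reagents = "CN", variant = c("aminothiatriazoles", "THIA_1"),
    inchikey = "SLQJKKVTPGNODA-UHFFFAOYSA-N"),
  tetra_me_menecs = list(
    reagents = c("CN", "S=C=NC"), variant = c("aminotetrazoles", "TET_1"),
    inchikey = "FBRRQXJRKCVETE-UHFFFAOYSA-N"),
  tetra_me2_bnncs = list(
    reagents = c("CNC", "S=C=NCc1ccccc1"),
    variant = c("aminotetrazoles", "TET_1"),
    inchikey = "UDOXHSLXCAPDGB-UHFFFAOYSA-N"),
  bki_acetamide = list(
    reagents = c("CC1=CC(=O)OC(C)(C)O1", "CC(N)=O"),
    variant = c("betaketoimides", "BKI_1"),
    inchikey = "IZOZBUJRWPPEBT-UHFFFAOYSA-N"),
  bki_benzamide = list(
    reagents = c("CC1=CC(=O)OC(C)(C)O1", "NC(=O)c1ccccc1"),
    variant = c("betaketoimides", "BKI_1"),
    inchikey = "BJCFBSKAHBOOGK-UHFFFAOYSA-N"),
  wood_t1_phenol = list(
    reagents = c("Oc1ccccc1", "O=C(Cl)CC#N"),
    variant = c("trucesmiles", "TS01"),
    inchikey = "DKFPBXQCCCIWLC-UHFFFAOYSA-N"),
  wood_t1_aniline = list(
    reagents = c("Nc1ccccc1", "O=C(Cl)CC#N"),
    variant = c("trucesmiles", "TS01"),
    inchikey = "DJEAUFPPXDHFCN-UHFFFAOYSA-N"),
  wood_t2_phenol = list(
    reagents = c("Oc1ccccc1", "O=C(Cl)CCC#N"),
    variant = c("trucesmiles", "TS02"),
    inchikey = "GMPNSKPTQXVWAF-UHFFFAOYSA-N"),
  wood_t4_chiral = list(
    reagents = c("Oc1ccccc1", "O=C(Cl)C(C)C#N"),
    variant = c("trucesmiles", "TS04"),
    inchikey = "LIHRKJFTTDKLPV-UHFFFAOYSA-N"),
  wood_t7_sulfonamide = list(
    reagents = c("NS(=O)(=O)c1ccccc1", "O=C(Cl)CC#N"),
    variant = c("trucesmiles", "TS07"),
    inchikey = "DKFPBXQCCCIWLC-UHFFFAOYSA-N"),
  w22_anh_styrene = list(
    reagents = c("CC(=O)OC(C)=O", "C=Cc1ccccc1"),
    variant = c("cycloadd22", "W22_1"),
    inchikey = "UVGRBUMTKCGCPM-UHFFFAOYSA-N"),
  w22_acl_acrylate = list(
    reagents = c("CC(=O)Cl", "C=CC(=O)OC"),
    variant = c("cycloadd22", "W22_2"),
    inchikey = "ZBKTYQPZUVJWDQ-UHFFFAOYSA-N"),
  w42_anh_furan = list(
    reagents = c("CC(=O)OC(C)=O", "c1ccoc1"),
    variant = c("cycloadd42", "W42_1"),
    inchikey = "JUFJGAKFYJTINT-UHFFFAOYSA-N"),
  w42_anh_cyclopentadiene = list(
    reagents = c("CC(=O)OC(C)=O", "C1=CC=CC1"),
    variant = c("cycloadd42", "W42_3"),
    inchikey = "DQSAFYQNCMYZIK-UHFFFAOYSA-N"),
  w42_acl_nmepyrrole = list(
    reagents = c("CC(=O)Cl", "Cn1cccc1"),
    variant = c("cycloadd42", "W42_6"),
    inchikey = "UATJSVLUIDDHNK-UHFFFAOYSA-N"))

# frozen precursor-transform expectations (same oracle)
oracle_precursor <- list(
  acetoacetic = list(smiles = "CC(=O)CC(=O)O",
                     inchikey = "XFRBXZCBOYNMJP-UHFFFAOYSA-N"),
  benzoylacetic = list(smiles = "O=C(O)CC(=O)c1ccccc1",
                       inchikey = "XVDIUPDVIULPMF-UHFFFAOYSA-N"),
  double_motif = list(
    smiles = "OC(=O)CC(=O)CC(C)C(=O)CC(=O)O",
    inchikeys = c("VBPRYODZJFRDJB-UHFFFAOYSA-N",
                  "HZLINORBMCKVDE-UHFFFAOYSA-N")))

get_variant <- function(reaction_id, variant_id) {
  defn <- builtin_reaction(reaction_id)
  for (v in defn$variants) if (v$variant_id == variant_id) return(v)
  stop("no variant ", variant_id)
}

# Brute-force enumeration oracle: plain double loop over the full
# cross-product of the (already expanded) pools, ignoring the chunked
# streaming machinery; identity set keyed on InChIKey.
brute_force_inchikeys <- function(defn, pools) {
  keys <- character(0)
  for (v in defn$variants) {
    comp <- synthenum:::resolve_components(defn, v)
    pa <- pools[[comp[1]]]
    if (is.null(pa) || !nrow(pa)) next
    if (length(comp) == 1L) {
      for (i in seq_len(nrow(pa))) {
        prods <- apply_variant(v, pa$stripped_smiles[i])
        keys <- c(keys, smiles_inchikey(prods))
      }
    } else {
      pb <- pools[[comp[2]]]
      if (is.null(pb) || !nrow(pb)) next
      for (i in seq_len(nrow(pa))) {
        for (j in seq_len(nrow(pb))) {
          prods <- apply_variant(v, c(pa$stripped_smiles[i],
                                      pb$stripped_smiles[j]))
          keys <- c(keys, smiles_inchikey(prods))
        }
      }
    }
  }
  sort(unique(keys[!is.na(keys)]))
}
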