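# Physicochemical descriptors, druglikeness gating, QED and structural
# alerts.

#' Compute the descriptor block for molecules
#'
#' Molecular weight, Wildman-Crippen logP, Lipinski hydrogen-bond acceptor
#' (N+O) and donor (N/O bearing H) counts, rotatable bonds, topological
#' polar surface area, heavy-atom count, Fsp3, QED and the druglike verdict
#' of [druglike_gate()]. Deterministic and a pure function of the structure:
#' two SMILES of the same molecule give identical records.
#'
#' @param smiles character vector of SMILES.
#' @param hac_gate apply the heavy-atom cutoff inside the druglike verdict
#'   (default `TRUE`).
#' @return data frame with one row per molecule: `smiles`, `mw`, `clogp`,
#'   `hba`, `hbd`, `rotb`, `tpsa`, `hac`, `fsp3`, `qed`, `druglike`.
#' @export
#' @examples
#' compute_descriptors("c1ccccc1")
compute_descriptors <- function(smiles, hac_gate = TRUE) {
  stopifnot(is.character(smiles))
  d <- .ob_descriptors(smiles)
  if (any(!d$ok)) {
    stop("unparseable SMILES at position(s): ",
         paste(utils::head(which(!d$ok), 5), collapse = ", "), call. = FALSE)
  }
  alerts <- alert_hit_counts(smiles, "brenk")
  qed <- qed_score(mw = d$mw, clogp = d$clogp, hba = d$hba, hbd = d$hbd,
                   tpsa = d$tpsa, rotb = d$rotb, arom = d$arom_rings,
                   alerts = alerts)
  out <- data.frame(smiles = smiles, mw = d$mw, clogp = d$clogp,
                    hba = d$hba, hbd = d$hbd, rotb = d$rotb, tpsa = d$tpsa,
                    hac = d$hac, fsp3 = d$fsp3, qed = qed,
                    stringsAsFactors = FALSE)
  out$druglike <- druglike_gate(out, hac_gate = hac_gate)
  out
}

#' Lipinski + Veber druglikeness gate
#'
#' A record passes iff MW <= 500 Da, logP <= 5, HBA <= 10, HBD <= 5,
#' ROTB <= 10, TPSA <= 140 A^2 and (optionally) heavy atoms <= 38. The gate
#' is monotone: raising any descriptor never turns a failing record into a
#' passing one.
#'
#' @param rec data frame with columns `mw`, `clogp`, `hba`, `hbd`, `rotb`,
#'   `tpsa` and (if `hac_gate`) `hac`.
#' @param hac_gate include the 38-heavy-atom cutoff (default `TRUE`).
#' @return logical vector.
#' @export
druglike_gate <- function(rec, hac_gate = TRUE) {
  ok <- rec$mw <= 500 & rec$clogp <= 5 & rec$hba <= 10 & rec$hbd <= 5 &
    rec$rotb <= 10 & rec$tpsa <= 140
  if (hac_gate) ok <- ok & rec$hac <= 38
  ok
}

alert_catalog_files <- function() {
  c(pains_a = "pains_a.txt", pains_b = "pains_b.txt", pains_c = "pains_c.txt",
    brenk = "brenk_synthetic.txt", nih = "nih_synthetic.txt")
}

#' Load a packaged structural-alert catalog
#'
#' PAINS A/B/C are the published WEHI patterns; the Brenk-style and
#' NIH-style catalogs are curated approximations authored for this package
#' (their files carry a `_synthetic` label), covering the canonical motif
#' families of the original publications.
#'
#' @param catalog one of `"pains_a"`, `"pains_b"`, `"pains_c"`, `"brenk"`,
#'   `"nih"`.
#' @return data frame with columns `name` and `smarts`.
#' @export
alert_catalog <- function(catalog = names(alert_catalog_files())) {
  catalog <- match.arg(catalog)
  path <- system.file("extdata", "alerts", alert_catalog_files()[[catalog]],
                      package = "synthenum")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(name = vapply(f, `[[`, character(1), 1),
             smarts = vapply(f, `[[`, character(1), 2),
             stringsAsFactors = FALSE)
}

# cache compiled-catalog hit matrices are cheap; cache only the tables
.alert_cache <- new.env(parent = emptyenv())

alert_patterns <- function(catalog) {
  if (is.null(.alert_cache[[catalog]])) {
    .alert_cache[[catalog]] <- alert_catalog(catalog)
  }
  .alert_cache[[catalog]]
}

alert_hit_counts <- function(smiles, catalog) {
  pats <- alert_patterns(catalog)
  hits <- smarts_screen(smiles, pats$smarts)
  rowSums(hits, na.rm = TRUE)
}

#' Structural-alert flags
#'
#' Flags a molecule for each alert catalog: `TRUE` iff at least one pattern
#' of that catalog matches. The five flags are independent indicator
#' columns.
#'
#' @param smiles character vector of SMILES.
#' @return data frame with logical columns `pains_a`, `pains_b`, `pains_c`,
#'   `brenk`, `nih`.
#' @export
structural_alerts <- function(smiles) {
  stopifnot(is.character(smiles))
  bad <- is.na(smiles_canonical(smiles))
  if (any(bad)) {
    stop("unparseable SMILES at position(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(row.names = seq_along(smiles))
  for (cat in names(alert_catalog_files())) {
    out[[cat]] <- alert_hit_counts(smiles, cat) > 0L
  }
  out
}

#' Alert rates of a library
#'
#' @param flags data frame of alert indicator columns
#'   ([structural_alerts()] output).
#' @return data frame with one row per catalog: `catalog`, `hits`, `n`,
#'   `percent`.
#' @export
alert_rates <- function(flags) {
  stopifnot(nrow(flags) > 0L)
  data.frame(
    catalog = names(flags),
    hits = vapply(flags, sum, integer(1)),
    n = nrow(flags),
    percent = 100 * vapply(flags, mean, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Asymmetric double-sigmoid desirability functions with the published QED
# parameterization (a, b, c, d, e, f, dmax per descriptor).
.qed_ads_params <- list(
  mw     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353,
             49.22325677, 65.37051707, 104.9805561),
  clogp  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897,
             0.822739154, 0.576295591, 131.3186604),
  hba    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202,
             0.290141953, 1.300669958, 148.7763046),
  hbd    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001,
             0.713820843, 0.920922555, 258.1632616),
  tpsa   = c(1.876861559, 125.2232657, 62.90773554, 87.83366614,
             12.01999824, 28.51324732, 104.5686167),
  rotb   = c(0.01, 272.4121427, 2.55837997, 1.565547684,
             1.271567166, 2.758063707, 105.4420403),
  arom   = c(3.21778897, 957.7374108, 2.274627939, 0.000000001,
             1.317690384, 0.375760881, 312.337261),
  alerts = c(0.01, 1199.094025, -0.09002883, 0.000000001,
             0.185904477, 0.875193782, 417.725314))

.qed_weights <- c(mw = 0.66, clogp = 0.46, hba = 0.05, hbd = 0.61,
                  tpsa = 0.06, rotb = 0.65, arom = 0.48, alerts = 0.95)

qed_ads <- function(x, p) {
  d <- p[1] + p[2] / (1 + exp(-(x - p[3] + p[4] / 2) / p[5])) *
    (1 - 1 / (1 + exp(-(x - p[3] - p[4] / 2) / p[6])))
  pmax(d / p[7], 0.003)
}

#' Quantitative estimate of druglikeness
#'
#' Weighted QED: the geometric weighted mean of eight desirability
#' transforms (molecular weight, logP, acceptors, donors, TPSA, rotatable
#' bonds, aromatic rings, structural alerts) using the published asymmetric
#' double-sigmoid parameters and weights. The alert term counts hits of the
#' packaged Brenk-style catalog.
#'
#' @param mw,clogp,hba,hbd,tpsa,rotb,arom,alerts numeric vectors of the
#'   eight underlying descriptors.
#' @return numeric vector of QED values in `[0, 1]`.
#' @export
qed_score <- function(mw, clogp, hba, hbd, tpsa, rotb, arom, alerts) {
  vals <- list(mw = mw, clogp = clogp, hba = hba, hbd = hbd, tpsa = tpsa,
               rotb = rotb, arom = arom, alerts = alerts)
  acc <- 0
  for (nm in names(vals)) {
    acc <- acc + .qed_weights[[nm]] *
      log(qed_ads(vals[[nm]], .qed_ads_params[[nm]]))
  }
  exp(acc / sum(.qed_weights))
}
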