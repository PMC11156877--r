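# Building-block catalogs: purchasability tiers and synthon-compatibility
# filtering.

#' Purchasability tiers
#'
#' The five availability/price groups of commercial building-block catalogs,
#' from the best-priced in-stock group (BB50) to expensive make-on-demand
#' stock (BB10).
#'
#' @return character vector of tier tokens, cheapest first.
#' @export
bb_tiers <- function() c("BB50", "BB40", "BB30", "BB20", "BB10")

#' Is a tier "cheap"?
#'
#' The cheap category covers the affordable in-stock groups BB50 and BB40;
#' everything else (BB30, BB20, BB10) is expensive.
#'
#' @param tier character vector of tier tokens.
#' @return logical vector.
#' @export
#' @examples
#' classify_cheap(c("BB50", "BB30"))
classify_cheap <- function(tier) {
  tier <- match.arg(tier, bb_tiers(), several.ok = TRUE)
  tier %in% c("BB50", "BB40")
}

#' Assemble a building-block catalog
#'
#' @param smiles character vector of SMILES strings.
#' @param vendor_id character vector of catalog identifiers.
#' @param tier character vector of tier tokens (see [bb_tiers()]).
#' @return data frame of class `bb_catalog` with columns `smiles`,
#'   `vendor_id`, `tier`, `heavy_atoms`. A `vendor_id` listed under several
#'   tiers keeps its cheapest tier. Heavy atoms are counted on the
#'   salt-stripped structure.
#' @export
bb_catalog <- function(smiles, vendor_id, tier) {
  stopifnot(length(smiles) == length(vendor_id),
            length(smiles) == length(tier),
            all(tier %in% bb_tiers()))
  if (anyDuplicated(vendor_id)) {
    rank <- match(tier, bb_tiers())
    ord <- order(match(vendor_id, unique(vendor_id)), rank)
    keep <- ord[!duplicated(vendor_id[ord])]
    keep <- sort(keep)
    smiles <- smiles[keep]; vendor_id <- vendor_id[keep]; tier <- tier[keep]
  }
  stripped <- strip_salts(smiles)
  out <- data.frame(smiles = smiles, vendor_id = vendor_id, tier = tier,
                    heavy_atoms = heavy_atom_count(stripped),
                    stringsAsFactors = FALSE)
  out$stripped_smiles <- stripped
  class(out) <- c("bb_catalog", class(out))
  out
}

#' Read a building-block catalog file
#'
#' One record per line, tab-separated: SMILES, vendor id, tier token.
#'
#' @param path file path.
#' @return a [bb_catalog()] data frame.
#' @export
read_catalog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(bb_catalog(character(0), character(0), character(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 3L)
  if (length(bad)) {
    stop("catalog line ", bad[1], ": expected 3 tab-separated fields",
         call. = FALSE)
  }
  bb_catalog(vapply(f, `[[`, character(1), 1),
             vapply(f, `[[`, character(1), 2),
             vapply(f, `[[`, character(1), 3))
}

#' Select catalog blocks compatible with a synthon
#'
#' A block is accepted iff its salt-stripped structure matches at least one
#' inclusion pattern of the synthon, matches none of the synthon-specific
#' exclusions, matches none of the global exclusions, and has at most
#' `max_heavy_atoms` heavy atoms. Input order is preserved; unparseable
#' SMILES are skipped with a message, never an error.
#'
#' @param blocks a [bb_catalog()] data frame.
#' @param synthon a [synthon_definition()].
#' @param global_exclusions character vector of SMARTS applied to all
#'   reagents of the reaction.
#' @param max_heavy_atoms size cap in heavy atoms (default 40).
#' @return data frame with the accepted rows of `blocks` plus `synthon_id`,
#'   `symmetric` (symmetric-reagent detector fired) and a `match_sites` list
#'   column holding one integer vector of atom indices per distinct
#'   embedding of the inclusion patterns.
#' @export
filter_catalog <- function(blocks, synthon, global_exclusions = character(0),
                           max_heavy_atoms = 40L) {
  stopifnot(inherits(synthon, "synthon_definition"))
  n <- nrow(blocks)
  if (n == 0L) {
    out <- blocks[integer(0), , drop = FALSE]
    out$synthon_id <- character(0)
    out$symmetric <- logical(0)
    out$match_sites <- list()
    return(out)
  }
  smi <- blocks$stripped_smiles %||% strip_salts(blocks$smiles)
  parseable <- !is.na(smi)
  if (any(!parseable)) {
    message(sum(!parseable), " block(s) with unparseable SMILES skipped")
  }
  hac <- blocks$heavy_atoms %||% heavy_atom_count(smi)
  keep <- parseable & !is.na(hac) & hac <= max_heavy_atoms
  # screens are vectorized over the surviving blocks
  idx <- which(keep)
  if (length(idx)) {
    if (length(synthon$exclusion_patterns)) {
      hit <- smarts_screen(smi[idx], synthon$exclusion_patterns)
      keep[idx[rowSums(hit, na.rm = TRUE) > 0L]] <- FALSE
    }
  }
  idx <- which(keep)
  if (length(idx) && length(global_exclusions)) {
    hit <- smarts_screen(smi[idx], unname(global_exclusions))
    keep[idx[rowSums(hit, na.rm = TRUE) > 0L]] <- FALSE
  }
  idx <- which(keep)
  sites <- vector("list", n)
  sym <- rep(FALSE, n)
  for (i in idx) {
    ms <- list()
    for (p in synthon$inclusion_patterns) {
      ms <- c(ms, smarts_match(smi[i], p, addh = TRUE))
    }
    if (!length(ms)) { keep[i] <- FALSE; next }
    sites[[i]] <- unique(ms)
    if (!is.null(synthon$symmetric_pattern)) {
      sym[i] <- length(smarts_match(smi[i], synthon$symmetric_pattern,
                                    addh = TRUE)) > 0L
    }
  }
  idx <- which(keep)
  out <- blocks[idx, , drop = FALSE]
  rownames(out) <- NULL
  out$synthon_id <- rep(synthon$synthon_id, length(idx))
  out$symmetric <- sym[idx]
  out$match_sites <- sites[idx]
  out
}

#' Expand a precursor block into reactive reagents
#'
#' Applies a one-component precursor transform (for instance beta-keto acid
#' to dioxinone) to a purchasable block, returning the canonical SMILES of
#' every derived reagent; empty when the transform does not apply.
#'
#' @param smiles a single block SMILES.
#' @param precursor_transform one-component mapped transform SMARTS.
#' @return character vector of canonical product SMILES.
#' @export
#' @examples
#' \dontrun{
#' apply_precursor("CC(=O)CC(=O)O",
#'   builtin_reaction("betaketoimides")$synthons[[2]]$precursor_transform)
#' }
apply_precursor <- function(smiles, precursor_transform) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  apply_transform(precursor_transform, smiles)
}
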