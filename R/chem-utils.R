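#' Canonical SMILES
#'
#' Canonicalizes SMILES strings with Open Babel. Unparseable inputs yield
#' `NA_character_`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
#' @examples
#' smiles_canonical(c("OCC", "C1=CC=CC=C1"))
smiles_canonical <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  out <- .ob_cansmi(smiles)
  out[!nzchar(out)] <- NA_character_
  out
}

#' Standard InChIKey
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of 27-character standard InChIKeys, `NA` where
#'   parsing failed.
#' @export
smiles_inchikey <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  out <- .ob_inchikey(smiles)
  out[!nzchar(out)] <- NA_character_
  out
}

#' Validate SMARTS patterns
#'
#' @param smarts character vector of SMARTS patterns.
#' @return logical vector, `TRUE` where the pattern compiles.
#' @export
smarts_is_valid <- function(smarts) {
  stopifnot(is.character(smarts))
  if (length(smarts) == 0L) return(logical(0))
  .ob_smarts_valid(vapply(smarts, rewrite_mapped_h, character(1)))
}

#' Substructure screen
#'
#' Matches each molecule against each pattern. Molecules are matched with
#' explicit hydrogens so that patterns written with explicit `[#1]` atoms
#' (the published PAINS dialect) behave as intended.
#'
#' @param smiles character vector of molecules.
#' @param smarts character vector of patterns.
#' @param addh add explicit hydrogens before matching (default `TRUE`).
#' @return logical matrix, molecules in rows, patterns in columns; `NA` rows
#'   for unparseable molecules.
#' @export
smarts_screen <- function(smiles, smarts, addh = TRUE) {
  stopifnot(is.character(smiles), is.character(smarts))
  if (length(smiles) == 0L || length(smarts) == 0L) {
    return(matrix(logical(0), nrow = length(smiles), ncol = length(smarts)))
  }
  .ob_screen(smiles, vapply(smarts, rewrite_mapped_h, character(1)), addh)
}

#' Heavy-atom count
#'
#' @param smiles character vector of SMILES.
#' @return integer vector of heavy (non-hydrogen) atom counts, `NA` on
#'   parse failure.
#' @export
heavy_atom_count <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(integer(0))
  d <- .ob_descriptors(smiles)
  d$hac
}

#' Keep the largest organic fragment
#'
#' Salt/solvate stripping: retains the connected fragment with the most heavy
#' atoms (ties resolved by lexicographically smallest canonical SMILES).
#'
#' @param smiles character vector of SMILES.
#' @return canonical SMILES of the largest fragment; `NA` on parse failure.
#' @export
strip_salts <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  out <- .ob_largest_fragment(smiles)
  out[!nzchar(out)] <- NA_character_
  out
}

# Open Babel's SMARTS parser rejects mapped bare hydrogens ("[H:9]"); the
# equivalent element form "[#1:9]" is accepted. Registry strings stay
# verbatim; the rewrite happens only on the way into the matcher.
rewrite_mapped_h <- function(smarts) {
  gsub("\\[H(:[0-9]+)\\]", "[#1\\1]", smarts)
}

# Perceived molecular graph (kekulized bond orders) used by the transform
# engine, scaffold pruning and fingerprints.
mol_graph <- function(smiles, addh = FALSE) {
  g <- .ob_mol_graph(smiles, addh)
  if (!isTRUE(g$ok)) return(NULL)
  g
}

# Unique SMARTS matches as a list of integer vectors in pattern-atom order.
smarts_match <- function(smiles, smarts, addh = FALSE) {
  .ob_match(smiles, rewrite_mapped_h(smarts), addh)
}
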