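# Hashed circular (Morgan-style) fingerprints and MaxMin diversity picking.
# The fingerprint is a faithful radius-2 ECFP-type algorithm but is not
# bit-compatible with other toolkits' implementations; it is used only for
# intra-package diversity distances.

# Deterministic integer hashing on doubles below 2^53, reduced mod 2^31-1.
.hash_mix <- function(codes) {
  h <- 17
  for (x in codes) {
    h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  }
  h
}

#' Circular fingerprint bit set
#'
#' Hashed circular fingerprint of radius `radius` folded to `nbits` bits.
#' Atom invariants: element, heavy degree, total hydrogen count, formal
#' charge, ring membership, aromaticity.
#'
#' @param smiles a single SMILES string.
#' @param radius neighborhood radius (default 2, the ECFP4 equivalent).
#' @param nbits fold size (default 2048).
#' @return sorted integer vector of set bits (0-based).
#' @export
ecfp_bits <- function(smiles, radius = 2L, nbits = 2048L) {
  g <- mol_graph(smiles, addh = FALSE)
  if (is.null(g)) stop("unparseable SMILES: ", smiles, call. = FALSE)
  a <- g$atoms
  n <- nrow(a)
  if (n == 0L) return(integer(0))
  b <- g$bonds
  nbrs <- vector("list", n)
  if (nrow(b)) {
    for (e in seq_len(nrow(b))) {
      nbrs[[b$from[e]]] <- rbind(nbrs[[b$from[e]]], c(b$to[e], b$order[e]))
      nbrs[[b$to[e]]] <- rbind(nbrs[[b$to[e]]], c(b$from[e], b$order[e]))
    }
  }
  code <- vapply(seq_len(n), function(i) {
    .hash_mix(c(a$z[i], a$degree[i], a$nh[i], a$charge[i] + 10,
                as.integer(a$in_ring[i]), as.integer(a$arom[i])))
  }, numeric(1))
  bits <- code
  for (r in seq_len(radius)) {
    nxt <- vapply(seq_len(n), function(i) {
      if (is.null(nbrs[[i]])) return(.hash_mix(c(r, code[i])))
      env <- nbrs[[i]]
      pairs <- env[order(env[, 2], code[env[, 1]]), , drop = FALSE]
      .hash_mix(c(r, code[i], as.vector(t(cbind(pairs[, 2],
                                                code[pairs[, 1]])))))
    }, numeric(1))
    code <- nxt
    bits <- c(bits, code)
  }
  sort(unique(as.integer(bits %% nbits)))
}

#' Tanimoto similarity of two bit sets
#'
#' @param a,b integer vectors of set bits.
#' @return Tanimoto coefficient in `[0, 1]`; two empty sets count as
#'   identical.
#' @export
fp_tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' MaxMin diversity selection
#'
#' Greedy MaxMin: seed with a deterministic pseudo-random first pick, then
#' repeatedly add the candidate whose minimum Tanimoto distance
#' (1 - similarity) to the selected set is largest. Ties break on the lowest
#' index, so the pick is reproducible.
#'
#' @param fps list of fingerprint bit sets ([ecfp_bits()]).
#' @param k number of items to select (`<= length(fps)`).
#' @param seed integer seed for the starting item.
#' @return integer vector of selected indices, in pick order.
#' @export
maxmin_pick <- function(fps, k, seed = 1L) {
  n <- length(fps)
  stopifnot(k >= 1L, k <= n)
  first <- (as.integer(seed) %% n) + 1L
  picked <- first
  if (k == 1L) return(picked)
  mind <- vapply(seq_len(n), function(i)
    1 - fp_tanimoto(fps[[i]], fps[[first]]), numeric(1))
  for (step in seq_len(k - 1L)) {
    mind[picked] <- -Inf
    cand <- which.max(mind)
    picked <- c(picked, cand)
    if (length(picked) == k) break
    d <- vapply(seq_len(n), function(i)
      1 - fp_tanimoto(fps[[i]], fps[[cand]]), numeric(1))
    mind <- pmin(mind, d)
  }
  picked
}
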