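# Combinatorial enumeration of reaction products with provenance and
# purchasability coding.

#' Enumeration options
#'
#' @param chunk_size reagent pools are processed in chunks of up to this many
#'   blocks (default 2000); the product set is invariant to the choice.
#' @param dedup_scope `"per_reaction"` (default) removes InChIKey duplicates
#'   across all variants of the definition being enumerated; `"global"` is
#'   identical within one call and is intended for callers that pool several
#'   reactions and deduplicate with [dedup_products()].
#' @param max_products optional cap on the number of emitted products.
#' @param seed integer seed for any sampling step (e.g. [curation_sample()]).
#' @return list of class `enumeration_options`.
#' @export
enumeration_options <- function(chunk_size = 2000L,
                                dedup_scope = c("per_reaction", "global"),
                                max_products = NULL, seed = 1L) {
  chunk_size <- as.integer(chunk_size)
  stopifnot(chunk_size >= 1L)
  structure(list(chunk_size = chunk_size,
                 dedup_scope = match.arg(dedup_scope),
                 max_products = max_products,
                 seed = as.integer(seed)),
            class = "enumeration_options")
}

#' Apply one reaction variant to a reagent tuple
#'
#' @param variant a [reaction_variant()].
#' @param reagents character vector of reagent SMILES, one per component in
#'   template order.
#' @return character vector of distinct canonical product SMILES.
#' @export
apply_variant <- function(variant, reagents) {
  stopifnot(inherits(variant, "reaction_variant"))
  if (length(reagents) != length(variant$component_tags)) {
    stop("variant '", variant$variant_id, "' expects ",
         length(variant$component_tags), " reagent(s), got ",
         length(reagents), call. = FALSE)
  }
  apply_transform(variant$transform, reagents)
}

#' Purchasability code of a product
#'
#' Code `"1"`: every reagent is BB50. Code `"2"`: every reagent is cheap
#' (BB50/BB40) with at least one BB40. Everything else: `"expensive"`.
#'
#' @param reagent_tiers character vector of tier tokens, one per reagent.
#' @return `"1"`, `"2"` or `"expensive"`.
#' @export
#' @examples
#' assign_purchasability(c("BB50", "BB40"))
assign_purchasability <- function(reagent_tiers) {
  stopifnot(length(reagent_tiers) >= 1L,
            all(reagent_tiers %in% bb_tiers()))
  if (all(reagent_tiers == "BB50")) return("1")
  if (all(reagent_tiers %in% c("BB50", "BB40"))) return("2")
  "expensive"
}

# Resolve the non-precursor synthon owning each component tag.
resolve_components <- function(defn, variant) {
  vapply(variant$component_tags, function(tg) {
    owner <- vapply(defn$synthons, function(s)
      !s$is_precursor && tg %in% s$reaction_tags, logical(1))
    if (sum(owner) != 1L) {
      stop("tag '", tg, "' does not resolve to exactly one synthon",
           call. = FALSE)
    }
    defn$synthons[[which(owner)]]$synthon_id
  }, character(1))
}

#' Build reagent pools for a reaction from a catalog
#'
#' Filters the catalog for every synthon of the definition. Precursor
#' synthons are expanded with their one-component transform and the derived
#' reagents (inheriting the source block's vendor id and tier) are appended
#' to the pool of the non-precursor synthon sharing their reaction tag.
#'
#' @param defn a [reaction_definition()].
#' @param blocks a [bb_catalog()].
#' @param max_heavy_atoms size cap applied during filtering.
#' @return named list, synthon id to filtered pool data frame.
#' @export
build_pools <- function(defn, blocks, max_heavy_atoms = 40L) {
  pools <- list()
  for (s in defn$synthons) {
    if (s$is_precursor) next
    pools[[s$synthon_id]] <- filter_catalog(
      blocks, s, defn$global_exclusions, max_heavy_atoms)
  }
  for (s in defn$synthons) {
    if (!s$is_precursor) next
    hits <- filter_catalog(blocks, s, defn$global_exclusions,
                           max_heavy_atoms)
    if (!nrow(hits)) next
    target_id <- NULL
    for (t in defn$synthons) {
      if (!t$is_precursor && any(s$reaction_tags %in% t$reaction_tags)) {
        target_id <- t$synthon_id
        break
      }
    }
    if (is.null(target_id)) next
    target <- defn$synthons[[which(vapply(defn$synthons, function(t)
      t$synthon_id == target_id, logical(1)))]]
    derived <- list()
    for (i in seq_len(nrow(hits))) {
      prods <- apply_transform(s$precursor_transform,
                               hits$stripped_smiles[i] %||% hits$smiles[i])
      for (p in prods) {
        derived[[length(derived) + 1L]] <- data.frame(
          smiles = p, vendor_id = hits$vendor_id[i], tier = hits$tier[i],
          stringsAsFactors = FALSE)
      }
    }
    if (!length(derived)) next
    dd <- do.call(rbind, derived)
    dcat <- bb_catalog(dd$smiles, dd$vendor_id, dd$tier)
    dpool <- filter_catalog(dcat, target, defn$global_exclusions,
                            max_heavy_atoms)
    pools[[target_id]] <- rbind_pools(pools[[target_id]], dpool)
  }
  pools
}

rbind_pools <- function(a, b) {
  if (is.null(a) || nrow(a) == 0L) return(b)
  if (is.null(b) || nrow(b) == 0L) return(a)
  cols <- intersect(names(a), names(b))
  out <- rbind(a[, cols, drop = FALSE], b[, cols, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Enumerate the products of a reaction definition
#'
#' Runs every variant over the cross-product of its reagent pools, chunked
#' by `opts$chunk_size`, and emits each product once within the
#' deduplication scope (keyed on InChIKey). Multi-embedding reagents yield
#' one raw product per embedding before deduplication; symmetric reagents
#' therefore contribute each product once.
#'
#' @param defn a [reaction_definition()].
#' @param pools named list, synthon id to pool data frame (see
#'   [build_pools()]); every synthon referenced by a variant must be
#'   present.
#' @param opts an [enumeration_options()].
#' @return data frame of class `enumerated_products` with columns `smiles`,
#'   `product_id`, `inchikey`, `reaction_id`, `variant_id`, `reagent_a`,
#'   `reagent_b` (NA for one-component reactions), `purchasability`.
#' @export
enumerate_products <- function(defn, pools,
                               opts = enumeration_options()) {
  stopifnot(inherits(defn, "reaction_definition"))
  rows <- list()
  seen <- new.env(parent = emptyenv())
  capped <- FALSE
  for (v in defn$variants) {
    comp_ids <- resolve_components(defn, v)
    comp_pools <- lapply(comp_ids, function(id) pools[[id]])
    empty <- vapply(comp_pools, function(p) is.null(p) || nrow(p) == 0L,
                    logical(1))
    if (any(empty)) {
      warning("variant '", v$variant_id, "': empty pool for synthon '",
              comp_ids[empty][1], "'", call. = FALSE)
      next
    }
    arity <- length(comp_ids)
    chunks_a <- split(seq_len(nrow(comp_pools[[1]])),
                      ceiling(seq_len(nrow(comp_pools[[1]])) /
                              opts$chunk_size))
    for (ch in chunks_a) {
      idx_b <- if (arity == 2L) seq_len(nrow(comp_pools[[2]])) else NA_integer_
      for (ia in ch) {
        for (ib in idx_b) {
          if (capped) break
          smi_a <- comp_pools[[1]]$stripped_smiles[ia] %||%
            comp_pools[[1]]$smiles[ia]
          reag <- smi_a
          tiers <- comp_pools[[1]]$tier[ia]
          ids <- comp_pools[[1]]$vendor_id[ia]
          if (arity == 2L) {
            smi_b <- comp_pools[[2]]$stripped_smiles[ib] %||%
              comp_pools[[2]]$smiles[ib]
            reag <- c(reag, smi_b)
            tiers <- c(tiers, comp_pools[[2]]$tier[ib])
            ids <- c(ids, comp_pools[[2]]$vendor_id[ib])
          }
          prods <- apply_variant(v, reag)
          if (!length(prods)) next
          iks <- smiles_inchikey(prods)
          ok <- !is.na(iks)
          prods <- prods[ok]; iks <- iks[ok]
          multi <- length(prods) > 1L
          for (k in seq_along(prods)) {
            if (!is.null(seen[[iks[k]]])) next
            assign(iks[k], TRUE, envir = seen)
            pid <- paste(c(defn$reaction_id, v$variant_id, ids), collapse = "_")
            if (multi) pid <- paste0(pid, "_", k)
            rows[[length(rows) + 1L]] <- data.frame(
              smiles = prods[k], product_id = pid, inchikey = iks[k],
              reaction_id = defn$reaction_id, variant_id = v$variant_id,
              reagent_a = ids[1],
              reagent_b = if (arity == 2L) ids[2] else NA_character_,
              purchasability = assign_purchasability(tiers),
              stringsAsFactors = FALSE)
            if (!is.null(opts$max_products) &&
                length(rows) >= opts$max_products) {
              capped <- TRUE
              break
            }
          }
        }
        if (capped) break
      }
      if (capped) break
    }
    if (capped) break
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    smiles = character(0), product_id = character(0),
    inchikey = character(0), reaction_id = character(0),
    variant_id = character(0), reagent_a = character(0),
    reagent_b = character(0), purchasability = character(0),
    stringsAsFactors = FALSE)
  class(out) <- c("enumerated_products", class(out))
  out
}

#' Deduplicate products across reactions
#'
#' Global-identity deduplication on InChIKey for pooled enumerations; the
#' first occurrence wins.
#'
#' @param products data frame with an `inchikey` column.
#' @return the data frame without InChIKey duplicates.
#' @export
dedup_products <- function(products) {
  products[!duplicated(products$inchikey), , drop = FALSE]
}

#' Diversity pick of representative products
#'
#' MaxMin selection of `k` compounds under Tanimoto distance on hashed
#' radius-2 (ECFP4-style) 2048-bit circular fingerprints: the first compound
#' is drawn with the seed, then each pick maximizes the minimum distance to
#' the already-selected set. Used to extract a representative sample for
#' visual curation by chemists.
#'
#' @param products data frame with a `smiles` column (an
#'   `enumerated_products` frame works as is).
#' @param k number of compounds to select.
#' @param seed integer seed controlling the (otherwise arbitrary) starting
#'   compound.
#' @return the selected rows of `products`.
#' @export
curation_sample <- function(products, k, seed = 1L) {
  n <- nrow(products)
  if (k > n) {
    warning("k = ", k, " exceeds the ", n, " available products; ",
            "returning all", call. = FALSE)
    return(products)
  }
  fps <- lapply(products$smiles, ecfp_bits)
  pick <- maxmin_pick(fps, k, seed = seed)
  products[pick, , drop = FALSE]
}
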