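# Mapped-reaction-SMARTS transform engine.
#
# A transform is "reagent templates >> product template" with atom maps.
# Reagent templates are matched with Open Babel on hydrogen-explicit graphs
# (so templates that reference explicit [H] atoms or allow [*,H] R-groups
# behave as printed). Products are assembled by graph grafting:
#   * product-template atoms with a map inherit the matched reagent atom and
#     every substituent reachable through unmatched atoms;
#   * matched-but-unmapped reagent atoms are consumed (leaving groups);
#   * bonds between mapped atoms are defined solely by the product template;
#   * hydrogen counts rebalance against the valence change at each mapped
#     atom, with explicit Hn specs in the product template taking precedence.
# The assembled graph round-trips through a V2000 MOL block and Open Babel
# for sanitization, aromaticity perception and canonical SMILES.

REACTION_ARROW <- "⨠"  # typographic arrow variant, normalized to ">>"

normalize_transform <- function(transform) {
  gsub(REACTION_ARROW, ">>", transform, fixed = TRUE)
}

# Split a SMARTS/SMILES string on dots at bracket depth zero.
split_components <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  cut <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "[") depth <- depth + 1L
    else if (chars[i] == "]") depth <- depth - 1L
    else if (chars[i] == "." && depth == 0L) cut <- c(cut, i)
  }
  if (length(cut) == 0L) return(s)
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  vapply(seq_along(starts), function(k)
    substr(s, starts[k], ends[k]), character(1))
}

# Atom-map class for every pattern atom of a reagent template, in the order
# Open Babel reports match indices (its pattern-atom order). Atoms inside
# recursive $(...) environments belong to their enclosing atom and are not
# counted. Unmapped atoms get class 0.
smarts_pattern_maps <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  maps <- integer(0)
  i <- 1L
  organic1 <- c("B", "C", "N", "O", "S", "P", "F", "I",
                "b", "c", "n", "o", "s", "p", "a", "A", "*")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      depth <- 1L
      j <- i + 1L
      while (j <= n && depth > 0L) {
        if (chars[j] == "[") depth <- depth + 1L
        else if (chars[j] == "]") depth <- depth - 1L
        j <- j + 1L
      }
      content <- substr(s, i + 1L, j - 2L)
      m <- regmatches(content, regexpr(":[0-9]+$", content))
      maps <- c(maps, if (length(m)) as.integer(sub(":", "", m)) else 0L)
      i <- j
    } else if (ch == "C" && i < n && chars[i + 1L] == "l") {
      maps <- c(maps, 0L); i <- i + 2L
    } else if (ch == "B" && i < n && chars[i + 1L] == "r") {
      maps <- c(maps, 0L); i <- i + 2L
    } else if (ch %in% organic1) {
      maps <- c(maps, 0L); i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  maps
}

# Parse a product template (Kekule SMILES with atom maps and wildcards) into
# atom and bond tables. Mapped atoms whose bracket body is not a plain
# element spec (wildcards, comma lists, recursive environments) are treated
# as placeholders to be filled from the matched reagent atom.
parse_product_template <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  elem <- character(0); map <- integer(0); hcount <- integer(0)
  charge <- integer(0); frag <- integer(0)
  b_from <- integer(0); b_to <- integer(0); b_order <- integer(0)
  prev <- NA_integer_
  pending <- NA_integer_
  stack <- integer(0)
  rings <- list()
  fragment <- 1L
  organic1 <- c("B", "C", "N", "O", "S", "P", "F", "I")

  add_atom <- function(e, mp, hc, chg) {
    elem <<- c(elem, e); map <<- c(map, mp)
    hcount <<- c(hcount, hc); charge <<- c(charge, chg)
    frag <<- c(frag, fragment)
    idx <- length(elem)
    if (!is.na(prev)) {
      b_from <<- c(b_from, prev); b_to <<- c(b_to, idx)
      b_order <<- c(b_order, if (is.na(pending)) 1L else pending)
    }
    pending <<- NA_integer_
    prev <<- idx
    idx
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      depth <- 1L; j <- i + 1L
      while (j <= n && depth > 0L) {
        if (chars[j] == "[") depth <- depth + 1L
        else if (chars[j] == "]") depth <- depth - 1L
        j <- j + 1L
      }
      content <- substr(s, i + 1L, j - 2L)
      mp <- 0L
      mm <- regmatches(content, regexpr(":[0-9]+$", content))
      if (length(mm)) {
        mp <- as.integer(sub(":", "", mm))
        content <- sub(":[0-9]+$", "", content)
      }
      spec <- regmatches(content,
        regexec("^([A-Z][a-z]?)(H([0-9]*))?([+-][0-9]*)?$", content))[[1]]
      if (content == "#1") {
        add_atom("H", mp, NA_integer_, 0L)
      } else if (length(spec)) {
        hc <- if (nzchar(spec[3])) {
          if (nzchar(spec[4])) as.integer(spec[4]) else 1L
        } else NA_integer_
        chg <- 0L
        if (nzchar(spec[5])) {
          sgn <- if (substr(spec[5], 1, 1) == "+") 1L else -1L
          num <- substr(spec[5], 2, nchar(spec[5]))
          chg <- sgn * (if (nzchar(num)) as.integer(num) else 1L)
        }
        add_atom(spec[2], mp, hc, chg)
      } else {
        # wildcard / comma list / recursive body: placeholder for the
        # matched reagent atom
        if (mp == 0L) {
          stop("product template atom [", content,
               "] is neither a concrete element nor mapped", call. = FALSE)
        }
        add_atom(NA_character_, mp, NA_integer_, 0L)
      }
      i <- j
    } else if (ch == "C" && i < n && chars[i + 1L] == "l") {
      add_atom("Cl", 0L, NA_integer_, 0L); i <- i + 2L
    } else if (ch == "B" && i < n && chars[i + 1L] == "r") {
      add_atom("Br", 0L, NA_integer_, 0L); i <- i + 2L
    } else if (ch %in% organic1) {
      add_atom(ch, 0L, NA_integer_, 0L); i <- i + 1L
    } else if (ch == "=") {
      pending <- 2L; i <- i + 1L
    } else if (ch == "#") {
      pending <- 3L; i <- i + 1L
    } else if (ch == "-") {
      pending <- 1L; i <- i + 1L
    } else if (ch %in% as.character(0:9)) {
      key <- ch
      if (!is.null(rings[[key]])) {
        open <- rings[[key]]
        ord <- if (!is.na(pending)) pending
               else if (!is.na(open$order)) open$order else 1L
        b_from <- c(b_from, open$atom); b_to <- c(b_to, prev)
        b_order <- c(b_order, ord)
        rings[[key]] <- NULL
      } else {
        rings[[key]] <- list(atom = prev, order = pending)
      }
      pending <- NA_integer_
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      fragment <- fragment + 1L
      i <- i + 1L
    } else {
      stop("unsupported character '", ch, "' in product template: ", s,
           call. = FALSE)
    }
  }
  if (length(rings)) stop("unclosed ring bond in product template: ", s,
                          call. = FALSE)
  list(
    atoms = data.frame(elem = elem, map = map, hcount = hcount,
                       charge = charge, frag = frag,
                       stringsAsFactors = FALSE),
    bonds = data.frame(from = b_from, to = b_to, order = b_order)
  )
}

# Minimal V2000 MOL block from atom/bond tables (zero coordinates; Open
# Babel re-perceives aromaticity and implicit hydrogens on read).
graph_to_molblock <- function(elem, charge, from, to, order) {
  na <- length(elem); nb <- length(from)
  header <- c("", " synthenum", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, elem)
  bonds <- if (nb > 0) sprintf("%3d%3d%3d  0", from, to, order) else character(0)
  chg <- which(charge != 0L)
  chg_lines <- if (length(chg)) {
    vapply(chg, function(k) sprintf("M  CHG  1 %3d %3d", k, charge[k]),
           character(1))
  } else character(0)
  paste(c(header, atoms, bonds, chg_lines, "M  END"), collapse = "\n")
}

# Parse and sanity-check a transform once; reused across reagent tuples.
compile_transform <- function(transform) {
  transform <- normalize_transform(transform)
  sides <- strsplit(transform, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    stop("transform must contain exactly one '>>': ", transform, call. = FALSE)
  }
  reagent_templates <- split_components(sides[1])
  pattern_maps <- lapply(reagent_templates, smarts_pattern_maps)
  ok <- smarts_is_valid(reagent_templates)
  if (!all(ok)) {
    stop("unparseable reagent template: ", reagent_templates[!ok][1],
         call. = FALSE)
  }
  product <- parse_product_template(sides[2])
  reagent_maps <- sort(unique(unlist(pattern_maps)))
  reagent_maps <- reagent_maps[reagent_maps > 0L]
  product_maps <- sort(unique(product$atoms$map))
  product_maps <- product_maps[product_maps > 0L]
  orphan <- setdiff(product_maps, reagent_maps)
  if (length(orphan)) {
    stop("product atom map(s) ", paste(orphan, collapse = ", "),
         " absent from the reagent side", call. = FALSE)
  }
  list(reagent_templates = reagent_templates, pattern_maps = pattern_maps,
       product = product, arity = length(reagent_templates))
}

# Assemble the product graph for one combination of matches.
# graphs:  list of mol_graph() results (H-explicit), one per component
# matches: list of integer vectors (molecule atom idx in pattern-atom order)
# Returns canonical SMILES of the largest product fragment, or NA.
graft_product <- function(ct, graphs, matches) {
  patoms <- ct$product$atoms
  pbonds <- ct$product$bonds
  np <- nrow(patoms)

  # resolve mapped template atoms to (component, reagent atom)
  src_comp <- rep(NA_integer_, np)
  src_atom <- rep(NA_integer_, np)
  for (ci in seq_along(graphs)) {
    pm <- ct$pattern_maps[[ci]]
    mi <- matches[[ci]]
    for (k in which(pm > 0L)) {
      hit <- which(patoms$map == pm[k])
      src_comp[hit] <- ci
      src_atom[hit] <- mi[k]
    }
  }
  if (any(patoms$map > 0L & is.na(src_comp))) return(NA_character_)

  elem <- patoms$elem
  charge <- patoms$charge
  for (k in seq_len(np)) {
    if (patoms$map[k] > 0L) {
      ga <- graphs[[src_comp[k]]]$atoms
      if (is.na(elem[k])) elem[k] <- ga$elem[src_atom[k]]
      charge[k] <- ga$charge[src_atom[k]]
    }
  }
  if (anyNA(elem)) return(NA_character_)

  b_from <- pbonds$from
  b_to <- pbonds$to
  b_order <- pbonds$order

  # carry substituents reachable through unmatched atoms
  extra_h <- integer(0)       # product idx of copied explicit-H neighbours,
  extra_h_of <- integer(0)    # and the mapped product atom each hangs from
  for (ci in seq_along(graphs)) {
    g <- graphs[[ci]]
    matched <- unique(matches[[ci]])
    mapped_here <- which(src_comp == ci)
    if (!length(mapped_here)) next
    gb <- g$bonds
    adj <- vector("list", nrow(g$atoms))
    for (e in seq_len(nrow(gb))) {
      adj[[gb$from[e]]] <- c(adj[[gb$from[e]]], e)
      adj[[gb$to[e]]] <- c(adj[[gb$to[e]]], e)
    }
    seen <- rep(FALSE, nrow(g$atoms))
    copy_idx <- rep(NA_integer_, nrow(g$atoms))
    queue <- integer(0)
    for (pk in mapped_here) {
      a <- src_atom[pk]
      for (e in adj[[a]]) {
        nb <- if (gb$from[e] == a) gb$to[e] else gb$from[e]
        if (nb %in% matched) next
        if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
        # bond mapped-atom -> unmatched neighbour (added after atom copy)
      }
    }
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      copy_idx[a] <- length(elem) + 1L
      elem <- c(elem, g$atoms$elem[a])
      charge <- c(charge, g$atoms$charge[a])
      for (e in adj[[a]]) {
        nb <- if (gb$from[e] == a) gb$to[e] else gb$from[e]
        if (nb %in% matched || seen[nb]) next
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    # bonds among copied atoms and to mapped atoms
    for (e in seq_len(nrow(gb))) {
      a <- gb$from[e]; b <- gb$to[e]
      a_c <- if (!is.na(copy_idx[a])) copy_idx[a] else NA_integer_
      b_c <- if (!is.na(copy_idx[b])) copy_idx[b] else NA_integer_
      a_m <- mapped_here[match(a, src_atom[mapped_here])]
      b_m <- mapped_here[match(b, src_atom[mapped_here])]
      pa <- if (!is.na(a_c)) a_c else a_m
      pb <- if (!is.na(b_c)) b_c else b_m
      if (is.na(pa) || is.na(pb)) next
      if (!is.na(a_m) && !is.na(b_m)) next  # mapped-mapped: template decides
      b_from <- c(b_from, pa); b_to <- c(b_to, pb)
      b_order <- c(b_order, gb$order[e])
      if (!is.na(a_m) && g$atoms$elem[b] == "H") {
        extra_h <- c(extra_h, pb); extra_h_of <- c(extra_h_of, a_m)
      } else if (!is.na(b_m) && g$atoms$elem[a] == "H") {
        extra_h <- c(extra_h, pa); extra_h_of <- c(extra_h_of, b_m)
      }
    }
  }

  # hydrogen rebalancing at mapped atoms
  drop_atoms <- integer(0)
  for (pk in which(patoms$map > 0L)) {
    if (elem[pk] == "H") next
    g <- graphs[[src_comp[pk]]]
    gb <- g$bonds
    a <- src_atom[pk]
    matched <- unique(matches[[src_comp[pk]]])
    on_a <- gb$from == a | gb$to == a
    other <- ifelse(gb$from == a, gb$to, gb$from)
    m_old <- sum(gb$order[on_a & other %in% matched])
    t_new <- sum(b_order[seq_len(nrow(pbonds))][
      pbonds$from == pk | pbonds$to == pk])
    hs <- extra_h[extra_h_of == pk]
    target <- if (!is.na(patoms$hcount[pk])) {
      patoms$hcount[pk]
    } else {
      length(hs) - (t_new - m_old)
    }
    if (target < 0L) return(NA_character_)
    if (target < length(hs)) {
      drop_atoms <- c(drop_atoms, hs[seq_len(length(hs) - target)])
    } else if (target > length(hs)) {
      for (extra in seq_len(target - length(hs))) {
        elem <- c(elem, "H"); charge <- c(charge, 0L)
        b_from <- c(b_from, pk); b_to <- c(b_to, length(elem))
        b_order <- c(b_order, 1L)
      }
    }
  }
  # explicit Hn on new (unmapped) template atoms
  for (pk in which(patoms$map == 0L & !is.na(patoms$hcount))) {
    for (extra in seq_len(patoms$hcount[pk])) {
      elem <- c(elem, "H"); charge <- c(charge, 0L)
      b_from <- c(b_from, pk); b_to <- c(b_to, length(elem))
      b_order <- c(b_order, 1L)
    }
  }
  if (length(drop_atoms)) {
    keep <- setdiff(seq_along(elem), drop_atoms)
    remapv <- match(seq_along(elem), keep)
    sel <- b_from %in% keep & b_to %in% keep
    b_from <- remapv[b_from[sel]]
    b_to <- remapv[b_to[sel]]
    b_order <- b_order[sel]
    elem <- elem[keep]; charge <- charge[keep]
  }

  # connected components; keep largest fragment by heavy atoms
  nfinal <- length(elem)
  comp <- seq_len(nfinal)
  repeat {
    changed <- FALSE
    for (e in seq_along(b_from)) {
      r <- min(comp[b_from[e]], comp[b_to[e]])
      if (comp[b_from[e]] != r || comp[b_to[e]] != r) {
        comp[comp == comp[b_from[e]] | comp == comp[b_to[e]]] <- r
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  frag_ids <- unique(comp)
  best <- NA_character_
  best_key <- NULL
  for (fid in frag_ids) {
    sel_a <- which(comp == fid)
    heavy <- sum(elem[sel_a] != "H")
    if (heavy == 0L) next
    remapv <- match(seq_len(nfinal), sel_a)
    sel_b <- which(b_from %in% sel_a & b_to %in% sel_a)
    mb <- graph_to_molblock(elem[sel_a], charge[sel_a],
                            remapv[b_from[sel_b]], remapv[b_to[sel_b]],
                            b_order[sel_b])
    smi <- .ob_molblock_to_cansmi(mb)
    if (!nzchar(smi)) next
    key <- list(-heavy, smi)
    if (is.null(best_key) ||
        key[[1]] < best_key[[1]] ||
        (key[[1]] == best_key[[1]] && key[[2]] < best_key[[2]])) {
      best_key <- key
      best <- smi
    }
  }
  best
}

#' Apply a mapped reaction transform to reagent molecules
#'
#' Runs a reaction SMARTS (atom-mapped reagent templates `>>` product
#' template) against a tuple of reagents, enumerating every combination of
#' substructure embeddings. By-product fragments on the product side are
#' discarded, keeping the largest fragment by heavy-atom count
#' (ties: lexicographically smallest canonical SMILES).
#'
#' @param transform reaction SMARTS string; the printed arrow glyph is
#'   accepted and normalized to `>>`.
#' @param reagents character vector of reagent SMILES, one per reagent
#'   template, in template order.
#' @return character vector of distinct canonical product SMILES (empty when
#'   the transform does not apply). Raw products that fail sanitization are
#'   dropped with a warning.
#' @export
#' @examples
#' apply_transform("[NX3;H2,H1;!$(NC=O):1]>>[N:1]C1=NN=NS1", "CNC")
apply_transform <- function(transform, reagents) {
  ct <- compile_transform(transform)
  if (length(reagents) != ct$arity) {
    stop("transform has ", ct$arity, " reagent template(s) but ",
         length(reagents), " reagent(s) were supplied", call. = FALSE)
  }
  graphs <- lapply(reagents, mol_graph, addh = TRUE)
  if (any(vapply(graphs, is.null, logical(1)))) {
    stop("unparseable reagent SMILES", call. = FALSE)
  }
  match_sets <- vector("list", ct$arity)
  for (ci in seq_len(ct$arity)) {
    match_sets[[ci]] <- smarts_match(reagents[ci],
                                     ct$reagent_templates[ci], addh = TRUE)
    if (length(match_sets[[ci]]) == 0L) return(character(0))
  }
  combos <- expand.grid(lapply(match_sets, seq_along))
  out <- character(0)
  dropped <- 0L
  for (r in seq_len(nrow(combos))) {
    sel <- lapply(seq_len(ct$arity),
                  function(ci) match_sets[[ci]][[combos[r, ci]]])
    smi <- graft_product(ct, graphs, sel)
    if (is.na(smi)) dropped <- dropped + 1L else out <- c(out, smi)
  }
  if (dropped > 0L && length(out) == 0L && nrow(combos) > 0L) {
    warning(dropped, " raw product(s) failed assembly/sanitization",
            call. = FALSE)
  }
  unique(out)
}
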