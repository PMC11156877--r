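# Diversity analytics: Bemis-Murcko scaffolds, PMI/NPR shape, InChIKey
# identity partitions.

#' Bemis-Murcko scaffold
#'
#' Ring systems plus the linkers connecting them, with side chains removed;
#' terminal atoms attached to the scaffold by a double or triple bond (e.g.
#' exocyclic carbonyl oxygens) are retained. Acyclic molecules return the
#' empty-scaffold sentinel `""`.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical scaffold SMILES (`""` for acyclic
#'   molecules).
#' @export
#' @examples
#' murcko_scaffold("Cc1ccccc1")   # toluene -> benzene
murcko_scaffold <- function(smiles) {
  vapply(smiles, function(s) {
    g <- mol_graph(s, addh = FALSE)
    if (is.null(g)) stop("unparseable SMILES: ", s, call. = FALSE)
    a <- g$atoms; b <- g$bonds
    n <- nrow(a)
    if (!any(a$in_ring)) return("")
    keep <- rep(TRUE, n)
    # prune non-ring terminal atoms until only rings + linkers remain
    repeat {
      deg <- integer(n)
      if (nrow(b)) {
        sel <- keep[b$from] & keep[b$to]
        for (e in which(sel)) {
          deg[b$from[e]] <- deg[b$from[e]] + 1L
          deg[b$to[e]] <- deg[b$to[e]] + 1L
        }
      }
      drop <- which(keep & !a$in_ring & deg <= 1L)
      if (!length(drop)) break
      keep[drop] <- FALSE
    }
    # re-attach multiply-bonded terminal atoms (exocyclic =O and kin)
    if (nrow(b)) {
      repeat {
        extra <- which(!keep[b$from] & keep[b$to] & b$order >= 2L |
                       keep[b$from] & !keep[b$to] & b$order >= 2L)
        add <- unique(c(b$from[extra][!keep[b$from][extra]],
                        b$to[extra][!keep[b$to][extra]]))
        if (!length(add)) break
        keep[add] <- TRUE
      }
    }
    idx <- which(keep)
    remap <- match(seq_len(n), idx)
    sel_b <- which(keep[b$from] & keep[b$to])
    mb <- graph_to_molblock(a$elem[idx], a$charge[idx],
                            remap[b$from[sel_b]], remap[b$to[sel_b]],
                            b$order[sel_b])
    smi <- .ob_molblock_to_cansmi(mb)
    if (!nzchar(smi)) stop("scaffold sanitization failed for: ", s,
                           call. = FALSE)
    smi
  }, character(1), USE.NAMES = FALSE)
}

#' Scaffold census of a library
#'
#' @param smiles character vector of (deduplicated) library SMILES.
#' @return list of class `scaffold_summary`: `n_compounds`, `n_scaffolds`,
#'   `compounds_per_scaffold`, `scaffold_counts` (named count vector,
#'   including the `""` sentinel for acyclic molecules, reported
#'   separately as `n_acyclic`).
#' @export
scaffold_summary <- function(smiles) {
  sc <- murcko_scaffold(smiles)
  counts <- table(sc)
  counts <- setNames(as.integer(counts), names(counts))
  structure(list(
    n_compounds = length(sc),
    n_scaffolds = length(counts),
    compounds_per_scaffold = length(sc) / length(counts),
    n_acyclic = sum(sc == ""),
    scaffold_counts = counts
  ), class = "scaffold_summary")
}

#' @export
print.scaffold_summary <- function(x, ...) {
  cat("<scaffold_summary>", x$n_compounds, "compounds,", x$n_scaffolds,
      "scaffolds,", round(x$compounds_per_scaffold, 2),
      "compounds/scaffold\n")
  invisible(x)
}

#' Scaffold overlap between two libraries
#'
#' @param a,b [scaffold_summary()] objects built with the same
#'   canonicalization.
#' @return list with `shared` (count of scaffolds present in both),
#'   `fraction_a` and `fraction_b` (shared count over each library's
#'   scaffold count).
#' @export
scaffold_overlap <- function(a, b) {
  stopifnot(inherits(a, "scaffold_summary"),
            inherits(b, "scaffold_summary"))
  shared <- length(intersect(names(a$scaffold_counts),
                             names(b$scaffold_counts)))
  list(shared = shared,
       fraction_a = shared / a$n_scaffolds,
       fraction_b = shared / b$n_scaffolds)
}

#' Normalized principal-moments-of-inertia ratios
#'
#' Builds a single 3D conformer (distance-geometry style builder plus a
#' short force-field relaxation, deterministic per molecule), computes the
#' principal moments of inertia I1 <= I2 <= I3 of the mass-weighted
#' coordinates and returns NPR1 = I1/I3, NPR2 = I2/I3. Rod-like molecules
#' sit near (0, 1), discs near (0.5, 0.5), spheres near (1, 1).
#'
#' @param smiles character vector of SMILES.
#' @param seed integer kept for interface stability; the builder itself is
#'   deterministic.
#' @param ff_steps steepest-descent relaxation steps (default 200).
#' @return data frame with columns `npr1`, `npr2`.
#' @export
npr_shape <- function(smiles, seed = 42L, ff_steps = 200L) {
  res <- lapply(smiles, function(s) {
    e <- .ob_embed3d(s, as.integer(ff_steps))
    if (!isTRUE(e$ok)) stop("3D embedding failed for: ", s, call. = FALSE)
    npr_from_points(e$xyz, e$mass)
  })
  data.frame(npr1 = vapply(res, `[[`, numeric(1), 1),
             npr2 = vapply(res, `[[`, numeric(1), 2))
}

#' NPR ratios of an explicit point-mass set
#'
#' @param xyz numeric matrix (n x 3) of coordinates.
#' @param mass numeric vector of point masses (default: unit masses).
#' @return numeric vector `c(npr1, npr2)`.
#' @export
npr_from_points <- function(xyz, mass = rep(1, nrow(xyz))) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3, nrow(xyz) == length(mass))
  ctr <- colSums(xyz * mass) / sum(mass)
  p <- sweep(xyz, 2, ctr)
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  it <- matrix(c(
    sum(mass * (y^2 + z^2)), -sum(mass * x * y), -sum(mass * x * z),
    -sum(mass * x * y), sum(mass * (x^2 + z^2)), -sum(mass * y * z),
    -sum(mass * x * z), -sum(mass * y * z), sum(mass * (x^2 + y^2))),
    nrow = 3)
  ev <- sort(eigen(it, symmetric = TRUE, only.values = TRUE)$values)
  c(npr1 = ev[1] / ev[3], npr2 = ev[2] / ev[3])
}

#' Bin shape points into a density grid
#'
#' Histograms (NPR1, NPR2) points on an `nbins` x `nbins` grid over
#' NPR1 in `[0, 1]`, NPR2 in `[0.5, 1]`. Points violating the triangle
#' constraints (NPR1 <= NPR2 <= 1, NPR1 + NPR2 >= 1) beyond `tol` are
#' clamped onto the triangle with a warning.
#'
#' @param points data frame or matrix with NPR1/NPR2 in the first two
#'   columns.
#' @param nbins grid resolution per axis (default 200).
#' @param tol tolerance for the triangle check (default 1e-6).
#' @return list of class `shape_grid`: `nbins`, `grid` (counts), `n_total`.
#' @export
bin_shapes <- function(points, nbins = 200L, tol = 1e-6) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  bad <- pts[, 1] > pts[, 2] + tol | pts[, 2] > 1 + tol |
    pts[, 1] + pts[, 2] < 1 - tol | pts[, 1] < -tol
  if (any(bad)) {
    warning(sum(bad), " point(s) outside the NPR triangle were clamped",
            call. = FALSE)
    pts[, 2] <- pmin(pmax(pts[, 2], 0.5), 1)
    pts[, 1] <- pmin(pmax(pts[, 1], 1 - pts[, 2]), pts[, 2])
  }
  ix <- pmin(pmax(ceiling(pts[, 1] * nbins), 1L), nbins)
  iy <- pmin(pmax(ceiling((pts[, 2] - 0.5) / 0.5 * nbins), 1L), nbins)
  grid <- matrix(0L, nrow = nbins, ncol = nbins)
  for (k in seq_len(n)) grid[ix[k], iy[k]] <- grid[ix[k], iy[k]] + 1L
  structure(list(nbins = nbins, grid = grid, n_total = n),
            class = "shape_grid")
}

#' Partition InChIKeys for fast identity search
#'
#' Groups standard InChIKeys by (heavy-atom count, first two key letters),
#' each group holding a sorted key vector, mirroring a
#' directories-and-files identity store.
#'
#' @param inchikey character vector of standard 27-character InChIKeys.
#' @param heavy_atoms integer vector of heavy-atom counts.
#' @return named list of sorted key vectors, names `"<hac>/<prefix>"`, of
#'   class `inchikey_partition`.
#' @export
build_partition <- function(inchikey, heavy_atoms) {
  stopifnot(length(inchikey) == length(heavy_atoms))
  bad <- !grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", inchikey)
  if (any(bad)) {
    stop("malformed InChIKey: ", inchikey[which(bad)[1]], call. = FALSE)
  }
  key <- paste0(heavy_atoms, "/", substr(inchikey, 1, 2))
  out <- lapply(split(inchikey, key), function(x) sort(unique(x)))
  class(out) <- "inchikey_partition"
  out
}

#' Membership lookup in an InChIKey partition
#'
#' Equivalent to a linear scan over the full key list, but touches only the
#' (heavy atoms, prefix) bucket.
#'
#' @param partition an [build_partition()] object.
#' @param inchikey single standard InChIKey to look up.
#' @param heavy_atoms heavy-atom count of the query structure.
#' @return `TRUE` iff the key was inserted.
#' @export
partition_lookup <- function(partition, inchikey, heavy_atoms) {
  if (!grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", inchikey)) {
    stop("malformed InChIKey: ", inchikey, call. = FALSE)
  }
  bucket <- partition[[paste0(heavy_atoms, "/", substr(inchikey, 1, 2))]]
  !is.null(bucket) && inchikey %in% bucket
}

#' Write / read an InChIKey partition store
#'
#' On-disk layout: `<dir>/<heavy atoms>/<prefix>.txt`, sorted keys one per
#' line (grep-friendly).
#'
#' @param partition an [build_partition()] object.
#' @param dir store directory.
#' @return `write_partition_store` returns `dir` invisibly;
#'   `read_partition_store` returns the partition.
#' @export
write_partition_store <- function(partition, dir) {
  for (key in names(partition)) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    d <- file.path(dir, parts[1])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    writeLines(partition[[key]], file.path(d, paste0(parts[2], ".txt")))
  }
  invisible(dir)
}

#' @rdname write_partition_store
#' @export
read_partition_store <- function(dir) {
  files <- list.files(dir, pattern = "\\.txt$", recursive = TRUE,
                      full.names = TRUE)
  out <- lapply(files, function(f) readLines(f, warn = FALSE))
  names(out) <- vapply(files, function(f) {
    parts <- strsplit(f, .Platform$file.sep, fixed = TRUE)[[1]]
    np <- length(parts)
    paste0(parts[np - 1], "/", sub("\\.txt$", "", parts[np]))
  }, character(1))
  class(out) <- "inchikey_partition"
  out
}
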