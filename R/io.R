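# Readers/writers for the library exchange formats: tab-delimited SMILES
# files and the enumeration CSV. All writers are byte-reproducible for
# fixed inputs (no timestamps).

#' Write / read a tab-delimited SMILES file
#'
#' One record per line: SMILES, TAB, product name. Round-trips exactly.
#'
#' @param products data frame with columns `smiles` and `product_id`.
#' @param path file path.
#' @return `write_smiles` returns `path` invisibly; `read_smiles` returns a
#'   data frame with columns `smiles` and `product_id`.
#' @export
write_smiles <- function(products, path) {
  stopifnot(all(c("smiles", "product_id") %in% names(products)))
  writeLines(if (nrow(products)) {
    paste(products$smiles, products$product_id, sep = "\t")
  } else character(0), path)
  invisible(path)
}

#' @rdname write_smiles
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(smiles = character(0), product_id = character(0),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 2L)
  if (length(bad)) {
    stop("line ", bad[1], ": expected 2 tab-separated fields, found ",
         lengths(f)[bad[1]], call. = FALSE)
  }
  data.frame(smiles = vapply(f, `[[`, character(1), 1),
             product_id = vapply(f, `[[`, character(1), 2),
             stringsAsFactors = FALSE)
}

products_csv_columns <- function() {
  c("smiles", "product_id", "reaction_id", "variant_id", "reagent_a",
    "reagent_b", "mw", "clogp", "hba", "hbd", "rotb", "tpsa", "hac",
    "fsp3", "qed", "druglike", "purchasability")
}

#' Write / read the enumeration CSV
#'
#' Comma-delimited with a fixed, documented column order (see
#' `products_csv_columns()`): identity and provenance first, then the
#' descriptor block, the druglike flag and the purchasability code. Floats
#' are serialized with 6 significant digits. A cheap export
#' (`cheap = TRUE`, the default) only admits purchasability codes 1 and 2.
#'
#' @param rows data frame carrying all CSV columns.
#' @param path file path.
#' @param cheap validate that purchasability is 1 or 2 (default `TRUE`).
#' @return `write_products_csv` returns `path` invisibly;
#'   `read_products_csv` returns the data frame.
#' @export
write_products_csv <- function(rows, path, cheap = TRUE) {
  missing <- setdiff(products_csv_columns(), names(rows))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (cheap && nrow(rows) &&
      !all(rows$purchasability %in% c("1", "2", 1, 2))) {
    stop("cheap export admits purchasability codes 1 and 2 only",
         call. = FALSE)
  }
  out <- rows[, products_csv_columns(), drop = FALSE]
  for (col in c("mw", "clogp", "tpsa", "fsp3", "qed")) {
    out[[col]] <- signif(out[[col]], 6)
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, qmethod = "double")
  invisible(path)
}

#' @rdname write_products_csv
#' @export
read_products_csv <- function(path) {
  out <- utils::read.table(path, sep = ",", header = TRUE,
                           colClasses = c(purchasability = "character"),
                           stringsAsFactors = FALSE)
  missing <- setdiff(products_csv_columns(), names(out))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out
}
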