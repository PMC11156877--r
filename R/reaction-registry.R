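# Reaction definitions: synthons (reagent classes), mapped transform
# variants, and reaction-level global exclusions.
#
# On-disk format (two files per reaction, tab-delimited, one record per line,
# leading record-type token, '#' comments):
#
#   <id>_Reagents.txt
#     SYNTHON        <synthon_id> <inclusion SMARTS>   (repeatable)
#     EXCLUDE        <synthon_id> <exclusion SMARTS>
#     SYMMETRIC      <synthon_id> <SMARTS>
#     TAG            <synthon_id> <tag>[,<tag>...]
#     PRECURSOR      <synthon_id> <one-component transform SMARTS>
#     GLOBAL_EXCLUDE <name> <SMARTS>
#
#   <id>_Reactions.txt
#     REACTION <variant_id> <transform SMARTS> <tag>[,<tag>] [key=value ...]
#
# A synthon carrying a PRECURSOR record is an upstream feeder: catalog hits
# are converted by its one-component transform and the products join the
# pool of the (unique) non-precursor synthon sharing its reaction tag.

#' Construct a synthon definition
#'
#' A synthon is one reagent class of a reaction: the inclusion SMARTS that
#' qualify a building block (a block qualifies if it matches any of them),
#' synthon-specific exclusion SMARTS, an optional symmetric-reagent detector,
#' and the reaction tags that link the synthon to variant component slots.
#'
#' @param synthon_id short unique identifier.
#' @param inclusion_patterns character vector of SMARTS; a molecule
#'   qualifies if it matches any.
#' @param exclusion_patterns character vector of SMARTS vetoing a molecule.
#' @param symmetric_pattern optional SMARTS identifying symmetric reagents.
#' @param reaction_tags character vector linking the synthon to variant
#'   component slots; must be non-empty.
#' @param is_precursor logical; `TRUE` for upstream feeder classes that are
#'   converted by `precursor_transform` before the main reaction.
#' @param precursor_transform one-component mapped transform SMARTS
#'   (required when `is_precursor`).
#' @return an object of class `synthon_definition`.
#' @export
synthon_definition <- function(synthon_id, inclusion_patterns,
                               exclusion_patterns = character(0),
                               symmetric_pattern = NULL,
                               reaction_tags,
                               is_precursor = FALSE,
                               precursor_transform = NULL) {
  stopifnot(is.character(synthon_id), length(synthon_id) == 1L,
            nzchar(synthon_id),
            is.character(inclusion_patterns), length(inclusion_patterns) >= 1L,
            is.character(reaction_tags), length(reaction_tags) >= 1L)
  if (is_precursor && is.null(precursor_transform)) {
    stop("precursor synthon '", synthon_id,
         "' needs a precursor_transform", call. = FALSE)
  }
  structure(list(
    synthon_id = synthon_id,
    inclusion_patterns = inclusion_patterns,
    exclusion_patterns = exclusion_patterns,
    symmetric_pattern = symmetric_pattern,
    reaction_tags = reaction_tags,
    is_precursor = is_precursor,
    precursor_transform = precursor_transform
  ), class = "synthon_definition")
}

#' Construct a reaction variant
#'
#' One mapped SMARTS transform of a reaction, with the ordered reaction tags
#' naming which synthon feeds each reagent template.
#'
#' @param variant_id identifier, unique within the reaction.
#' @param transform mapped reaction SMARTS (`reagents >> product`).
#' @param component_tags character vector of reaction tags, one per reagent
#'   template, in template order.
#' @param annotations named character vector of free-form labels (chain
#'   length, chirality class, ...).
#' @return an object of class `reaction_variant`.
#' @export
reaction_variant <- function(variant_id, transform, component_tags,
                             annotations = character(0)) {
  stopifnot(is.character(variant_id), length(variant_id) == 1L,
            is.character(transform), length(transform) == 1L,
            is.character(component_tags), length(component_tags) >= 1L)
  ct <- compile_transform(transform)
  if (ct$arity != length(component_tags)) {
    stop("variant '", variant_id, "': transform has ", ct$arity,
         " reagent template(s) but ", length(component_tags),
         " component tag(s)", call. = FALSE)
  }
  structure(list(
    variant_id = variant_id,
    transform = normalize_transform(transform),
    component_tags = component_tags,
    annotations = annotations
  ), class = "reaction_variant")
}

#' Construct a reaction definition
#'
#' @param reaction_id identifier.
#' @param display_name human-readable name.
#' @param synthons list of [synthon_definition()] objects.
#' @param variants list of [reaction_variant()] objects (ordered).
#' @param global_exclusions character vector of SMARTS applied to every
#'   reagent of the reaction; may carry names.
#' @return an object of class `reaction_definition`.
#' @export
reaction_definition <- function(reaction_id, display_name, synthons,
                                variants, global_exclusions = character(0)) {
  stopifnot(is.character(reaction_id), length(reaction_id) == 1L,
            length(variants) >= 1L)
  ids <- vapply(synthons, function(s) s$synthon_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate synthon_id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  structure(list(
    reaction_id = reaction_id,
    display_name = display_name,
    synthons = synthons,
    variants = variants,
    global_exclusions = global_exclusions
  ), class = "reaction_definition")
}

#' @export
print.reaction_definition <- function(x, ...) {
  cat("<reaction_definition> ", x$reaction_id, " (", x$display_name, ")\n",
      "  synthons: ", paste(vapply(x$synthons, `[[`, character(1),
                                   "synthon_id"), collapse = ", "), "\n",
      "  variants: ", length(x$variants),
      ";  global exclusions: ", length(x$global_exclusions), "\n", sep = "")
  invisible(x)
}

read_record_lines <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else text
  data.frame(lineno = seq_along(lines), line = lines,
             stringsAsFactors = FALSE)
}

#' Parse a reagents file into synthon definitions
#'
#' @param text contents of a reagents file: a single string, a character
#'   vector of lines, or a file path.
#' @return list of [synthon_definition()] objects, with the reaction-level
#'   exclusion patterns attached as attribute `global_exclusions`.
#' @export
parse_synthon_file <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  recs <- read_record_lines(text)
  inclusion <- list(); exclusion <- list(); symmetric <- list()
  tags <- list(); precursor <- list()
  order_seen <- character(0)
  glob <- character(0); glob_names <- character(0)
  for (i in seq_len(nrow(recs))) {
    line <- trimws(recs$line[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    type <- f[1]
    bad_smarts <- function(s) !isTRUE(smarts_is_valid(s))
    if (type == "SYNTHON") {
      if (length(f) != 3L) stop("line ", recs$lineno[i],
                                ": SYNTHON needs id and SMARTS", call. = FALSE)
      if (bad_smarts(f[3])) stop("line ", recs$lineno[i],
                                 ": unparseable SMARTS: ", f[3], call. = FALSE)
      if (!(f[2] %in% order_seen)) order_seen <- c(order_seen, f[2])
      inclusion[[f[2]]] <- c(inclusion[[f[2]]], f[3])
    } else if (type == "EXCLUDE") {
      if (length(f) != 3L) stop("line ", recs$lineno[i],
                                ": EXCLUDE needs id and SMARTS", call. = FALSE)
      if (bad_smarts(f[3])) stop("line ", recs$lineno[i],
                                 ": unparseable SMARTS: ", f[3], call. = FALSE)
      exclusion[[f[2]]] <- c(exclusion[[f[2]]], f[3])
    } else if (type == "SYMMETRIC") {
      if (length(f) != 3L) stop("line ", recs$lineno[i],
                                ": SYMMETRIC needs id and SMARTS",
                                call. = FALSE)
      if (bad_smarts(f[3])) stop("line ", recs$lineno[i],
                                 ": unparseable SMARTS: ", f[3], call. = FALSE)
      symmetric[[f[2]]] <- f[3]
    } else if (type == "TAG") {
      if (length(f) != 3L) stop("line ", recs$lineno[i],
                                ": TAG needs id and tag list", call. = FALSE)
      tags[[f[2]]] <- c(tags[[f[2]]],
                        strsplit(f[3], ",", fixed = TRUE)[[1]])
    } else if (type == "PRECURSOR") {
      if (length(f) != 3L) stop("line ", recs$lineno[i],
                                ": PRECURSOR needs id and transform",
                                call. = FALSE)
      precursor[[f[2]]] <- f[3]
    } else if (type == "GLOBAL_EXCLUDE") {
      if (length(f) != 3L) stop("line ", recs$lineno[i],
                                ": GLOBAL_EXCLUDE needs name and SMARTS",
                                call. = FALSE)
      if (bad_smarts(f[3])) stop("line ", recs$lineno[i],
                                 ": unparseable SMARTS: ", f[3], call. = FALSE)
      glob <- c(glob, f[3]); glob_names <- c(glob_names, f[2])
    } else {
      stop("line ", recs$lineno[i], ": unknown record type '", type, "'",
           call. = FALSE)
    }
  }
  extra <- setdiff(c(names(exclusion), names(symmetric), names(tags),
                     names(precursor)), order_seen)
  if (length(extra)) {
    stop("record(s) for undeclared synthon id(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  out <- lapply(order_seen, function(id) {
    tg <- tags[[id]]
    if (is.null(tg)) stop("synthon '", id, "' has no TAG record",
                          call. = FALSE)
    synthon_definition(
      synthon_id = id,
      inclusion_patterns = inclusion[[id]],
      exclusion_patterns = exclusion[[id]] %||% character(0),
      symmetric_pattern = symmetric[[id]],
      reaction_tags = tg,
      is_precursor = !is.null(precursor[[id]]),
      precursor_transform = precursor[[id]]
    )
  })
  attr(out, "global_exclusions") <- setNames(glob, glob_names)
  out
}

#' Parse a reactions file into variants
#'
#' @param text contents of a reactions file (string, lines, or file path).
#' @return list of [reaction_variant()] objects in file order; an empty file
#'   yields an empty list.
#' @export
parse_reaction_file <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  recs <- read_record_lines(text)
  out <- list()
  for (i in seq_len(nrow(recs))) {
    line <- trimws(recs$line[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (f[1] != "REACTION") {
      stop("line ", recs$lineno[i], ": unknown record type '", f[1], "'",
           call. = FALSE)
    }
    if (length(f) < 4L) {
      stop("line ", recs$lineno[i],
           ": REACTION needs id, transform and tags", call. = FALSE)
    }
    ann <- character(0)
    if (length(f) > 4L) {
      kv <- strsplit(f[5:length(f)], "=", fixed = TRUE)
      ann <- setNames(vapply(kv, function(x) paste(x[-1], collapse = "="),
                             character(1)),
                      vapply(kv, `[[`, character(1), 1))
    }
    v <- tryCatch(
      reaction_variant(f[2], f[3],
                       strsplit(f[4], ",", fixed = TRUE)[[1]], ann),
      error = function(e) stop("line ", recs$lineno[i], ": ",
                               conditionMessage(e), call. = FALSE))
    out[[length(out) + 1L]] <- v
  }
  out
}

#' Serialize synthon definitions to the reagents-file format
#'
#' Inverse of [parse_synthon_file()]: `parse(serialize(x))` reproduces `x`
#' field by field.
#'
#' @param synthons list of synthon definitions.
#' @param global_exclusions optional named character vector of reaction-level
#'   exclusions.
#' @return character vector of file lines.
#' @export
serialize_synthons <- function(synthons,
                               global_exclusions = attr(synthons,
                                                        "global_exclusions")) {
  lines <- character(0)
  for (s in synthons) {
    for (p in s$inclusion_patterns)
      lines <- c(lines, paste("SYNTHON", s$synthon_id, p, sep = "\t"))
    for (p in s$exclusion_patterns)
      lines <- c(lines, paste("EXCLUDE", s$synthon_id, p, sep = "\t"))
    if (!is.null(s$symmetric_pattern))
      lines <- c(lines, paste("SYMMETRIC", s$synthon_id,
                              s$symmetric_pattern, sep = "\t"))
    lines <- c(lines, paste("TAG", s$synthon_id,
                            paste(s$reaction_tags, collapse = ","),
                            sep = "\t"))
    if (s$is_precursor)
      lines <- c(lines, paste("PRECURSOR", s$synthon_id,
                              s$precursor_transform, sep = "\t"))
  }
  if (length(global_exclusions)) {
    nm <- names(global_exclusions)
    if (is.null(nm)) nm <- paste0("rule", seq_along(global_exclusions))
    lines <- c(lines, paste("GLOBAL_EXCLUDE", nm, global_exclusions,
                            sep = "\t"))
  }
  lines
}

#' Serialize reaction variants to the reactions-file format
#'
#' @param variants list of reaction variants.
#' @return character vector of file lines.
#' @export
serialize_variants <- function(variants) {
  vapply(variants, function(v) {
    base <- paste("REACTION", v$variant_id, v$transform,
                  paste(v$component_tags, collapse = ","), sep = "\t")
    if (length(v$annotations)) {
      base <- paste(c(base, paste0(names(v$annotations), "=",
                                   v$annotations)), collapse = "\t")
    }
    base
  }, character(1))
}

#' Validate a reaction definition
#'
#' Checks that every SMARTS parses, every variant component tag resolves to
#' exactly one non-precursor synthon, product-side atom maps appear on the
#' reagent side, and warns about synthons no variant consumes.
#'
#' @param defn a [reaction_definition()].
#' @return an object of class `validation_report` with fields `ok` (no
#'   error-severity issues) and `issues` (data frame of severity, location,
#'   message).
#' @export
validate_reaction <- function(defn) {
  sev <- character(0); loc <- character(0); msg <- character(0)
  note <- function(s, l, m) {
    sev <<- c(sev, s); loc <<- c(loc, l); msg <<- c(msg, m)
  }
  tag_owner <- list()
  for (s in defn$synthons) {
    where <- paste0("synthon:", s$synthon_id)
    for (p in c(s$inclusion_patterns, s$exclusion_patterns,
                s$symmetric_pattern)) {
      if (!isTRUE(smarts_is_valid(p)))
        note("error", where, paste("unparseable SMARTS:", p))
    }
    if (s$is_precursor) {
      tryCatch(compile_transform(s$precursor_transform),
               error = function(e)
                 note("error", where, conditionMessage(e)))
    } else {
      for (tg in s$reaction_tags)
        tag_owner[[tg]] <- c(tag_owner[[tg]], s$synthon_id)
    }
  }
  for (tg in names(tag_owner)) {
    if (length(tag_owner[[tg]]) > 1L)
      note("error", paste0("tag:", tg),
           paste("tag claimed by multiple non-precursor synthons:",
                 paste(tag_owner[[tg]], collapse = ", ")))
  }
  used_tags <- character(0)
  for (v in defn$variants) {
    where <- paste0("variant:", v$variant_id)
    ct <- tryCatch(compile_transform(v$transform), error = function(e) e)
    if (inherits(ct, "error")) {
      note("error", where, conditionMessage(ct))
      next
    }
    if (ct$arity != length(v$component_tags))
      note("error", where,
           sprintf("transform arity %d != %d component tags", ct$arity,
                   length(v$component_tags)))
    for (tg in v$component_tags) {
      used_tags <- c(used_tags, tg)
      n_owner <- length(tag_owner[[tg]])
      if (n_owner == 0L)
        note("error", where, paste("unresolved tag:", tg))
    }
  }
  for (p in defn$global_exclusions) {
    if (!isTRUE(smarts_is_valid(p)))
      note("error", "global_exclusions", paste("unparseable SMARTS:", p))
  }
  for (s in defn$synthons) {
    if (s$is_precursor) next
    if (!any(s$reaction_tags %in% used_tags))
      note("warning", paste0("synthon:", s$synthon_id),
           "synthon not referenced by any variant")
  }
  structure(list(
    ok = !any(sev == "error"),
    issues = data.frame(severity = sev, location = loc, message = msg,
                        stringsAsFactors = FALSE)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ok =", x$ok, "\n")
  if (nrow(x$issues)) print(x$issues) else cat("  no issues\n")
  invisible(x)
}

builtin_ids <- function() {
  c("betaketoimides", "aminothiatriazoles", "aminotetrazoles",
    "trucesmiles", "cycloadd22", "cycloadd42")
}

builtin_display_names <- function() {
  c(betaketoimides = "beta-keto-imides",
    aminothiatriazoles = "5-amino-thiatriazoles",
    aminotetrazoles = "5-amino-tetrazoles",
    trucesmiles = "Truce-Smiles rearrangement",
    cycloadd22 = "[2+2]-cycloaddition",
    cycloadd42 = "[4+2]-cycloaddition")
}

#' Load one packaged reaction definition
#'
#' @param reaction_id one of the packaged reaction identifiers (see
#'   [builtin_library()]).
#' @return a [reaction_definition()].
#' @export
builtin_reaction <- function(reaction_id) {
  reaction_id <- match.arg(reaction_id, builtin_ids())
  dir <- system.file("extdata", "reactions", package = "synthenum")
  synthons <- parse_synthon_file(file.path(dir, paste0(reaction_id,
                                                       "_Reagents.txt")))
  variants <- parse_reaction_file(file.path(dir, paste0(reaction_id,
                                                        "_Reactions.txt")))
  reaction_definition(
    reaction_id = reaction_id,
    display_name = builtin_display_names()[[reaction_id]],
    synthons = synthons,
    variants = variants,
    global_exclusions = attr(synthons, "global_exclusions")
  )
}

#' The packaged reaction library
#'
#' The six built-in reaction definitions: beta-keto-imides (with dioxinone
#' precursor transforms from free and O-protected beta-keto acids),
#' 5-amino-thiatriazoles, 5-amino-tetrazoles, the Truce-Smiles rearrangement
#' (12 transform variants), the \[2+2\]-cycloaddition (4 variants) and the
#' \[4+2\]-cycloaddition (6 variants).
#'
#' @return named list of [reaction_definition()] objects.
#' @export
#' @examples
#' length(builtin_library())
builtin_library <- function() {
  setNames(lapply(builtin_ids(), builtin_reaction), builtin_ids())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
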