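# Readers and writers for long-format plate data, results tables and
# phylogenetic trees.  All tabular I/O is plain delimited text: comma by
# default, tab accepted.  The long format is
#   culture, well, chemicals, replicate, time_h, od
# with `chemicals` a semicolon-joined list of panel names (empty for the
# no-chemical control).

.plate_cols <- c("culture", "well", "chemicals", "replicate", "time_h", "od")

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a long-format plate-reader table
#'
#' Each row is one OD reading of one well at one time point.  Wells are
#' validated to map to exactly one (culture, mixture, replicate) and to
#' carry a strictly increasing time grid.
#'
#' @param path path to a delimited text file with columns
#'   `culture, well, chemicals, replicate, time_h, od`.
#' @param panel a [chemical_panel()]; chemical names in the file must
#'   belong to it.
#' @param exclude_wells optional character vector of well ids to drop
#'   (e.g. curves flagged as contaminated); exclusions are recorded in
#'   `attr(, "excluded")`.
#' @return a `plate_table`: a data.frame with columns
#'   `culture, well, mixture, replicate, time_h, od` where `mixture` is
#'   the integer subset encoding, plus the panel in `attr(, "panel")`.
#' @export
read_plate_table <- function(path, panel, exclude_wells = NULL) {
  stopifnot(inherits(panel, "chemical_panel"))
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character",
                          na.strings = character(0))
  missing <- setdiff(.plate_cols, names(df))
  if (length(missing) > 0L)
    .stop_class("stressmix_format", "plate table is missing column(s): %s",
                paste(missing, collapse = ", "))
  df <- df[.plate_cols]
  df$chemicals <- as.character(df$chemicals)
  df$mixture <- vapply(strsplit(df$chemicals, ";", fixed = TRUE),
                       function(ch) mixture(trimws(ch), panel), integer(1))
  out <- data.frame(culture   = as.character(df$culture),
                    well      = as.character(df$well),
                    mixture   = df$mixture,
                    replicate = as.integer(df$replicate),
                    time_h    = as.numeric(df$time_h),
                    od        = as.numeric(df$od),
                    stringsAsFactors = FALSE)
  excluded <- character(0)
  if (!is.null(exclude_wells)) {
    excluded <- intersect(unique(out$well), exclude_wells)
    out <- out[!(out$well %in% exclude_wells), , drop = FALSE]
  }
  validate_plate_table(out)
  structure(out, panel = panel, excluded = excluded,
            class = c("plate_table", "data.frame"))
}

#' Validate plate-table invariants
#'
#' Checks that (well, time) pairs are unique, that each well maps to one
#' (culture, mixture, replicate) triple, that times are strictly
#' increasing per well, and that OD readings are non-negative.
#'
#' @param plate a plate data.frame (see [read_plate_table()]).
#' @return the input, invisibly.
#' @export
validate_plate_table <- function(plate) {
  if (anyDuplicated(plate[c("well", "time_h")]))
    .stop_class("stressmix_validation",
                "duplicated (well, time_h) readings in plate table")
  meta <- unique(plate[c("well", "culture", "mixture", "replicate")])
  if (anyDuplicated(meta$well))
    .stop_class("stressmix_validation",
                "well(s) mapped to more than one culture/mixture/replicate: %s",
                paste(unique(meta$well[duplicated(meta$well)]), collapse = ", "))
  bad_time <- vapply(split(plate$time_h, plate$well),
                     function(t) any(diff(t) <= 0), logical(1))
  if (any(bad_time))
    .stop_class("stressmix_validation",
                "non-increasing time grid in well(s): %s",
                paste(names(bad_time)[bad_time], collapse = ", "))
  if (any(plate$od < 0))
    .stop_class("stressmix_validation", "negative OD readings in plate table")
  invisible(plate)
}

#' Write a plate table back to delimited text
#'
#' Inverse of [read_plate_table()]: `mixture` encodings are expanded to
#' semicolon-joined chemical names so a written table re-reads
#' identically.
#'
#' @param plate a `plate_table`.
#' @param path output file path.
#' @param panel panel to use for decoding; defaults to the one attached
#'   to `plate`.
#' @param sep field separator (`","` or `"\t"`).
#' @export
write_plate_table <- function(plate, path, panel = attr(plate, "panel"),
                              sep = ",") {
  stopifnot(inherits(panel, "chemical_panel"))
  out <- data.frame(culture   = plate$culture,
                    well      = plate$well,
                    chemicals = mixture_chemicals(plate$mixture, panel),
                    replicate = plate$replicate,
                    time_h    = plate$time_h,
                    od        = plate$od)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chemical panel file
#'
#' One chemical name per line (or a single-column delimited file with a
#' `chemical` header).
#'
#' @param path file path.
#' @return a [chemical_panel()].
#' @export
read_panel <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L && identical(tolower(lines[1]), "chemical"))
    lines <- lines[-1L]
  chemical_panel(lines)
}

#' Read a phylogenetic tree for the signal tests
#'
#' Thin wrapper over [ape::read.tree()] that enforces labelled, unique
#' tips and strictly positive branch lengths (non-positive lengths are
#' replaced by `epsilon`, with a message).
#'
#' @param path newick file path.
#' @param epsilon replacement for non-positive branch lengths.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path, epsilon = 1e-6) {
  tree <- ape::read.tree(path)
  if (is.null(tree))
    .stop_class("stressmix_format", "could not parse newick file: %s", path)
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    .stop_class("stressmix_validation", "tree has unlabelled tips")
  if (anyDuplicated(tree$tip.label))
    .stop_class("stressmix_validation", "duplicated tip labels: %s",
                paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                      collapse = ", "))
  if (is.null(tree$edge.length))
    .stop_class("stressmix_validation", "tree has no branch lengths")
  n_bad <- sum(tree$edge.length <= 0)
  if (n_bad > 0L) {
    message(sprintf("read_tree: replacing %d non-positive branch length(s) with %g",
                    n_bad, epsilon))
    tree$edge.length[tree$edge.length <= 0] <- epsilon
  }
  tree
}

#' Check that tree tips and response-table cultures match
#'
#' @param tree an [ape::phylo] tree.
#' @param culture_ids character vector of culture labels.
#' @return invisibly `TRUE`; errors listing unmatched labels otherwise.
#' @export
match_tree_cultures <- function(tree, culture_ids) {
  miss_tree <- setdiff(tree$tip.label, culture_ids)
  miss_data <- setdiff(culture_ids, tree$tip.label)
  if (length(miss_tree) || length(miss_data))
    .stop_class("stressmix_validation",
                "tree/response mismatch; tips without data: [%s]; cultures without tips: [%s]",
                paste(miss_tree, collapse = ", "),
                paste(miss_data, collapse = ", "))
  invisible(TRUE)
}

#' Write / read per-well AUC tables
#'
#' Interchange format between the AUC and interaction steps:
#' `culture, mixture, replicate, auc` with `mixture` as semicolon-joined
#' chemical names (empty = control).
#'
#' @param aucs an AUC table (see [plate_auc()]).
#' @param path file path.
#' @param panel a [chemical_panel()].
#' @export
write_auc_table <- function(aucs, path, panel = attr(aucs, "panel")) {
  stopifnot(inherits(panel, "chemical_panel"))
  out <- data.frame(culture = aucs$culture,
                    mixture = mixture_chemicals(aucs$mixture, panel),
                    replicate = aucs$replicate, auc = aucs$auc)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_auc_table
#' @export
read_auc_table <- function(path, panel) {
  stopifnot(inherits(panel, "chemical_panel"))
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character",
                          na.strings = character(0))
  need <- c("culture", "mixture", "replicate", "auc")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    .stop_class("stressmix_format", "AUC table is missing column(s): %s",
                paste(missing, collapse = ", "))
  structure(data.frame(
    culture = df$culture,
    mixture = vapply(strsplit(df$mixture, ";", fixed = TRUE),
                     function(ch) mixture(trimws(ch), panel), integer(1)),
    replicate = as.integer(df$replicate),
    auc = as.numeric(df$auc),
    stringsAsFactors = FALSE),
    panel = panel, class = c("auc_table", "data.frame"))
}

#' Write / read gated response tables
#'
#' `culture, mixture, complexity, g, ci_low, ci_high, significant,
#' direction`, with `mixture` as semicolon-joined chemical names.
#'
#' @param responses the `responses` data.frame of a [stressmix()] fit.
#' @param path file path.
#' @param panel a [chemical_panel()].
#' @export
write_response_table <- function(responses, path, panel) {
  stopifnot(inherits(panel, "chemical_panel"))
  out <- responses
  out$mixture <- mixture_chemicals(out$mixture, panel)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path, panel) {
  stopifnot(inherits(panel, "chemical_panel"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character(0))
  df$mixture <- vapply(strsplit(df$mixture, ";", fixed = TRUE),
                       function(ch) mixture(trimws(ch), panel), integer(1))
  for (col in c("g", "ci_low", "ci_high"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  if ("complexity" %in% names(df)) df$complexity <- as.integer(df$complexity)
  if ("significant" %in% names(df)) df$significant <- as.logical(df$significant)
  df
}
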