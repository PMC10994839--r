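# Chemical panels and mixture (subset) encodings.
#
# A mixture is a subset of a fixed, ordered chemical panel.  Internally
# subsets are stored as integer bitmasks over panel indices (bit i set
# means chemical i+1 is present), which makes the 2^n lattice operations
# (subset tests, subset enumeration, Moebius sums) O(1) per step.

#' Define an ordered panel of chemical stressors
#'
#' The panel fixes the canonical chemical order for an analysis; all
#' mixture encodings refer to panel indices, and design files refer to
#' chemicals by name.
#'
#' @param names character vector of unique chemical identifiers.
#' @return an object of class `chemical_panel`: a character vector with
#'   the panel size in `attr(, "size")`.
#' @examples
#' panel <- chemical_panel(c("oxytetracycline", "tebuconazole", "glyphosate"))
#' enumerate_mixtures(panel)
#' @export
chemical_panel <- function(names) {
  names <- as.character(names)
  if (length(names) < 1L) .stop_class("stressmix_validation", "empty panel")
  if (anyDuplicated(names))
    .stop_class("stressmix_validation", "duplicated chemical names in panel: %s",
                paste(unique(names[duplicated(names)]), collapse = ", "))
  if (length(names) > 30L)
    .stop_class("stressmix_validation", "panels above 30 chemicals are not supported")
  structure(names, size = length(names), class = "chemical_panel")
}

#' @export
print.chemical_panel <- function(x, ...) {
  cat("Chemical panel (", attr(x, "size"), " chemicals):\n  ",
      paste(unclass(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- bitmask primitives (internal) ----------------------------------------

# popcount of a mask
.mask_size <- function(mask) {
  n <- integer(length(mask))
  m <- as.integer(mask)
  while (any(m > 0L)) {
    n <- n + (m %% 2L)
    m <- m %/% 2L
  }
  n
}

# 1-based panel indices of the chemicals in a mask
.mask_members <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:29)) != 0L)

# mask from 1-based panel indices
.mask_from_members <- function(idx) {
  if (length(idx) == 0L) return(0L)
  sum(bitwShiftL(1L, as.integer(idx) - 1L))
}

# all non-empty proper submasks of `mask`
.proper_submasks <- function(mask) {
  mask <- as.integer(mask)
  out <- integer(0)
  sub <- bitwAnd(mask - 1L, mask)
  while (sub > 0L) {
    out <- c(out, sub)
    sub <- bitwAnd(sub - 1L, mask)
  }
  out
}

#' Encode a set of chemical names as a mixture
#'
#' @param chemicals character vector of chemical names (possibly empty,
#'   meaning the no-chemical control).
#' @param panel a [chemical_panel()].
#' @return integer bitmask over panel indices.
#' @export
mixture <- function(chemicals, panel) {
  stopifnot(inherits(panel, "chemical_panel"))
  chemicals <- chemicals[nzchar(chemicals)]
  if (length(chemicals) == 0L) return(0L)
  idx <- match(chemicals, unclass(panel))
  if (anyNA(idx))
    .stop_class("stressmix_validation", "chemical(s) not in panel: %s",
                paste(chemicals[is.na(idx)], collapse = ", "))
  .mask_from_members(unique(idx))
}

#' Decode a mixture back to chemical names
#'
#' @param mask integer mixture encoding (vectorised).
#' @param panel a [chemical_panel()].
#' @param collapse separator used to join names; `NULL` returns a list.
#' @return character vector of labels (`""` for the control) or a list of
#'   name vectors when `collapse = NULL`.
#' @export
mixture_chemicals <- function(mask, panel, collapse = ";") {
  stopifnot(inherits(panel, "chemical_panel"))
  nm <- lapply(as.integer(mask), function(m) unclass(panel)[.mask_members(m)])
  if (is.null(collapse)) return(nm)
  vapply(nm, paste, character(1), collapse = collapse)
}

#' Number of chemicals in a mixture
#'
#' @param mask integer mixture encoding (vectorised).
#' @return integer vector of mixture complexities.
#' @export
mixture_size <- function(mask) .mask_size(as.integer(mask))

#' Enumerate all non-empty chemical mixtures of a panel
#'
#' Returns the `2^n - 1` non-empty subsets of the panel, ordered by
#' complexity (number of chemicals) and then lexicographically by member
#' indices.  This ordering is the canonical mixture order used for
#' response fingerprints.
#'
#' @param panel a [chemical_panel()].
#' @return integer vector of mixture encodings.
#' @examples
#' length(enumerate_mixtures(chemical_panel(letters[1:8])))  # 255
#' @export
enumerate_mixtures <- function(panel) {
  stopifnot(inherits(panel, "chemical_panel"))
  n <- attr(panel, "size")
  out <- integer(0)
  for (k in seq_len(n)) {
    sets <- utils::combn(n, k)
    out <- c(out, apply(sets, 2L, .mask_from_members))
  }
  as.integer(out)
}
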