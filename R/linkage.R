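#' Glycosidic linkage codes
#'
#' A linkage code identifies a partially methylated alditol acetate (PMAA)
#' derivative by the monosaccharide it came from, its ring form, and the
#' carbon positions that were glycosidically substituted. The canonical
#' string form is the one used throughout plant cell wall linkage analysis:
#' `"4-Glcp"` is glucopyranose linked through C-4, `"2,3,5-Araf"` is
#' arabinofuranose substituted at C-2, C-3 and C-5, and `"t-Galp"` is a
#' terminal (non-reducing end, unsubstituted) galactopyranose.
#'
#' `parse_linkage()` decomposes canonical strings; `format_linkage()` is its
#' inverse, so `format_linkage(parse_linkage(x)) == x` for any valid `x`.
#' Sugars derived from carboxyl-reduced uronic acids (GalA, GlcA — analysed
#' as their 6,6-dideuterio neutral forms) are flagged with `uronic_origin`.
#'
#' @param x character vector of linkage codes, e.g. `c("t-Araf", "4-GalAp")`.
#' @return `parse_linkage()` returns a data.frame with one row per code and
#'   columns `linkage` (canonical form), `sugar`, `ring` (`"p"`/`"f"`),
#'   `positions` (list column of sorted integer vectors; empty = terminal),
#'   `terminal` and `uronic_origin` (logicals).
#' @examples
#' parse_linkage(c("4-Glcp", "t-Araf", "2,3,5-Araf", "4-GalAp"))
#' @export
parse_linkage <- function(x) {
  stopifnot(is.character(x), length(x) >= 1)
  rx <- "^(t|[2-6](,[2-6])*)-(Ara|Xyl|Glc|Gal|Man|Rha|Fuc|GalA|GlcA)(p|f)$"
  bad <- x[!grepl(rx, x)]
  if (length(bad) > 0) {
    stop("invalid linkage code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  pos_part <- sub(rx, "\\1", x)
  sugar <- sub(rx, "\\3", x)
  ring <- sub(rx, "\\4", x)
  positions <- lapply(pos_part, function(p) {
    if (p == "t") integer(0) else as.integer(strsplit(p, ",")[[1]])
  })
  dup <- vapply(positions, anyDuplicated, integer(1)) > 0
  if (any(dup)) {
    stop("duplicated position in linkage code(s): ",
         paste(unique(x[dup]), collapse = ", "), call. = FALSE)
  }
  unsorted <- vapply(positions, is.unsorted, logical(1))
  if (any(unsorted)) {
    stop("non-canonical linkage code(s) (positions must be sorted): ",
         paste(unique(x[unsorted]), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    linkage = x, sugar = sugar, ring = ring,
    terminal = lengths(positions) == 0,
    uronic_origin = sugar %in% c("GalA", "GlcA"),
    stringsAsFactors = FALSE
  )
  out$positions <- positions
  canonical <- format_linkage(out)
  if (!identical(canonical, x)) {
    nc <- x[canonical != x]
    stop("non-canonical linkage code(s) (positions must be sorted, unique): ",
         paste(unique(nc), collapse = ", "), call. = FALSE)
  }
  out[, c("linkage", "sugar", "ring", "positions", "terminal", "uronic_origin")]
}

#' @rdname parse_linkage
#' @param parsed a data.frame as returned by `parse_linkage()`.
#' @export
format_linkage <- function(parsed) {
  stopifnot(is.data.frame(parsed), all(c("sugar", "ring", "positions") %in%
                                         names(parsed)))
  pos <- vapply(parsed$positions, function(p) {
    if (length(p) == 0) "t" else paste(p, collapse = ",")
  }, character(1))
  paste0(pos, "-", parsed$sugar, parsed$ring)
}

#' @rdname parse_linkage
#' @export
is_valid_linkage <- function(x) {
  vapply(x, function(code) {
    !inherits(try(parse_linkage(code), silent = TRUE), "try-error")
  }, logical(1), USE.NAMES = FALSE)
}

# Sorted canonical order for deterministic tie-breaking: plain C-locale
# string order on the canonical form.
linkage_order <- function(x) order(x, method = "radix")
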