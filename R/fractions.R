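#' Cell wall extraction schemes and fraction labels
#'
#' Sequential extraction of a de-starched cell wall (alcohol-insoluble
#' residue, AIR) produces named fractions. Three schemes are built in,
#' matching the extract series used in antibody screening and in linkage
#' analysis, plus a `"whole"` scheme for unfractionated walls:
#'
#' * `"ELISA-series"`: AO, SC, 1M KOH, 4M KOH, CH, 4M KOHPC
#'   (ammonium oxalate, sodium carbonate, two KOH steps, chlorite,
#'   post-chlorite KOH).
#' * `"MAPP-series"`: CDTA, NaOH, cellulase.
#' * `"linkage-series"`: EDTA+Na2CO3 (the pooled chelator/carbonate
#'   extract), 4M KOH, Residue.
#' * `"whole"`: AIR.
#'
#' @param name fraction name, one of the scheme's labels.
#' @param scheme extraction scheme id; if `NULL`, any scheme containing
#'   `name` is accepted.
#' @param pretreatment optional pretreatment flag (e.g. `"NaBD4"` for
#'   borodeuteride reduction before fractionation).
#' @return a `fraction_label` object (a named list with `name`, `scheme`,
#'   `pretreatment`).
#' @examples
#' fraction_label("EDTA+Na2CO3", "linkage-series", pretreatment = "NaBD4")
#' fraction_schemes()
#' @export
fraction_label <- function(name, scheme = NULL, pretreatment = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  schemes <- fraction_schemes()
  if (is.null(scheme)) {
    hits <- names(schemes)[vapply(schemes, function(s) name %in% s, logical(1))]
    if (length(hits) == 0) {
      stop("fraction name '", name, "' belongs to no known scheme; ",
           "pass an explicit scheme to use a custom label", call. = FALSE)
    }
    scheme <- hits[[1]]
  } else if (scheme %in% names(schemes) && !name %in% schemes[[scheme]]) {
    stop("fraction name '", name, "' is not a label of scheme '", scheme,
         "' (allowed: ", paste(schemes[[scheme]], collapse = ", "), ")",
         call. = FALSE)
  }
  structure(
    list(name = name, scheme = scheme, pretreatment = pretreatment),
    class = "fraction_label"
  )
}

#' @rdname fraction_label
#' @export
fraction_schemes <- function() {
  list(
    "ELISA-series"   = c("AO", "SC", "1M KOH", "4M KOH", "CH", "4M KOHPC"),
    "MAPP-series"    = c("CDTA", "NaOH", "cellulase"),
    "linkage-series" = c("EDTA+Na2CO3", "4M KOH", "Residue"),
    "whole"          = "AIR"
  )
}

#' @export
print.fraction_label <- function(x, ...) {
  pre <- if (is.null(x$pretreatment)) "" else paste0(" [", x$pretreatment, "]")
  cat("<fraction> ", x$name, " (", x$scheme, ")", pre, "\n", sep = "")
  invisible(x)
}

# Accept either a fraction_label or a bare name string.
as_fraction_name <- function(fraction) {
  if (inherits(fraction, "fraction_label")) fraction$name
  else if (is.character(fraction) && length(fraction) == 1) fraction
  else stop("'fraction' must be a fraction_label or a single name string",
            call. = FALSE)
}
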