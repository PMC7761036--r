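#' Read and write GC-MS PMAA peak tables
#'
#' A peak table holds one row per integrated chromatographic peak from a
#' PMAA GC-MS run: an identifier, retention time in minutes, detector area,
#' and optionally a centroided spectrum and an already-assigned linkage.
#' Spectra are encoded in a single cell as `"mz:intensity;mz:intensity;..."`
#' with m/z strictly increasing.
#'
#' @param path path to a CSV (or TSV, inferred from the extension) file.
#' @param dialect named character vector remapping the expected column names
#'   `peak_id`, `rt_min`, `area`, `spectrum`, `linkage` onto the file's
#'   actual column names, e.g. `c(area = "Area.1")`. Unmentioned columns
#'   keep their default names.
#' @return a tibble of peak records with columns `peak_id` (character),
#'   `rt_min`, `area` (numeric), `spectrum` (list of two-column matrices or
#'   `NULL`s), `linkage` (character or `NA`); row order preserved.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("peak_id,rt_min,area", "p1,10.2,200", "p2,11.5,300"), f)
#' parse_peak_table(f)
#' @export
parse_peak_table <- function(path, dialect = character(0)) {
  if (!file.exists(path)) stop("peak table not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  cols <- c(peak_id = "peak_id", rt_min = "rt_min", area = "area",
            spectrum = "spectrum", linkage = "linkage")
  if (length(dialect) > 0) cols[names(dialect)] <- dialect
  for (req in c("peak_id", "rt_min", "area")) {
    if (!cols[[req]] %in% names(raw)) {
      stop("peak table is missing required column '", cols[[req]], "'",
           call. = FALSE)
    }
  }
  n <- nrow(raw)
  area <- suppressWarnings(as.numeric(raw[[cols[["area"]]]]))
  rt <- suppressWarnings(as.numeric(raw[[cols[["rt_min"]]]]))
  if (n > 0) {
    bad <- which(is.na(area) | area < 0)
    if (length(bad) > 0) {
      stop("negative or non-numeric area in peak table row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (anyNA(rt)) {
      stop("non-numeric retention time in peak table row(s) ",
           paste(which(is.na(rt)), collapse = ", "), call. = FALSE)
    }
  }
  spec_col <- cols[["spectrum"]]
  spectra <- if (spec_col %in% names(raw) && n > 0) {
    lapply(seq_len(n), function(i) parse_spectrum_string(raw[[spec_col]][i]))
  } else {
    rep(list(NULL), n)
  }
  link_col <- cols[["linkage"]]
  linkage <- if (link_col %in% names(raw) && n > 0) {
    lk <- raw[[link_col]]
    lk[!nzchar(trimws(lk)) | is.na(lk)] <- NA_character_
    ok <- !is.na(lk)
    if (any(ok)) parse_linkage(lk[ok])  # validates; errors name the token
    lk
  } else {
    rep(NA_character_, n)
  }
  tibble::tibble(
    peak_id = as.character(raw[[cols[["peak_id"]]]]),
    rt_min = if (n > 0) rt else numeric(0),
    area = if (n > 0) area else numeric(0),
    spectrum = spectra,
    linkage = linkage
  )
}

#' @rdname parse_peak_table
#' @param peaks a peak tibble as returned by `parse_peak_table()`.
#' @export
write_peak_table <- function(peaks, path) {
  stopifnot(is.data.frame(peaks))
  out <- data.frame(
    peak_id = peaks$peak_id,
    rt_min = peaks$rt_min,
    area = peaks$area,
    spectrum = vapply(peaks$spectrum, deparse_spectrum_string, character(1)),
    linkage = ifelse(is.na(peaks$linkage), "", peaks$linkage),
    stringsAsFactors = FALSE
  )
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# "mz:int;mz:int" -> two-column matrix (mz, intensity); "" -> NULL
parse_spectrum_string <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(NULL)
  pairs <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  parts <- strsplit(pairs, ":", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("malformed spectrum cell (expected 'mz:intensity;...'): ", s,
         call. = FALSE)
  }
  mz <- as.numeric(vapply(parts, `[[`, character(1), 1))
  int <- as.numeric(vapply(parts, `[[`, character(1), 2))
  validate_spectrum(cbind(mz = mz, intensity = int))
}

deparse_spectrum_string <- function(spec) {
  if (is.null(spec)) return("")
  paste(paste0(format(spec[, 1], trim = TRUE, scientific = FALSE), ":",
               format(spec[, 2], trim = TRUE, scientific = FALSE)),
        collapse = ";")
}

validate_spectrum <- function(spec) {
  if (anyNA(spec)) stop("spectrum contains non-numeric values", call. = FALSE)
  if (any(spec[, 2] < 0)) stop("spectrum intensities must be >= 0", call. = FALSE)
  if (is.unsorted(spec[, 1], strictly = TRUE)) {
    stop("spectrum m/z values must be strictly increasing", call. = FALSE)
  }
  spec
}
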