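#' Spectral matching of PMAA electron-impact spectra
#'
#' Peaks are assigned to linkages by comparing their EI fragmentation
#' patterns (and retention times) with those of authentic standards.
#' `match_spectrum()` scores a query spectrum against every entry of a
#' reference library with a cosine similarity computed over greedily
#' paired fragment ions: candidate peak pairs within `mz_tolerance` are
#' accepted in order of decreasing intensity product, each peak used at
#' most once, and the cosine is the sum of paired intensity products over
#' the product of the full spectra's Euclidean norms. Identical spectra
#' score 1; spectra sharing no fragments score 0.
#'
#' @param query two-column matrix `(mz, intensity)` with strictly
#'   increasing m/z.
#' @param library a spectrum library as returned by
#'   [read_spectrum_library()]: a list of entries, each a list with
#'   `linkage` (canonical code), `spectrum` (matrix), and optionally
#'   `rt_min` and `rt_window` (minutes).
#' @param mz_tolerance maximum m/z difference (Da) for two fragments to be
#'   paired; default 0.5 (unit-resolution quadrupole data).
#' @return a tibble with columns `linkage`, `similarity`, `rt_min`,
#'   `rt_window`, sorted by decreasing similarity; ties broken by linkage
#'   code string order.
#' @examples
#' lib <- list(list(linkage = "4-Glcp",
#'                  spectrum = cbind(mz = c(102, 118, 233), intensity = c(1, .6, .3))))
#' match_spectrum(cbind(c(102, 118, 233), c(1, .6, .3)), lib)
#' @export
match_spectrum <- function(query, library, mz_tolerance = 0.5) {
  if (is.null(query) || nrow(query) == 0) {
    stop("query spectrum is empty", call. = FALSE)
  }
  if (length(library) == 0) stop("spectrum library is empty", call. = FALSE)
  stopifnot(mz_tolerance > 0)
  validate_spectrum(query)
  sims <- vapply(library, function(entry) {
    cosine_greedy(query, entry$spectrum, mz_tolerance)
  }, numeric(1))
  out <- tibble::tibble(
    linkage = vapply(library, `[[`, character(1), "linkage"),
    similarity = sims,
    rt_min = vapply(library, function(e) e$rt_min %||% NA_real_, numeric(1)),
    rt_window = vapply(library, function(e) e$rt_window %||% NA_real_,
                       numeric(1))
  )
  out[order(-out$similarity, out$linkage, method = "radix"), ]
}

# Greedy nearest-peak cosine: pair peaks within tolerance by decreasing
# intensity product, each peak used once.
cosine_greedy <- function(a, b, tol) {
  validate_spectrum(b)
  na <- sqrt(sum(a[, 2]^2))
  nb <- sqrt(sum(b[, 2]^2))
  if (na == 0 || nb == 0) return(0)
  d <- abs(outer(a[, 1], b[, 1], "-"))
  cand <- which(d <= tol, arr.ind = TRUE)
  if (nrow(cand) == 0) return(0)
  prod <- a[cand[, 1], 2] * b[cand[, 2], 2]
  ord <- order(-prod, d[cand])
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  dot <- 0
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      dot <- dot + prod[k]
    }
  }
  dot / (na * nb)
}

#' Assign linkages to peaks by library matching
#'
#' Runs [match_spectrum()] for every peak carrying a spectrum and writes
#' the top hit into the `linkage` column when it passes the similarity
#' threshold and, when the library entry provides a retention window, when
#' the peak's retention time falls within `rt_min ± rt_window`. Peaks with
#' a pre-existing assignment are left untouched.
#'
#' @inheritParams match_spectrum
#' @param peaks a peak tibble from [parse_peak_table()].
#' @param threshold minimum cosine similarity for assignment (default 0.7).
#' @return the peak tibble with `linkage` filled in and a `match_score`
#'   column added.
#' @export
assign_linkages <- function(peaks, library, mz_tolerance = 0.5,
                            threshold = 0.7) {
  stopifnot(is.data.frame(peaks), threshold >= 0, threshold <= 1)
  peaks$match_score <- NA_real_
  for (i in seq_len(nrow(peaks))) {
    if (!is.na(peaks$linkage[i]) || is.null(peaks$spectrum[[i]])) next
    ranked <- match_spectrum(peaks$spectrum[[i]], library, mz_tolerance)
    top <- ranked[1, ]
    rt_ok <- is.na(top$rt_min) || is.na(top$rt_window) ||
      abs(peaks$rt_min[i] - top$rt_min) <= top$rt_window
    if (top$similarity >= threshold && rt_ok) {
      peaks$linkage[i] <- top$linkage
      peaks$match_score[i] <- top$similarity
    }
  }
  peaks
}

#' Read a PMAA reference spectrum library
#'
#' Two plain-text formats are supported. An MSP-style text file is a
#' sequence of blocks:
#' ```
#' NAME: 4-Glcp
#' RT: 24.1
#' RT_WINDOW: 0.5
#' Num Peaks: 3
#' 102 999; 118 620; 233 310
#' ```
#' (`RT`/`RT_WINDOW` optional; peak lines are `mz intensity` pairs
#' separated by `;` or newlines). Alternatively a JSON array of objects
#' with fields `linkage`, `rt_min`, `rt_window`, `mz`, `intensity`.
#'
#' @param path path to a `.msp`/`.txt` or `.json` library file.
#' @return a list of entries, each a list with `linkage`, `spectrum`
#'   (two-column matrix), `rt_min`, `rt_window`.
#' @export
read_spectrum_library <- function(path) {
  if (!file.exists(path)) stop("spectrum library not found: ", path,
                               call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    entries <- lapply(seq_len(nrow(raw)), function(i) {
      list(
        linkage = raw$linkage[i],
        spectrum = validate_spectrum(cbind(mz = unlist(raw$mz[i]),
                                           intensity = unlist(raw$intensity[i]))),
        rt_min = if ("rt_min" %in% names(raw)) raw$rt_min[i] else NA_real_,
        rt_window = if ("rt_window" %in% names(raw)) raw$rt_window[i]
                    else NA_real_
      )
    })
  } else {
    entries <- parse_msp(readLines(path, warn = FALSE))
  }
  parse_linkage(vapply(entries, `[[`, character(1), "linkage"))  # validate
  entries
}

parse_msp <- function(lines) {
  lines <- trimws(lines)
  starts <- grep("^NAME\\s*:", lines, ignore.case = TRUE)
  if (length(starts) == 0) {
    stop("no NAME: blocks found in MSP library", call. = FALSE)
  }
  ends <- c(starts[-1] - 1, length(lines))
  lapply(seq_along(starts), function(k) {
    block <- lines[starts[k]:ends[k]]
    get_field <- function(key) {
      hit <- grep(paste0("^", key, "\\s*:"), block, ignore.case = TRUE)
      if (length(hit) == 0) return(NA_character_)
      trimws(sub("^[^:]*:", "", block[hit[1]]))
    }
    name <- get_field("NAME")
    np_line <- grep("^Num Peaks\\s*:", block, ignore.case = TRUE)
    if (length(np_line) == 0) {
      stop("MSP block '", name, "' has no 'Num Peaks:' line", call. = FALSE)
    }
    n_peaks <- as.integer(trimws(sub("^[^:]*:", "", block[np_line[1]])))
    peak_text <- paste(block[seq(np_line[1] + 1, length(block))],
                       collapse = " ; ")
    toks <- strsplit(peak_text, "[;[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals) || length(vals) %% 2 != 0) {
      stop("malformed peak list in MSP block '", name, "'", call. = FALSE)
    }
    m <- matrix(vals, ncol = 2, byrow = TRUE)
    if (nrow(m) != n_peaks) {
      stop("MSP block '", name, "' declares ", n_peaks, " peaks but lists ",
           nrow(m), call. = FALSE)
    }
    list(
      linkage = name,
      spectrum = validate_spectrum(cbind(mz = m[, 1], intensity = m[, 2])),
      rt_min = suppressWarnings(as.numeric(get_field("RT"))),
      rt_window = suppressWarnings(as.numeric(get_field("RT_WINDOW")))
    )
  })
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0) y else x
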