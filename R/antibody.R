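#' Antibody-based glycome screens
#'
#' Both screen formats supported here — ELISA panels of cell-wall-directed
#' monoclonal antibodies (mAbs) against sequential extracts, and MicroArray
#' Polymer Profiling (MAPP) of extracts printed on nitrocellulose — produce
#' an OD reading per probe x extract x replicate (x dilution for MAPP).
#' The `antibody_array` container is a tidy tibble with columns `mab_id`,
#' `epitope_group`, `extract`, `replicate`, `dilution`, `od` and optionally
#' `background`, plus a processing log attribute.
#'
#' @param readings data.frame with at least `mab_id`, `epitope_group`,
#'   `extract`, `od`; `replicate` and `dilution` default to 1,
#'   `background` to absent.
#' @param group_order optional ordered character vector of epitope groups
#'   (rows of heatmaps follow this order); defaults to order of first
#'   appearance.
#' @return an `antibody_array` tibble.
#' @export
antibody_array <- function(readings, group_order = NULL) {
  stopifnot(is.data.frame(readings))
  need <- c("mab_id", "epitope_group", "extract", "od")
  missing_cols <- setdiff(need, names(readings))
  if (length(missing_cols) > 0) {
    stop("readings are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(readings)
  if (!"replicate" %in% names(out)) out$replicate <- 1L
  if (!"dilution" %in% names(out)) out$dilution <- 1L
  if (any(out$od < 0)) stop("OD readings must be >= 0", call. = FALSE)
  n_dil <- length(unique(out$dilution))
  if (n_dil < 1 || n_dil > 4) {
    stop("between 1 and 4 dilutions are supported; found ", n_dil,
         call. = FALSE)
  }
  # a mAb must carry a single epitope group
  grp <- unique(out[, c("mab_id", "epitope_group")])
  if (anyDuplicated(grp$mab_id)) {
    stop("mAb(s) listed under more than one epitope group: ",
         paste(unique(grp$mab_id[duplicated(grp$mab_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(group_order)) group_order <- unique(out$epitope_group)
  unknown <- setdiff(unique(out$epitope_group), group_order)
  if (length(unknown) > 0) {
    stop("epitope group(s) not in group order: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  attr(out, "group_order") <- group_order
  attr(out, "log") <- character(0)
  class(out) <- c("antibody_array", class(out))
  out
}

array_log <- function(array, msg) {
  attr(array, "log") <- c(attr(array, "log"), msg)
  array
}

rebuild_array <- function(data, template) {
  out <- tibble::as_tibble(data)
  attr(out, "group_order") <- attr(template, "group_order")
  attr(out, "log") <- attr(template, "log")
  class(out) <- c("antibody_array", class(out))
  out
}

#' Subtract assay background from an antibody array
#'
#' Removes the no-antigen (ELISA) or no-primary-antibody (MAPP) signal
#' from every reading: `corrected = max(0, od - background)`. Negative
#' corrected values are floored at zero — below-background readings mean
#' no binding. The background can be supplied per cell (a `background`
#' column), per probe or per extract (a named vector), or as a single
#' scalar; the mode used is recorded in the processing log, and the
#' `background` column is zeroed afterwards so the operation is
#' idempotent.
#'
#' @param array an [antibody_array()].
#' @param background `NULL` to use the array's `background` column, a
#'   scalar, or a named numeric vector keyed by `mab_id` or by `extract`.
#' @return the corrected `antibody_array`.
#' @export
subtract_background <- function(array, background = NULL) {
  stopifnot(inherits(array, "antibody_array"))
  if (is.null(background)) {
    if (!"background" %in% names(array)) {
      stop("no 'background' column and no background argument given",
           call. = FALSE)
    }
    if (anyNA(array$background)) {
      bad <- which(is.na(array$background))[1]
      stop("missing background for cell ", array$mab_id[bad], " x ",
           array$extract[bad], call. = FALSE)
    }
    bg <- array$background
    mode <- "per-cell"
  } else if (length(background) == 1 && is.null(names(background))) {
    bg <- rep(background, nrow(array))
    mode <- "scalar"
  } else if (all(names(background) %in% array$mab_id) ||
             all(array$mab_id %in% names(background))) {
    bg <- background[array$mab_id]
    mode <- "per-probe"
  } else if (all(array$extract %in% names(background))) {
    bg <- background[array$extract]
    mode <- "per-extract"
  } else {
    stop("background names match neither probes nor extracts", call. = FALSE)
  }
  if (anyNA(bg)) {
    bad <- which(is.na(bg))[1]
    stop("missing background for cell ", array$mab_id[bad], " x ",
         array$extract[bad], call. = FALSE)
  }
  array$od <- pmax(0, array$od - as.numeric(bg))
  array$background <- 0
  array_log(array, paste0("background subtracted (", mode,
                          "); negatives floored at 0"))
}

#' Average replicate wells
#'
#' Per probe x extract x dilution mean over replicates; the replicate
#' count is retained in an `n_rep` column.
#'
#' @param array an [antibody_array()].
#' @return an `antibody_array` with one row per probe x extract x
#'   dilution.
#' @export
average_replicates <- function(array) {
  stopifnot(inherits(array, "antibody_array"))
  key <- interaction(array$mab_id, array$extract, array$dilution, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(array)), key), function(idx) {
    data.frame(
      mab_id = array$mab_id[idx[1]],
      epitope_group = array$epitope_group[idx[1]],
      extract = array$extract[idx[1]],
      replicate = 1L,
      dilution = array$dilution[idx[1]],
      od = mean(array$od[idx]),
      n_rep = length(idx),
      stringsAsFactors = FALSE
    )
  }))
  rownames(agg) <- NULL
  out <- rebuild_array(agg, array)
  array_log(out, "replicates averaged")
}

#' Collapse dilution series to one value per probe and extract
#'
#' MAPP arrays print each extract in several dilutions; a single signal
#' per probe x extract is obtained by taking the strongest spot
#' (`mode = "max"`, the default — the usual in-range-spot convention),
#' the mean across dilutions, or one named dilution.
#'
#' @param array an [antibody_array()].
#' @param mode `"max"`, `"mean"`, or a dilution identifier present in the
#'   array's `dilution` column.
#' @return an `antibody_array` with one row per probe x extract.
#' @export
collapse_dilutions <- function(array, mode = "max") {
  stopifnot(inherits(array, "antibody_array"))
  if (!mode %in% c("max", "mean")) {
    if (!mode %in% as.character(unique(array$dilution))) {
      stop("dilution '", mode, "' not present in the array", call. = FALSE)
    }
    array <- array[as.character(array$dilution) == mode, ]
  }
  key <- interaction(array$mab_id, array$extract, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(array)), key), function(idx) {
    od <- switch(mode, max = max(array$od[idx]), mean = mean(array$od[idx]),
                 array$od[idx[1]])
    data.frame(
      mab_id = array$mab_id[idx[1]],
      epitope_group = array$epitope_group[idx[1]],
      extract = array$extract[idx[1]],
      replicate = array$replicate[idx[1]],
      dilution = 1L,
      od = od,
      n_rep = if ("n_rep" %in% names(array)) array$n_rep[idx[1]] else 1L,
      stringsAsFactors = FALSE
    )
  }))
  rownames(agg) <- NULL
  out <- rebuild_array(agg, array)
  array_log(out, paste0("dilutions collapsed (mode=", mode, ")"))
}

#' Build an epitope-grouped heatmap matrix
#'
#' Arranges corrected mean signals into a probe x extract matrix whose
#' rows are grouped by epitope (in the configured group order, probes
#' alphabetical within a group) and whose columns follow the extract
#' series order. Values are the corrected means, untransformed — the map
#' is a lossless export of the processed array.
#'
#' @param array a background-subtracted, replicate-averaged,
#'   dilution-collapsed [antibody_array()] (one row per probe x extract).
#' @param group_order ordered epitope groups; defaults to the array's.
#' @param extract_order ordered extract columns; defaults to the ELISA
#'   series AO, SC, 1M KOH, 4M KOH, CH, 4M KOHPC when all extracts belong
#'   to it, otherwise to first appearance.
#' @return a numeric matrix with a `groups` attribute (epitope group per
#'   row).
#' @export
build_heatmap <- function(array, group_order = NULL, extract_order = NULL) {
  stopifnot(inherits(array, "antibody_array"))
  key <- paste(array$mab_id, array$extract)
  if (anyDuplicated(key)) {
    stop("array has multiple rows per probe x extract; average replicates ",
         "and collapse dilutions first", call. = FALSE)
  }
  if (is.null(group_order)) group_order <- attr(array, "group_order")
  unknown <- setdiff(unique(array$epitope_group), group_order)
  if (length(unknown) > 0) {
    stop("probe(s) with unknown epitope group: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  extracts <- unique(array$extract)
  if (is.null(extract_order)) {
    elisa <- fraction_schemes()[["ELISA-series"]]
    extract_order <- if (all(extracts %in% elisa)) {
      elisa[elisa %in% extracts]
    } else {
      extracts
    }
  }
  probes <- unique(array[, c("mab_id", "epitope_group")])
  probes <- probes[order(match(probes$epitope_group, group_order),
                         probes$mab_id, method = "radix"), ]
  m <- matrix(NA_real_, nrow = nrow(probes), ncol = length(extract_order),
              dimnames = list(probes$mab_id, extract_order))
  for (i in seq_len(nrow(array))) {
    m[array$mab_id[i], array$extract[i]] <- array$od[i]
  }
  attr(m, "groups") <- stats::setNames(probes$epitope_group, probes$mab_id)
  m
}

#' Draw a heatmap of a processed antibody array
#'
#' @param matrix output of [build_heatmap()].
#' @param ... passed to [pheatmap::pheatmap()].
#' @export
plot_heatmap <- function(matrix, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_heatmap() requires pheatmap", call. = FALSE)
  }
  ann <- data.frame(group = attr(matrix, "groups"))
  pheatmap::pheatmap(matrix, cluster_rows = FALSE, cluster_cols = FALSE,
                     annotation_row = ann, ...)
}
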