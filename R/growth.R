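#' Bacterial growth curves on defined carbohydrate sources
#'
#' Growth proficiency on an insoluble substrate is assessed from manual
#' OD600 readings at a few time points (0, 5 and 24 h by default),
#' in replicate, alongside no-inoculum blanks of the same medium.
#'
#' @param isolate isolate identifier.
#' @param condition carbon source, e.g. `"glucose"`, `"MM"` (no
#'   carbohydrate) or `"CM NSP"`.
#' @param time_h numeric vector of time points (hours), non-decreasing
#'   within a replicate.
#' @param od600 OD600 readings, one per time point (recycled across
#'   `replicate`).
#' @param replicate replicate index per reading.
#' @param blank_od no-inoculum background reading per time point (same
#'   length as `time_h` after recycling).
#' @return a `growth_curve` tibble with columns `isolate`, `condition`,
#'   `replicate`, `time_h`, `od600`, `blank_od`.
#' @export
growth_curve <- function(isolate, condition, time_h, od600,
                         replicate = 1L, blank_od = 0) {
  n <- length(time_h)
  stopifnot(length(od600) == n)
  out <- tibble::tibble(
    isolate = isolate, condition = condition,
    replicate = rep_len(as.integer(replicate), n),
    time_h = time_h, od600 = od600,
    blank_od = rep_len(blank_od, n)
  )
  for (r in unique(out$replicate)) {
    tt <- out$time_h[out$replicate == r]
    if (is.unsorted(tt)) {
      stop("time points must be non-decreasing within a replicate",
           call. = FALSE)
    }
  }
  if (any(out$od600 < 0) || any(out$blank_od < 0)) {
    stop("OD readings must be >= 0", call. = FALSE)
  }
  class(out) <- c("growth_curve", class(out))
  out
}

#' @rdname growth_curve
#' @param curve a `growth_curve`.
#' @return `subtract_blank()` returns the curve with
#'   `od600 = max(0, od600 - blank_od)` and `blank_od` zeroed.
#' @export
subtract_blank <- function(curve) {
  stopifnot(inherits(curve, "growth_curve"))
  curve$od600 <- pmax(0, curve$od600 - curve$blank_od)
  curve$blank_od <- 0
  curve
}

# mean corrected OD at a required time point
od_at <- function(curve, t) {
  hit <- abs(curve$time_h - t) < 1e-9
  if (!any(hit)) {
    stop("growth curve for ", curve$isolate[1], " (", curve$condition[1],
         ") has no reading at ", t, " h", call. = FALSE)
  }
  mean(curve$od600[hit])
}

#' Classify growth proficiency on a test substrate
#'
#' An isolate is called a `"high-efficiency"` utilizer of the test
#' substrate when its blank-corrected OD600 at 24 h reaches at least
#' `threshold_fraction` of the glucose control's 24 h OD *and* clears the
#' absolute floor `min_od`; `"low"` when it clears the floor but not the
#' fraction (growth to low density); `"none"` otherwise. Both thresholds
#' are explicit, logged parameters — the qualitative moderate/low/no
#' growth split depends on them.
#'
#' @param curve blank-corrected [growth_curve()] on the test substrate.
#' @param control blank-corrected [growth_curve()] of the same isolate on
#'   the glucose control.
#' @param threshold_fraction fraction of the control's 24 h OD required
#'   for the high-efficiency call (default 0.25).
#' @param min_od absolute OD600 floor separating low growth from no
#'   growth (default 0.1).
#' @param at time point (hours) at which growth is judged (default 24).
#' @return a one-row tibble `isolate, condition, od, control_od, ratio,
#'   label, threshold_fraction, min_od`.
#' @export
classify_growth <- function(curve, control, threshold_fraction = 0.25,
                            min_od = 0.1, at = 24) {
  stopifnot(inherits(curve, "growth_curve"), inherits(control, "growth_curve"))
  od <- od_at(curve, at)
  ctrl <- od_at(control, at)
  if (ctrl <= 0) stop("control 24 h OD must be > 0", call. = FALSE)
  label <- if (od >= threshold_fraction * ctrl && od >= min_od) {
    "high-efficiency"
  } else if (od >= min_od) {
    "low"
  } else {
    "none"
  }
  tibble::tibble(
    isolate = curve$isolate[1], condition = curve$condition[1],
    od = od, control_od = ctrl, ratio = od / ctrl, label = label,
    threshold_fraction = threshold_fraction, min_od = min_od
  )
}

#' Read growth curves from CSV
#'
#' Expects columns `isolate, condition, replicate, time_h, od600,
#' blank_od`.
#'
#' @param path CSV file path.
#' @return a named list of [growth_curve()] objects, one per
#'   isolate x condition.
#' @export
read_growth_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("isolate", "condition", "replicate", "time_h", "od600", "blank_od")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("growth table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- paste(raw$isolate, raw$condition, sep = " | ")
  lapply(split(raw, key), function(d) {
    d <- d[order(d$replicate, d$time_h), ]
    growth_curve(d$isolate[1], d$condition[1], d$time_h, d$od600,
                 d$replicate, d$blank_od)
  })
}
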