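#' Molar percent linkage profiles
#'
#' A linkage profile gives the relative molar abundance (molar%) of each
#' detected glycosidic linkage in one sample or cell-wall fraction,
#' together with replicate statistics. It is represented as a tibble with
#' columns `linkage`, `molar_mean`, `molar_sd`, `n`, carrying the fraction
#' label as an attribute.
#'
#' @param linkage character vector of canonical linkage codes.
#' @param molar_mean molar% values (mean over replicates), in `[0, 100]`,
#'   summing to 100 within `sum_tolerance`.
#' @param molar_sd standard deviations (0 for single measurements).
#' @param n replicate counts (>= 1).
#' @param fraction a [fraction_label()] or fraction name string.
#' @param sum_tolerance allowed deviation of `sum(molar_mean)` from 100;
#'   default 0.5 absorbs rounding in hand-entered tables.
#' @return a `linkage_profile` tibble.
#' @export
linkage_profile <- function(linkage, molar_mean, molar_sd = 0, n = 1L,
                            fraction = "AIR", sum_tolerance = 0.5) {
  stopifnot(length(linkage) == length(molar_mean))
  parse_linkage(linkage)
  if (anyDuplicated(linkage)) {
    stop("duplicated linkage codes in profile: ",
         paste(unique(linkage[duplicated(linkage)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(molar_mean < 0 | molar_mean > 100)) {
    stop("molar% values must lie in [0, 100]", call. = FALSE)
  }
  molar_sd <- rep_len(molar_sd, length(linkage))
  n <- rep_len(as.integer(n), length(linkage))
  if (any(molar_sd < 0)) stop("molar_sd must be >= 0", call. = FALSE)
  if (any(n < 1)) stop("replicate count n must be >= 1", call. = FALSE)
  total <- sum(molar_mean)
  if (abs(total - 100) > sum_tolerance) {
    stop(sprintf("molar%% values sum to %.3f, not 100 (tolerance %.3g)",
                 total, sum_tolerance), call. = FALSE)
  }
  out <- tibble::tibble(linkage = unname(linkage),
                        molar_mean = unname(molar_mean),
                        molar_sd = unname(molar_sd), n = unname(n))
  attr(out, "fraction") <- as_fraction_name(fraction)
  class(out) <- c("linkage_profile", class(out))
  out
}

#' @rdname linkage_profile
#' @param x object to test or print.
#' @export
is_linkage_profile <- function(x) inherits(x, "linkage_profile")

#' @export
print.linkage_profile <- function(x, ...) {
  cat("<linkage_profile> fraction:", attr(x, "fraction"),
      "| total:", format(sum(x$molar_mean), digits = 6), "\n")
  NextMethod()
}

#' Compute molar percent linkage composition from assigned peaks
#'
#' Converts detector peak areas into relative molar composition. Areas of
#' peaks assigned to the same linkage are summed, divided by that
#' linkage's response factor (default 1: raw relative areas, the usual
#' reading of PMAA data unless an effective-carbon-response table is
#' supplied), and normalised so the profile sums to exactly 100.
#'
#' @param peaks a peak tibble in which every row has a `linkage`
#'   assignment (see [assign_linkages()]).
#' @param response_factors optional named numeric vector of positive
#'   per-linkage response factors; unlisted linkages default to 1.
#' @param fraction fraction label attached to the resulting profile.
#' @return a [linkage_profile()] with `n = 1` and `molar_sd = 0`.
#' @examples
#' pk <- tibble::tibble(peak_id = c("a", "b", "c"), rt_min = 1:3,
#'                      area = c(2, 3, 5), spectrum = list(NULL, NULL, NULL),
#'                      linkage = c("t-Araf", "5-Araf", "4-Galp"))
#' compute_molar_composition(pk)
#' @export
compute_molar_composition <- function(peaks, response_factors = NULL,
                                      fraction = "AIR") {
  stopifnot(is.data.frame(peaks))
  unassigned <- is.na(peaks$linkage)
  if (any(unassigned)) {
    stop("unassigned peak(s): ",
         paste(peaks$peak_id[unassigned], collapse = ", "), call. = FALSE)
  }
  if (any(peaks$area < 0)) stop("peak areas must be >= 0", call. = FALSE)
  by_linkage <- tapply(peaks$area, peaks$linkage, sum)
  linkages <- names(by_linkage)
  factors <- rep(1, length(linkages))
  if (!is.null(response_factors)) {
    if (any(response_factors <= 0)) {
      stop("response factors must be > 0", call. = FALSE)
    }
    hit <- linkages %in% names(response_factors)
    factors[hit] <- response_factors[linkages[hit]]
  }
  adjusted <- as.numeric(by_linkage) / factors
  total <- sum(adjusted)
  if (total <= 0) stop("total adjusted peak area is zero", call. = FALSE)
  ord <- linkage_order(linkages)
  linkage_profile(
    linkage = linkages[ord],
    molar_mean = 100 * adjusted[ord] / total,
    molar_sd = 0, n = 1L, fraction = fraction,
    sum_tolerance = 1e-9
  )
}

#' Aggregate replicate linkage profiles
#'
#' Combines replicate profiles of the same fraction into per-linkage mean
#' and sample standard deviation (n - 1 denominator; `sd = 0` when a
#' single replicate is given). A linkage absent from a replicate is a
#' measured zero in that replicate, not missing data — molar% is
#' compositional, so non-detection contributes 0 to the mean.
#'
#' @param profiles list of [linkage_profile()] objects sharing one
#'   fraction label.
#' @return a [linkage_profile()] with `n` equal to the number of
#'   replicates.
#' @export
aggregate_replicates <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  if (!all(vapply(profiles, is_linkage_profile, logical(1)))) {
    stop("all elements must be linkage_profile objects", call. = FALSE)
  }
  fracs <- unique(vapply(profiles, attr, character(1), "fraction"))
  if (length(fracs) != 1) {
    stop("profiles come from different fractions: ",
         paste(fracs, collapse = ", "), call. = FALSE)
  }
  n_rep <- length(profiles)
  all_linkages <- sort(unique(unlist(lapply(profiles, `[[`, "linkage"))),
                       method = "radix")
  values <- vapply(profiles, function(p) {
    v <- stats::setNames(rep(0, length(all_linkages)), all_linkages)
    v[p$linkage] <- p$molar_mean
    v
  }, numeric(length(all_linkages)))
  values <- matrix(values, nrow = length(all_linkages),
                   dimnames = list(all_linkages, NULL))
  means <- rowMeans(values)
  sds <- if (n_rep == 1) rep(0, length(all_linkages)) else apply(values, 1, stats::sd)
  linkage_profile(all_linkages, means, sds, n = n_rep, fraction = fracs,
                  sum_tolerance = 0.5)
}

#' @rdname linkage_profile
#' @param profile a `linkage_profile`.
#' @param path output CSV path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(is_linkage_profile(profile))
  out <- data.frame(fraction = attr(profile, "fraction"),
                    linkage = profile$linkage,
                    molar_mean = profile$molar_mean,
                    molar_sd = profile$molar_sd,
                    n = profile$n)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname linkage_profile
#' @export
read_profile <- function(path, sum_tolerance = 0.5) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fraction", "linkage", "molar_mean", "molar_sd", "n")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("profile CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  frac <- unique(raw$fraction)
  if (length(frac) != 1) {
    stop("profile CSV must contain exactly one fraction; found: ",
         paste(frac, collapse = ", "), call. = FALSE)
  }
  linkage_profile(raw$linkage, raw$molar_mean, raw$molar_sd, raw$n,
                  fraction = frac, sum_tolerance = sum_tolerance)
}
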