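#' Allocate linkage molar percentages to polysaccharide classes
#'
#' The central inverse step of cell-wall linkage analysis: each linkage's
#' molar% is distributed over the polysaccharide classes that can contain
#' it, using a deterministic three-pass procedure.
#'
#' **Pass 1 (exclusive linkages).** A linkage mapping to exactly one class
#' (after fraction overrides) gives that class its full molar%.
#'
#' **Pass 2 (stoichiometric rules, fixed order).**
#' (a) *4-GalAp* is split between the two pectin backbones: RG-I receives
#' `min(4-GalAp, 2-Rhap + 2,4-Rhap)` — the alternating
#' \[2)-Rha-(1,4)-GalA-(1\] backbone pairs one galacturonosyl residue with
#' each rhamnosyl residue — and the remainder is homogalacturonan.
#' (b) *4-Glcp* is consumed by xyloglucan up to `4,6-Glcp *
#' xg_unbranched_ratio` (the XXXG motif has one unbranched backbone
#' glucose per three xylosylated ones), then by heteromannan up to
#' `4-Manp * glc_man_ratio` (glucomannan backbone stoichiometry), and the
#' remainder is cellulose — except in fractions where the CE x 4-Glcp
#' pair is overridden (the chelator/carbonate and 4 M KOH extracts, where
#' cellulose does not solubilise), in which case the remainder goes to
#' xyloglucan.
#' (c) *Shared terminal residues* (t-Araf, t-Galp, t-Fucp, ... wherever a
#' terminal linkage still maps to several classes) are split across the
#' candidate classes in proportion to each class's branch-point demand:
#' the weighted sum of that class's already-allocated demand-set linkages
#' (e.g. arabinan demands t-Araf in proportion to its 2,5-Araf +
#' 2,3,5-Araf branch points). If every candidate's demand is zero the
#' full amount goes to the first candidate in assignment-table row order.
#'
#' **Pass 3.** Linkages absent from the table fall into the unassigned
#' (UA) residual.
#'
#' Every row of the returned matrix conserves its linkage's input molar%
#' exactly (to 1e-9).
#'
#' @param profile a [linkage_profile()].
#' @param table an `assignment_table` (default [default_assignment_table()]).
#' @param fraction fraction label used to apply overrides; defaults to the
#'   profile's own fraction attribute.
#' @return an `allocation_matrix`: numeric matrix linkage x class (columns
#'   are [polysaccharide_classes()], UA last), with attributes `fraction`
#'   and `input` (the input molar% vector).
#' @examples
#' prof <- linkage_profile(c("2-Rhap", "2,4-Rhap", "4-GalAp", "t-GalAp"),
#'                         c(10, 5, 40, 2) / 0.57, fraction = "AIR")
#' allocate_linkages(prof)
#' @export
allocate_linkages <- function(profile, table = default_assignment_table(),
                              fraction = NULL) {
  stopifnot(is_linkage_profile(profile), inherits(table, "assignment_table"))
  if (is.null(fraction)) fraction <- attr(profile, "fraction")
  fraction <- as_fraction_name(fraction)
  parse_linkage(profile$linkage)

  classes <- effective_classes(table, fraction)
  class_names <- names(classes)
  all_cols <- c(class_names, "UA")
  amounts <- stats::setNames(profile$molar_mean, profile$linkage)
  M <- matrix(0, nrow = length(amounts), ncol = length(all_cols),
              dimnames = list(names(amounts), all_cols))

  candidates <- lapply(names(amounts), function(lk) {
    class_names[vapply(classes, function(v) lk %in% v, logical(1))]
  })
  names(candidates) <- names(amounts)

  # Pass 1: exclusive linkages
  for (lk in names(amounts)) {
    if (length(candidates[[lk]]) == 1) {
      M[lk, candidates[[lk]]] <- amounts[[lk]]
    }
  }

  handled <- character(0)

  # Pass 2a: 4-GalAp between RG-I and HG via the alternating backbone
  lk <- "4-GalAp"
  if (lk %in% names(amounts) && length(candidates[[lk]]) > 1 &&
      all(c("RG-I", "HG") %in% candidates[[lk]])) {
    rha <- sum(amounts[intersect(c("2-Rhap", "2,4-Rhap"), names(amounts))])
    to_rgi <- min(amounts[[lk]], rha)
    M[lk, "RG-I"] <- to_rgi
    M[lk, "HG"] <- amounts[[lk]] - to_rgi
    handled <- c(handled, lk)
  }

  # Pass 2b: 4-Glcp among XG, HM, CE
  lk <- "4-Glcp"
  if (lk %in% names(amounts) && length(candidates[[lk]]) > 1) {
    handled <- c(handled, lk)
    cand <- candidates[[lk]]
    pool <- amounts[[lk]]
    if ("XG" %in% cand) {
      branched <- if ("4,6-Glcp" %in% names(amounts)) amounts[["4,6-Glcp"]] else 0
      take <- min(pool, branched * table$rules$xg_unbranched_ratio)
      M[lk, "XG"] <- take
      pool <- pool - take
    }
    if ("HM" %in% cand) {
      man <- if ("4-Manp" %in% names(amounts)) amounts[["4-Manp"]] else 0
      take <- min(pool, man * table$rules$glc_man_ratio)
      M[lk, "HM"] <- take
      pool <- pool - take
    }
    if ("CE" %in% cand) {
      M[lk, "CE"] <- pool
    } else if ("XG" %in% cand) {
      # cellulose suppressed in this fraction: the leftover backbone
      # glucose is xyloglucan, not discarded
      M[lk, "XG"] <- M[lk, "XG"] + pool
    } else if ("HM" %in% cand) {
      M[lk, "HM"] <- M[lk, "HM"] + pool
    } else {
      M[lk, "UA"] <- pool
    }
  }

  # Pass 2c: remaining shared linkages (terminal residues) by
  # demand-proportional splitting
  for (lk in names(amounts)) {
    cand <- candidates[[lk]]
    if (length(cand) <= 1 || lk %in% handled) next
    demand <- vapply(cand, function(cl) {
      ds <- table$rules$demand_sets[[cl]]
      if (is.null(ds)) return(0)
      ds <- parse_demand_set(ds)
      sum(vapply(seq_len(nrow(ds)), function(i) {
        if (ds$linkage[i] %in% rownames(M)) {
          ds$weight[i] * M[ds$linkage[i], cl]
        } else 0
      }, numeric(1)))
    }, numeric(1))
    if (sum(demand) > 0) {
      M[lk, cand] <- amounts[[lk]] * demand / sum(demand)
    } else {
      first <- intersect(table_class_order(), cand)[1]
      if (is.na(first)) first <- cand[1]
      M[lk, first] <- amounts[[lk]]
    }
  }

  # Pass 3: unmapped linkages are the unassigned residual
  for (lk in names(amounts)) {
    if (length(candidates[[lk]]) == 0) M[lk, "UA"] <- amounts[[lk]]
  }

  # align columns to the reporting order, adding absent classes as zeros
  full <- matrix(0, nrow = nrow(M), ncol = length(polysaccharide_classes()),
                 dimnames = list(rownames(M), polysaccharide_classes()))
  full[, colnames(M)[colnames(M) %in% colnames(full)]] <-
    M[, colnames(M)[colnames(M) %in% colnames(full)], drop = FALSE]
  structure(full, fraction = fraction, input = amounts,
            class = c("allocation_matrix", class(full)))
}

#' Estimate polysaccharide composition from an allocation matrix
#'
#' Column sums of the allocation matrix: each class's estimated molar% is
#' the total of the linkage molar% allocated to it, and UA collects what
#' no class claims. The composition totals the profile total (100 for a
#' valid profile).
#'
#' @param matrix an `allocation_matrix` from [allocate_linkages()].
#' @return a `polysaccharide_composition` tibble with columns `class`,
#'   `molar_percent` (one row per class in reporting order) and a
#'   `fraction` attribute.
#' @export
estimate_composition <- function(matrix) {
  stopifnot(inherits(matrix, "allocation_matrix"))
  input <- attr(matrix, "input")
  drift <- abs(rowSums(matrix) - input)
  if (any(drift > 1e-9)) {
    stop("allocation matrix does not conserve rows: ",
         paste(names(input)[drift > 1e-9], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    class = polysaccharide_classes(),
    molar_percent = unname(colSums(matrix)[polysaccharide_classes()])
  )
  attr(out, "fraction") <- attr(matrix, "fraction")
  attr(out, "provenance") <- matrix
  class(out) <- c("polysaccharide_composition", class(out))
  out
}

#' @rdname estimate_composition
#' @param profile a [linkage_profile()].
#' @param table an `assignment_table`.
#' @param fraction optional fraction override.
#' @export
estimate_polysaccharides <- function(profile,
                                     table = default_assignment_table(),
                                     fraction = NULL) {
  estimate_composition(allocate_linkages(profile, table, fraction))
}

#' @export
print.polysaccharide_composition <- function(x, ...) {
  cat("<polysaccharide_composition> fraction:", attr(x, "fraction"),
      "| total:", format(sum(x$molar_percent), digits = 6), "\n")
  NextMethod()
}

#' Compare polysaccharide compositions across fractions
#'
#' Collates compositions into one long table (fraction x class x molar%)
#' suitable for stacked-bar display, with classes in the fixed reporting
#' order AB, AG-I, AG-II/ET, HX, XG, CA, CE, RG-I, HG, HM, UA.
#'
#' @param compositions list of `polysaccharide_composition` objects with
#'   distinct fraction labels.
#' @return a tibble with columns `fraction`, `class` (factor in reporting
#'   order), `molar_percent`.
#' @export
compare_fractions <- function(compositions) {
  stopifnot(is.list(compositions), length(compositions) >= 1)
  fracs <- vapply(compositions, attr, character(1), "fraction")
  if (anyDuplicated(fracs)) {
    stop("duplicate fraction labels: ",
         paste(unique(fracs[duplicated(fracs)]), collapse = ", "),
         call. = FALSE)
  }
  order_levels <- c("AB", "AG-I", "AG-II/ET", "HX", "XG", "CA", "CE",
                    "RG-I", "HG", "HM", "UA")
  rows <- lapply(seq_along(compositions), function(i) {
    comp <- compositions[[i]]
    tibble::tibble(fraction = fracs[i], class = comp$class,
                   molar_percent = comp$molar_percent)
  })
  out <- do.call(rbind, rows)
  out$class <- factor(out$class, levels = order_levels)
  out[order(match(out$fraction, fracs), out$class), ]
}

#' Stacked-bar plot of fraction compositions
#'
#' @param report long table from [compare_fractions()].
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_composition <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_composition() requires ggplot2", call. = FALSE)
  }
  ggplot2::ggplot(report, ggplot2::aes(x = .data$fraction,
                                       y = .data$molar_percent,
                                       fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "molar %", fill = "polysaccharide") +
    ggplot2::theme_minimal()
}
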