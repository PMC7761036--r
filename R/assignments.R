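#' Polysaccharide classes
#'
#' The closed set of polysaccharide classes used for linkage allocation,
#' in reporting order: arabinan (AB), type I arabinogalactan (AG-I),
#' type II arabinogalactan merged with extensin (AG-II/ET — extensin's
#' glycan linkages are a subset of AG-II's, so the two are one reporting
#' class), heteroxylan (HX), xyloglucan (XG), callose (CA), cellulose
#' (CE), rhamnogalacturonan I (RG-I), homogalacturonan (HG), heteromannan
#' (HM), and UA for unassigned linkages.
#'
#' @return character vector of class codes in reporting order.
#' @export
polysaccharide_classes <- function() {
  c("AB", "AG-I", "AG-II/ET", "HX", "XG", "CA", "CE", "RG-I", "HG", "HM", "UA")
}

# Class order as the assignment table lists its rows; used as the
# deterministic fallback when terminal residues have zero branch-point
# demand everywhere.
table_class_order <- function() {
  c("AB", "AG-I", "AG-II/ET", "HX", "XG", "CE", "CA", "RG-I", "HG", "HM")
}

#' Linkage-to-polysaccharide assignment tables
#'
#' The assignment table maps each polysaccharide class to the glycosidic
#' linkages diagnostic for it, together with fraction-specific overrides
#' and the stoichiometric rules used to resolve linkages shared by
#' several classes. `default_assignment_table()` returns the built-in
#' table for dicot cell walls:
#'
#' * AB: t-Araf, 5-Araf, 2,5-Araf, 2,3,5-Araf
#' * AG-I: t-Araf, 4-Galp, 4,6-Galp
#' * AG-II/ET: t-Arap, t-Araf, 2-Araf, 3-Araf, t-Rhap, t-Fucp, t-Galp,
#'   3-Galp, 6-Galp, 3,6-Galp, 3,4,6-Galp
#' * HX: t-Araf, 4-Xylp, 2,4-Xylp, 3,4-Xylp, 2,3,4-Xylp, t-GlcAp
#' * XG: t-Xylp, 2-Xylp, t-Fucp, t-Galp, 2-Galp, 4-Glcp, 4,6-Glcp
#' * CE: 4-Glcp
#' * CA: 3-Glcp (dicots lack mixed-linkage glucan, so 3-Glcp is callose)
#' * RG-I: 2-Rhap, 2,4-Rhap, 4-GalAp, 3,4-GalAp
#' * HG: t-GalAp, 4-GalAp
#' * HM: 4-Manp, 4,6-Manp, t-Galp, 4-Glcp
#'
#' The built-in overrides suppress the CE x 4-Glcp pair in the
#' `EDTA+Na2CO3` and `4M KOH` fractions: cellulose is insoluble in those
#' extractants, so 4-Glcp recovered there belongs to xyloglucan (and
#' glucomannan), not cellulose.
#'
#' @section Rules:
#' `rules` holds the constants of the shared-linkage arithmetic (see
#' [allocate_linkages()]): `xg_unbranched_ratio` (unbranched 4-Glcp per
#' branched 4,6-Glcp backbone residue in xyloglucan; default 1/3, the
#' XXXG motif), `glc_man_ratio` (glucose per 4-linked mannose in
#' glucomannan; default 1/3), and `demand_sets`, a named list giving, per
#' class, the branch-point linkages (with optional multipliers written as
#' `"2*2,3,4-Xylp"`) whose allocated molar% measures that class's demand
#' for shared terminal residues.
#'
#' @return an `assignment_table` object: a list with elements `classes`
#'   (named list of linkage character vectors), `overrides` (data.frame
#'   `fraction`, `class`, `linkage`), `rules`.
#' @examples
#' tab <- default_assignment_table()
#' tab$classes$AB
#' @export
default_assignment_table <- function() {
  classes <- list(
    "AB"       = c("t-Araf", "5-Araf", "2,5-Araf", "2,3,5-Araf"),
    "AG-I"     = c("t-Araf", "4-Galp", "4,6-Galp"),
    "AG-II/ET" = c("t-Arap", "t-Araf", "2-Araf", "3-Araf", "t-Rhap",
                   "t-Fucp", "t-Galp", "3-Galp", "6-Galp", "3,6-Galp",
                   "3,4,6-Galp"),
    "HX"       = c("t-Araf", "4-Xylp", "2,4-Xylp", "3,4-Xylp", "2,3,4-Xylp",
                   "t-GlcAp"),
    "XG"       = c("t-Xylp", "2-Xylp", "t-Fucp", "t-Galp", "2-Galp",
                   "4-Glcp", "4,6-Glcp"),
    "CE"       = "4-Glcp",
    "CA"       = "3-Glcp",
    "RG-I"     = c("2-Rhap", "2,4-Rhap", "4-GalAp", "3,4-GalAp"),
    "HG"       = c("t-GalAp", "4-GalAp"),
    "HM"       = c("4-Manp", "4,6-Manp", "t-Galp", "4-Glcp")
  )
  overrides <- data.frame(
    fraction = c("EDTA+Na2CO3", "4M KOH"),
    class = c("CE", "CE"),
    linkage = c("4-Glcp", "4-Glcp"),
    stringsAsFactors = FALSE
  )
  rules <- list(
    xg_unbranched_ratio = 1 / 3,
    glc_man_ratio = 1 / 3,
    demand_sets = list(
      "AB"       = c("2,5-Araf", "2,3,5-Araf"),
      "AG-I"     = "4,6-Galp",
      "AG-II/ET" = c("3,6-Galp", "3,4,6-Galp"),
      "HX"       = c("2,4-Xylp", "3,4-Xylp", "2*2,3,4-Xylp"),
      "XG"       = "2-Xylp",
      "HM"       = "4,6-Manp"
    )
  )
  new_assignment_table(classes, overrides, rules)
}

new_assignment_table <- function(classes, overrides, rules) {
  stopifnot(is.list(classes), length(classes) >= 1)
  known <- setdiff(polysaccharide_classes(), "UA")
  bad_class <- setdiff(names(classes), known)
  if (length(bad_class) > 0) {
    stop("unknown polysaccharide class code(s): ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  }
  parse_linkage(unique(unlist(classes, use.names = FALSE)))
  if (nrow(overrides) > 0) {
    for (i in seq_len(nrow(overrides))) {
      cl <- overrides$class[i]; lk <- overrides$linkage[i]
      if (!cl %in% names(classes) || !lk %in% classes[[cl]]) {
        stop("override references non-existent class-linkage pair: ",
             cl, " x ", lk, call. = FALSE)
      }
    }
  }
  bad_demand <- setdiff(names(rules$demand_sets), names(classes))
  if (length(bad_demand) > 0) {
    stop("demand set for class not in table: ",
         paste(bad_demand, collapse = ", "), call. = FALSE)
  }
  structure(list(classes = classes, overrides = overrides, rules = rules),
            class = "assignment_table")
}

#' Load an assignment table from a configuration file
#'
#' With no configuration the built-in [default_assignment_table()] is
#' returned. A YAML or JSON config can replace the class map, add or
#' drop fraction overrides, and change rule constants. Schema:
#' ```yaml
#' classes: {AB: [t-Araf, 5-Araf], ...}      # replaces the class map
#' overrides: [{fraction: "4M KOH", class: CE, linkage: 4-Glcp}, ...]
#' rules:
#'   glc_man_ratio: 0.33
#'   xg_unbranched_ratio: 0.33
#'   demand_sets: {AB: [2,5-Araf], ...}
#' ```
#' Omitted top-level keys keep their defaults. Unknown linkage strings or
#' class codes raise an error naming the offending token.
#'
#' @param config optional path to a YAML (`.yml`/`.yaml`) or JSON file.
#' @return an `assignment_table`.
#' @export
load_assignment_table <- function(config = NULL) {
  tab <- default_assignment_table()
  if (is.null(config)) return(tab)
  if (!file.exists(config)) stop("config file not found: ", config,
                                 call. = FALSE)
  cfg <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(config)
  }
  classes <- tab$classes
  if (!is.null(cfg$classes)) {
    classes <- lapply(cfg$classes, function(v) as.character(unlist(v)))
  }
  overrides <- tab$overrides
  if (!is.null(cfg$overrides)) {
    ov <- cfg$overrides
    if (is.data.frame(ov)) {
      overrides <- ov[, c("fraction", "class", "linkage")]
    } else {
      overrides <- do.call(rbind, lapply(ov, function(o) {
        data.frame(fraction = o$fraction, class = o$class,
                   linkage = o$linkage, stringsAsFactors = FALSE)
      }))
      if (is.null(overrides)) {
        overrides <- data.frame(fraction = character(0), class = character(0),
                                linkage = character(0))
      }
    }
  } else if (!is.null(cfg$classes)) {
    # class map replaced but overrides kept: drop overrides whose pair no
    # longer exists rather than erroring on the defaults
    keep <- overrides$class %in% names(classes)
    if (any(keep)) {
      keep[keep] <- vapply(which(keep), function(i) {
        overrides$linkage[i] %in% classes[[overrides$class[i]]]
      }, logical(1))
    }
    overrides <- overrides[keep, , drop = FALSE]
  }
  rules <- tab$rules
  if (!is.null(cfg$rules)) {
    for (key in c("glc_man_ratio", "xg_unbranched_ratio")) {
      if (!is.null(cfg$rules[[key]])) rules[[key]] <- as.numeric(cfg$rules[[key]])
    }
    if (!is.null(cfg$rules$demand_sets)) {
      ds <- lapply(cfg$rules$demand_sets, function(v) as.character(unlist(v)))
      rules$demand_sets[names(ds)] <- ds
    }
    rules$demand_sets <- rules$demand_sets[
      names(rules$demand_sets) %in% names(classes)]
  } else {
    rules$demand_sets <- rules$demand_sets[
      names(rules$demand_sets) %in% names(classes)]
  }
  new_assignment_table(classes, overrides, rules)
}

#' @export
print.assignment_table <- function(x, ...) {
  cat("<assignment_table>", length(x$classes), "classes,",
      nrow(x$overrides), "fraction override(s)\n")
  for (cl in names(x$classes)) {
    cat(format(cl, width = 9), paste(x$classes[[cl]], collapse = ", "), "\n")
  }
  invisible(x)
}

# Effective class -> linkage map for a fraction, after overrides.
effective_classes <- function(table, fraction) {
  fraction <- as_fraction_name(fraction)
  classes <- table$classes
  ov <- table$overrides
  if (nrow(ov) > 0) {
    hit <- ov[ov$fraction == fraction, , drop = FALSE]
    for (i in seq_len(nrow(hit))) {
      classes[[hit$class[i]]] <- setdiff(classes[[hit$class[i]]],
                                         hit$linkage[i])
    }
  }
  classes
}

# Parse demand-set entries "2*2,3,4-Xylp" -> weight 2, linkage "2,3,4-Xylp".
parse_demand_set <- function(entries) {
  weights <- rep(1, length(entries))
  has_mult <- grepl("^[0-9.]+\\*", entries)
  weights[has_mult] <- as.numeric(sub("\\*.*$", "", entries[has_mult]))
  linkages <- sub("^[0-9.]+\\*", "", entries)
  data.frame(linkage = linkages, weight = weights, stringsAsFactors = FALSE)
}
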