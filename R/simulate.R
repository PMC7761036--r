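#' Polymer templates: linkage distributions of idealised polysaccharides
#'
#' Each template is a named numeric vector of linkage fractions (summing
#' to 1) describing the PMAA linkage signature an idealised polymer of
#' that class would produce. Template parameters follow the same
#' stoichiometric assumptions the allocator inverts — the alternating
#' RG-I backbone, the XXXG xyloglucan motif, the 1:3 glucomannan
#' glucose:mannose ratio, and shared terminal residues emitted exactly at
#' each class's branch-point demand — so that forward simulation followed
#' by allocation recovers the input composition (the inverse problem is
#' well-posed by construction). Only non-reducing termini are emitted, at
#' fraction `1/dp`; reducing ends are ignored, matching the estimator.
#'
#' @param dp degree of polymerisation of the backbone (`Inf` for no
#'   terminal contribution).
#' @param branch_fraction fraction of backbone residues carrying a single
#'   branch.
#' @name polymer_templates
NULL

normalize_template <- function(x) {
  x <- x[x > 0]
  x / sum(x)
}

#' @rdname polymer_templates
#' @export
template_hg <- function(dp = 100) {
  stopifnot(dp > 1)
  normalize_template(c("t-GalAp" = 1 / dp, "4-GalAp" = 1 - 1 / dp))
}

#' @rdname polymer_templates
#' @export
template_rgi <- function(branch_fraction = 0.5) {
  b <- branch_fraction
  stopifnot(b >= 0, b <= 1)
  normalize_template(c("4-GalAp" = 0.5, "2-Rhap" = 0.5 * (1 - b),
                       "2,4-Rhap" = 0.5 * b))
}

#' @rdname polymer_templates
#' @export
template_arabinan <- function(branch_fraction = 0.25, dp = Inf) {
  b <- branch_fraction
  stopifnot(b >= 0, b <= 1, dp > 1)
  term <- if (is.finite(dp)) 1 / dp else 0
  normalize_template(c("5-Araf" = 1 - b, "2,5-Araf" = b,
                       "t-Araf" = b + term))
}

#' @rdname polymer_templates
#' @export
template_agi <- function(branch_fraction = 0.2, dp = Inf) {
  b <- branch_fraction
  term <- if (is.finite(dp)) 1 / dp else 0
  normalize_template(c("4-Galp" = 1 - b, "4,6-Galp" = b,
                       "t-Araf" = b, "t-Galp" = term))
}

#' @rdname polymer_templates
#' @export
template_agii <- function() {
  normalize_template(c("6-Galp" = 0.20, "3-Galp" = 0.15, "3,6-Galp" = 0.20,
                       "t-Araf" = 0.20, "t-Galp" = 0.20, "t-Arap" = 0.05))
}

#' @rdname polymer_templates
#' @param double_branch_fraction fraction of backbone residues branched
#'   at two positions.
#' @param frac_o2 of singly-branched xylan backbone residues, the
#'   fraction substituted at O-2 rather than O-3.
#' @export
template_heteroxylan <- function(branch_fraction = 0.15,
                                 double_branch_fraction = 0.02,
                                 frac_o2 = 0.25) {
  b <- branch_fraction; d <- double_branch_fraction
  stopifnot(b + d <= 1)
  normalize_template(c(
    "4-Xylp" = 1 - b - d,
    "2,4-Xylp" = b * frac_o2,
    "3,4-Xylp" = b * (1 - frac_o2),
    "2,3,4-Xylp" = d,
    "t-Araf" = b + 2 * d
  ))
}

#' @rdname polymer_templates
#' @param gal_fraction fraction of xylosyl side chains extended with
#'   galactose (the L side chain of XLXG/XXLG repeats).
#' @param fuc_fraction fraction of galactosylated side chains further
#'   fucosylated; non-zero values break exact parameter recovery because
#'   t-Fucp demand is then shared with AG-II (a stress-test knob).
#' @export
template_xyloglucan <- function(gal_fraction = 1 / 3, fuc_fraction = 0) {
  g <- gal_fraction; f <- fuc_fraction
  stopifnot(g >= 0, g <= 1, f >= 0, f <= 1)
  # one XXXG repeat: 4 backbone Glc (1 unbranched + 3 xylosylated),
  # 3 xylosyl side chains
  normalize_template(c(
    "4-Glcp" = 1, "4,6-Glcp" = 3,
    "t-Xylp" = 3 * (1 - g), "2-Xylp" = 3 * g,
    "t-Galp" = 3 * g * (1 - f), "2-Galp" = 3 * g * f, "t-Fucp" = 3 * g * f
  ))
}

#' @rdname polymer_templates
#' @param gal_branch_fraction fraction of backbone mannosyl residues
#'   carrying a galactosyl branch.
#' @param glc_man_ratio backbone glucose per 4-linked mannose
#'   (glucomannan stoichiometry; must match the allocator's rule constant
#'   for exact recovery).
#' @export
template_heteromannan <- function(gal_branch_fraction = 0.1,
                                  glc_man_ratio = 1 / 3) {
  gb <- gal_branch_fraction; r <- glc_man_ratio
  normalize_template(c(
    "4-Manp" = 1 - gb, "4,6-Manp" = gb, "t-Galp" = gb,
    "4-Glcp" = (1 - gb) * r
  ))
}

#' @rdname polymer_templates
#' @export
template_cellulose <- function(dp = Inf) {
  term <- if (is.finite(dp)) 1 / dp else 0
  out <- c("4-Glcp" = 1 - term)
  if (term > 0) out <- c(out, "t-Glcp" = term)
  normalize_template(out)
}

#' @rdname polymer_templates
#' @export
template_callose <- function() {
  c("3-Glcp" = 1)
}

#' @rdname polymer_templates
#' @return `default_templates()`: named list of template vectors, one per
#'   polysaccharide class (UA excluded).
#' @export
default_templates <- function() {
  list(
    "AB" = template_arabinan(),
    "AG-I" = template_agi(),
    "AG-II/ET" = template_agii(),
    "HX" = template_heteroxylan(),
    "XG" = template_xyloglucan(),
    "CA" = template_callose(),
    "CE" = template_cellulose(),
    "RG-I" = template_rgi(),
    "HG" = template_hg(),
    "HM" = template_heteromannan()
  )
}

#' Forward-simulate a cell wall's linkage profile
#'
#' Mixes polymer templates according to a known (true) polysaccharide
#' composition and returns the noiseless molar% linkage profile the
#' mixture would produce: the weighted sum of the template linkage
#' distributions, renormalised to 100.
#'
#' @param composition named numeric vector of true molar% per
#'   polysaccharide class, summing to 100.
#' @param templates named list of template vectors covering every class
#'   in `composition` (default [default_templates()]).
#' @param fraction fraction label for the resulting profile.
#' @return a [linkage_profile()].
#' @examples
#' generate_cell_wall(c(HG = 40, CE = 60))
#' @export
generate_cell_wall <- function(composition, templates = default_templates(),
                               fraction = "AIR") {
  if (abs(sum(composition) - 100) > 1e-6) {
    stop("true composition must sum to 100 (got ",
         format(sum(composition)), ")", call. = FALSE)
  }
  missing_tpl <- setdiff(names(composition), names(templates))
  if (length(missing_tpl) > 0) {
    stop("no template for class(es): ",
         paste(missing_tpl, collapse = ", "), call. = FALSE)
  }
  mix <- numeric(0)
  for (cl in names(composition)) {
    tpl <- templates[[cl]] * composition[[cl]]
    for (lk in names(tpl)) {
      mix[lk] <- (if (lk %in% names(mix)) mix[[lk]] else 0) + tpl[[lk]]
    }
  }
  mix <- 100 * mix / sum(mix)
  ord <- linkage_order(names(mix))
  linkage_profile(names(mix)[ord], unname(mix)[ord], fraction = fraction,
                  sum_tolerance = 1e-9)
}

#' Add compositional measurement noise to a linkage profile
#'
#' Each replicate perturbs every linkage with a zero-truncated Gaussian
#' of standard deviation `cv * mean` and renormalises to 100 — the
#' simplest compositional noise model consistent with mean-and-whisker
#' replicate variation in PMAA data.
#'
#' @param profile a [linkage_profile()].
#' @param cv coefficient of variation (>= 0).
#' @param n_replicates number of replicates to generate.
#' @param seed integer seed; identical seeds give identical replicates.
#' @return list of `n_replicates` [linkage_profile()] objects.
#' @export
add_noise <- function(profile, cv = 0.05, n_replicates = 3, seed = NULL) {
  stopifnot(is_linkage_profile(profile), cv >= 0, n_replicates >= 1)
  gen <- function() {
    lapply(seq_len(n_replicates), function(i) {
      v <- pmax(0, profile$molar_mean +
                  stats::rnorm(nrow(profile), 0, cv * profile$molar_mean))
      if (sum(v) == 0) v <- profile$molar_mean  # degenerate draw: keep truth
      linkage_profile(profile$linkage, 100 * v / sum(v),
                      fraction = attr(profile, "fraction"),
                      sum_tolerance = 1e-9)
    })
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Default class-by-fraction extraction efficiencies
#'
#' Proportion of each polysaccharide class recovered in each fraction of
#' the sequential extraction (rows sum to 1). The defaults emulate the
#' behaviour of dicot walls: pectic polymers (HG, RG-I, and the
#' associated AB/AG side-chain polymers) release mostly into the
#' chelator/carbonate extract, hemicelluloses (XG, HX, HM) require 4 M
#' KOH, and cellulose stays in the insoluble residue.
#'
#' @return matrix class x fraction (`EDTA+Na2CO3`, `4M KOH`, `Residue`).
#' @export
default_extraction_matrix <- function() {
  fr <- c("EDTA+Na2CO3", "4M KOH", "Residue")
  m <- rbind(
    "AB"       = c(0.70, 0.20, 0.10),
    "AG-I"     = c(0.70, 0.20, 0.10),
    "AG-II/ET" = c(0.70, 0.20, 0.10),
    "HX"       = c(0.15, 0.70, 0.15),
    "XG"       = c(0.15, 0.70, 0.15),
    "CA"       = c(0.20, 0.50, 0.30),
    "CE"       = c(0.05, 0.05, 0.90),
    "RG-I"     = c(0.70, 0.20, 0.10),
    "HG"       = c(0.80, 0.10, 0.10),
    "HM"       = c(0.15, 0.70, 0.15)
  )
  colnames(m) <- fr
  m
}

#' Simulate sequential fractionation of a simulated wall
#'
#' Splits each class's mass across fractions according to an extraction
#' matrix, builds each fraction's renormalised linkage profile from the
#' class templates, and returns the fraction yields. Mass is conserved
#' exactly: with rows summing to 1 the fraction yields sum to 100% of
#' the starting mass.
#'
#' @param composition named true composition (molar%, summing to 100).
#' @param extraction extraction matrix class x fraction with rows summing
#'   to 1 (default [default_extraction_matrix()]).
#' @param templates class templates (default [default_templates()]).
#' @param starting_mass nominal starting mass in mg.
#' @return list with `profiles` (named list of [linkage_profile()], one
#'   per fraction), `yields` (a [compute_yields()] ledger),
#'   `class_masses` (class x fraction matrix, mg).
#' @export
generate_fractionation <- function(composition,
                                   extraction = default_extraction_matrix(),
                                   templates = default_templates(),
                                   starting_mass = 100) {
  if (abs(sum(composition) - 100) > 1e-6) {
    stop("true composition must sum to 100", call. = FALSE)
  }
  classes <- names(composition)
  missing_rows <- setdiff(classes, rownames(extraction))
  if (length(missing_rows) > 0) {
    stop("extraction matrix lacks row(s): ",
         paste(missing_rows, collapse = ", "), call. = FALSE)
  }
  E <- extraction[classes, , drop = FALSE]
  bad <- abs(rowSums(E) - 1) > 1e-9
  if (any(bad)) {
    stop("extraction matrix row(s) not summing to 1: ",
         paste(rownames(E)[bad], collapse = ", "), call. = FALSE)
  }
  class_masses <- sweep(E, 1, composition * starting_mass / 100, "*")
  fractions <- colnames(E)
  profiles <- list()
  for (f in fractions) {
    w <- class_masses[, f]
    w <- w[w > 0]
    if (length(w) == 0) next
    profiles[[f]] <- generate_cell_wall(100 * w / sum(w),
                                        templates = templates, fraction = f)
  }
  yields <- compute_yields(starting_mass,
                           stats::setNames(colSums(class_masses), fractions))
  list(profiles = profiles, yields = yields, class_masses = class_masses)
}

#' Simulate an antibody glycome screen
#'
#' Builds an antibody array whose readings are a linear response to
#' polysaccharide abundance: `od = affinity %*% abundance / 100 *
#' dilution_factor + background + noise`, floored at 0. Dilution factors
#' halve at each step.
#'
#' @param abundance class x extract matrix of polysaccharide abundances
#'   (e.g. molar% per fraction).
#' @param affinity probe x class matrix of binding affinities (OD per
#'   100% abundance), all >= 0.
#' @param panel data.frame `mab_id`, `epitope_group`, rows matching
#'   `affinity`'s rows.
#' @param background scalar true background OD added to every well.
#' @param noise_sd Gaussian well noise standard deviation.
#' @param n_replicates,n_dilutions replicate wells and printed dilutions.
#' @param seed integer seed.
#' @return an [antibody_array()] with a `background` column holding the
#'   true background.
#' @export
generate_antibody_plate <- function(abundance, affinity, panel,
                                    background = 0.05, noise_sd = 0.02,
                                    n_replicates = 3, n_dilutions = 1,
                                    seed = NULL) {
  stopifnot(all(affinity >= 0), nrow(affinity) == nrow(panel),
            n_dilutions >= 1, n_dilutions <= 4)
  if (!all(colnames(affinity) %in% rownames(abundance))) {
    stop("affinity columns must name rows of the abundance matrix",
         call. = FALSE)
  }
  signal <- affinity %*% abundance[colnames(affinity), , drop = FALSE] / 100
  extracts <- colnames(abundance)
  gen <- function() {
    rows <- expand.grid(probe = seq_len(nrow(panel)),
                        extract = extracts,
                        replicate = seq_len(n_replicates),
                        dilution = seq_len(n_dilutions),
                        stringsAsFactors = FALSE)
    dil_factor <- 2^(-(rows$dilution - 1))
    mu <- signal[cbind(rows$probe, match(rows$extract, extracts))] *
      dil_factor + background
    od <- pmax(0, mu + stats::rnorm(nrow(rows), 0, noise_sd))
    antibody_array(data.frame(
      mab_id = panel$mab_id[rows$probe],
      epitope_group = panel$epitope_group[rows$probe],
      extract = rows$extract,
      replicate = rows$replicate,
      dilution = rows$dilution,
      od = od,
      background = background,
      stringsAsFactors = FALSE
    ), group_order = unique(panel$epitope_group))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Growth-condition presets
#'
#' Logistic growth parameters shaped like manual OD600 growth assays of
#' Bacteroides isolates: a glucose positive control growing to high
#' density, a moderate grower on the polysaccharide substrate (the
#' high-efficiency phenotype), a weak grower reaching low density, and a
#' flat no-carbohydrate control.
#'
#' @return data.frame `condition, max_od, rate, od0`.
#' @export
growth_presets <- function() {
  data.frame(
    condition = c("glucose", "NSP-moderate", "NSP-low", "MM"),
    max_od = c(1.0, 0.4, 0.15, 0.01),
    rate = c(0.4, 0.25, 0.15, 0),
    od0 = c(0.01, 0.01, 0.01, 0.01),
    stringsAsFactors = FALSE
  )
}

logistic_od <- function(t, max_od, rate, od0) {
  if (rate == 0 || max_od <= od0) return(rep(od0, length(t)))
  max_od / (1 + (max_od - od0) / od0 * exp(-rate * t))
}

#' Simulate manual-time-point growth curves
#'
#' Samples logistic growth at a few manual reading times, adds a medium
#' blank level and well noise, and returns one [growth_curve()] per
#' condition row.
#'
#' @param params data.frame like [growth_presets()], optionally with an
#'   `isolate` column.
#' @param times reading times in hours (default 0, 5, 24).
#' @param blank_level true no-inoculum background OD.
#' @param noise_sd Gaussian reading noise (0 for noiseless curves).
#' @param n_replicates replicates per condition.
#' @param seed integer seed.
#' @return named list of [growth_curve()] objects keyed by condition.
#' @export
generate_growth_curves <- function(params = growth_presets(),
                                   times = c(0, 5, 24),
                                   blank_level = 0.05, noise_sd = 0,
                                   n_replicates = 3, seed = NULL) {
  stopifnot(all(params$rate >= 0), all(params$max_od >= 0))
  gen <- function() {
    out <- list()
    for (i in seq_len(nrow(params))) {
      mu <- logistic_od(times, params$max_od[i], params$rate[i],
                        params$od0[i])
      od <- pmax(0, rep(mu, n_replicates) + blank_level +
                   stats::rnorm(length(times) * n_replicates, 0, noise_sd))
      out[[params$condition[i]]] <- growth_curve(
        isolate = if ("isolate" %in% names(params)) params$isolate[i]
                  else "sim",
        condition = params$condition[i],
        time_h = rep(times, n_replicates),
        od600 = od,
        replicate = rep(seq_len(n_replicates), each = length(times)),
        blank_od = blank_level
      )
    }
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
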