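#' Fraction yield bookkeeping
#'
#' Sequential extraction splits a weighed starting cell wall into
#' recovered fraction masses; yields are expressed as percent of starting
#' mass. Losses (dialysis, washes) mean the yields need not sum to 100;
#' summing above 100 beyond a small tolerance indicates a weighing or
#' bookkeeping error and is flagged.
#'
#' @param starting_mass starting mass in mg (> 0).
#' @param fraction_masses named numeric vector of recovered masses (mg),
#'   one per fraction, all >= 0.
#' @param over_recovery_limit total-yield percentage above which the
#'   ledger is flagged (default 102).
#' @return a `yield_ledger`: a tibble with columns `fraction`, `mass_mg`,
#'   `yield_pct`, plus attributes `starting_mass`, `total_yield` and
#'   `over_recovery` (logical flag).
#' @examples
#' compute_yields(100, c("EDTA+Na2CO3" = 32.1, "4M KOH" = 29.0,
#'                       "Residue" = 38.9))
#' @export
compute_yields <- function(starting_mass, fraction_masses,
                           over_recovery_limit = 102) {
  if (!is.numeric(starting_mass) || length(starting_mass) != 1 ||
      starting_mass <= 0) {
    stop("starting_mass must be a single positive number (mg)", call. = FALSE)
  }
  if (is.null(names(fraction_masses)) || any(!nzchar(names(fraction_masses)))) {
    stop("fraction_masses must be a named vector", call. = FALSE)
  }
  if (any(fraction_masses < 0)) {
    stop("fraction masses must be >= 0", call. = FALSE)
  }
  yields <- 100 * fraction_masses / starting_mass
  out <- tibble::tibble(
    fraction = names(fraction_masses),
    mass_mg = unname(fraction_masses),
    yield_pct = unname(yields)
  )
  attr(out, "starting_mass") <- starting_mass
  attr(out, "total_yield") <- sum(yields)
  attr(out, "over_recovery") <- sum(yields) > over_recovery_limit
  class(out) <- c("yield_ledger", class(out))
  out
}

#' @export
print.yield_ledger <- function(x, ...) {
  cat("<yield_ledger> starting mass:", attr(x, "starting_mass"), "mg |",
      "total yield:", format(attr(x, "total_yield"), digits = 4), "%",
      if (attr(x, "over_recovery")) "[OVER-RECOVERY]" else "", "\n")
  NextMethod()
}
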