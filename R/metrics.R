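#' Strain evaluation metrics
#'
#' Quantities used to rank engineered strains: yield (product flux over
#' carbon-source uptake, optionally molar-mass normalized so the
#' theoretical upper bound is 1), productivity (yield times growth rate,
#' h^-1), the productivity range implied by FVA, metabolite production
#' flux-sums (ATP, NAD(P)H, FADH2, ...), and percent variation relative to
#' the wild type as printed in strain tables.
#'
#' @name metrics
NULL

#' Yield: product flux over carbon uptake
#'
#' `|product_flux| / |carbon_uptake_flux| * molar_mass_ratio`. Carbon
#' uptake follows the exchange sign convention (uptake negative); the
#' magnitude is used, so passing -3.63 or 3.63 is equivalent.
#'
#' @param product_flux Product flux (mmol gDW^-1 h^-1).
#' @param carbon_uptake_flux Carbon-source exchange flux (mmol gDW^-1 h^-1).
#' @param molar_mass_ratio Dimensionless normalization (default 1 =
#'   mole/mole yield).
#' @return Dimensionless yield >= 0. A zero product flux yields 0 even at
#'   zero uptake; a non-zero product flux at zero uptake is an error.
#' @export
yield_of <- function(product_flux, carbon_uptake_flux, molar_mass_ratio = 1) {
  if (product_flux == 0) return(0)
  if (carbon_uptake_flux == 0) {
    stop("yield undefined: zero carbon uptake with non-zero product flux",
         call. = FALSE)
  }
  abs(product_flux) / abs(carbon_uptake_flux) * molar_mass_ratio
}

#' Productivity: yield times growth rate
#'
#' @param yield Dimensionless yield.
#' @param growth_rate Growth rate (h^-1).
#' @return Productivity (h^-1).
#' @export
productivity_of <- function(yield, growth_rate) {
  stopifnot(is.finite(yield), is.finite(growth_rate),
            yield >= 0, growth_rate >= 0)
  yield * growth_rate
}

#' Percent variation of a strain value relative to the wild type
#'
#' `100 * (strain - wt) / wt`, the "(WT var. %)" columns of strain tables.
#'
#' @param strain_value,wt_value Scalars.
#' @return Percent; `NA` when `wt_value` is 0 (reported as not applicable).
#' @export
wt_variation <- function(strain_value, wt_value) {
  if (wt_value == 0) return(NA_real_)
  100 * (strain_value - wt_value) / wt_value
}

#' Production flux-sum of a metabolite
#'
#' Total rate at which the network produces a metabolite under a given flux
#' state: `sum_j max(0, S[met, j] * v_j)`. Only net production terms count
#' (a reaction running backwards through a consuming stoichiometry is
#' production). Used for the ATP/GTP/NADH/NADPH/FADH2 columns and bounds.
#'
#' @param model A `stoich_model`.
#' @param state A `flux_state` (or a named/plain flux vector).
#' @param metabolite Metabolite identifier.
#' @return Non-negative flux-sum (mmol gDW^-1 h^-1).
#' @export
cofactor_flux_sum <- function(model, state, metabolite) {
  if (!(metabolite %in% model$metabolite_ids)) {
    stop(sprintf("unknown metabolite '%s'", metabolite), call. = FALSE)
  }
  v <- if (inherits(state, "flux_state")) state$v else state
  row <- as.numeric(model$S[metabolite, ])
  sum(pmax(0, row * as.numeric(v)))
}

#' Point metrics of an applied strain
#'
#' Runs pFBA on a design-applied model and collects growth rate, product
#' flux, carbon uptake magnitude, yield, productivity and the production
#' flux-sums of the configured cofactor metabolites.
#'
#' @param model A `stoich_model` (design already applied, or apply via
#'   `design`).
#' @param design Optional [strain_design()] to apply first.
#' @param cofactors Metabolite ids to report flux-sums for (silently skips
#'   ids absent from the model).
#' @param molar_mass_ratio Passed to [yield_of()].
#' @return A `strain_metrics` list, or a list with `feasible = FALSE` if
#'   the LP is infeasible.
#' @export
strain_metrics <- function(model, design = NULL, cofactors = character(),
                           molar_mass_ratio = 1) {
  if (!is.null(design)) model <- apply_design(model, design)
  ps <- pfba(model)
  if (ps$status != "optimal") {
    return(structure(list(feasible = FALSE, status = ps$status),
                     class = "strain_metrics"))
  }
  growth <- ps$v[[model$biomass_reaction]]
  vprd <- ps$v[[model$product_reaction]]
  vcs <- ps$v[[model$carbon_source_exchange]]
  yld <- if (abs(vcs) < 1e-12) 0 else
    yield_of(vprd, vcs, molar_mass_ratio)
  cof <- stats::setNames(
    vapply(intersect(cofactors, model$metabolite_ids),
           function(mid) cofactor_flux_sum(model, ps, mid), numeric(1)),
    intersect(cofactors, model$metabolite_ids))
  n_ko <- if (is.null(design)) 0L else length(design$deletions)
  structure(list(
    feasible = TRUE, status = "optimal",
    growth_rate = growth,
    product_flux = vprd,
    carbon_uptake = abs(vcs),
    yield = yld,
    productivity = productivity_of(yld, max(growth, 0)),
    cofactor_production = cof,
    n_knockouts = n_ko,
    flux = ps$v
  ), class = "strain_metrics")
}

#' @export
print.strain_metrics <- function(x, ...) {
  if (!x$feasible) {
    cat("<strain_metrics> infeasible (", x$status, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "<strain_metrics> growth %.4g h^-1, product %.4g, yield %.4g, productivity %.4g h^-1, %d KO\n",
    x$growth_rate, x$product_flux, x$yield, x$productivity, x$n_knockouts))
  invisible(x)
}

#' Productivity range of a strain via FVA
#'
#' Applies the design, fixes growth and carbon uptake at their pFBA point
#' values, takes the FVA range of the product reaction at the configured
#' fraction of the growth optimum, and converts both ends to productivity
#' through yield x growth.
#'
#' @param model A `stoich_model`.
#' @param design A [strain_design()] (use an empty design for the WT).
#' @param fraction_of_optimum FVA fraction (default 1: ranges at the exact
#'   growth optimum).
#' @param molar_mass_ratio Passed to [yield_of()].
#' @return Named numeric `c(min = , max = )` in h^-1.
#' @export
productivity_range <- function(model, design = strain_design(),
                               fraction_of_optimum = 1.0,
                               molar_mass_ratio = 1) {
  applied <- apply_design(model, design)
  met <- strain_metrics(applied, cofactors = character(),
                        molar_mass_ratio = molar_mass_ratio)
  if (!met$feasible) stop("infeasible strain: productivity range undefined",
                          call. = FALSE)
  rng <- fva(applied, fraction_of_optimum, reactions = applied$product_reaction)
  if (met$carbon_uptake < 1e-12) {
    lohi <- c(0, 0)
  } else {
    lohi <- c(
      yield_of(max(rng$min, 0), met$carbon_uptake, molar_mass_ratio),
      yield_of(max(rng$max, 0), met$carbon_uptake, molar_mass_ratio)
    ) * max(met$growth_rate, 0)
  }
  c(min = min(lohi), max = max(lohi))
}
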