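#' Assemble the modelling design from a methylation study
#'
#' Convenience chain of the standard preprocessing: apply the multiplicative
#' life-span correction, impute missing maximum life spans from the
#' phylogeny, filter probes on detection p-values, aggregate beta values
#' into strata, and return the aligned design matrix and log response for
#' the requested trait.
#'
#' @param dataset a [simulate_dataset()] result, or any list with components
#'   `traits`, `tree`, `meth` and `detection` of the same shapes.
#' @param trait one of `"max_lifespan"`, `"gestation"`, `"maturity"`.
#' @param mode stratum definition, `"species"` or `"species_tissue"`.
#' @param fdr,species_fraction probe-filter parameters (see
#'   [filter_probes()]).
#' @param correction multiplicative life-span correction factor.
#' @return List with `x` (strata x filtered-CpGs matrix), `y` (log trait per
#'   stratum), `species` (per row), `orders` (per row), `observed` (logical
#'   per row: trait not imputed), `traits` (corrected, imputed table),
#'   `cpgs` (retained probe ids) and `strata`.
#' @export
prepare_design <- function(dataset,
                           trait = c("max_lifespan", "gestation", "maturity"),
                           mode = c("species", "species_tissue"),
                           fdr = 0.05, species_fraction = 0.85,
                           correction = 1.3) {
  trait <- match.arg(trait)
  mode <- match.arg(mode)
  traits <- apply_lifespan_correction(dataset$traits, factor = correction)
  traits <- impute_lifespan(traits, dataset$tree)
  keep <- filter_probes(dataset$detection, fdr = fdr,
                        species_fraction = species_fraction)
  agg <- aggregate_methylation(dataset$meth, mode)
  X <- agg$beta[, keep, drop = FALSE]
  sp <- agg$strata$species
  col <- switch(trait, max_lifespan = "max_lifespan_yr",
                gestation = "gestation_d", maturity = "maturity_yr")
  y <- to_log(traits[[col]][match(sp, traits$species)])
  names(y) <- rownames(X)
  observed <- if (trait == "max_lifespan")
    !traits$lifespan_imputed[match(sp, traits$species)]
  else rep(TRUE, length(sp))
  orders <- if (!is.null(dataset$tree$orders))
    unname(dataset$tree$orders[sp]) else rep(NA_character_, length(sp))
  list(x = X, y = y, species = sp, orders = orders, observed = observed,
       traits = traits, cpgs = keep, strata = agg$strata, trait = trait,
       mode = mode)
}
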