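#' Configuration for the synthetic methylation study generator
#'
#' Collects every knob of the synthetic-data generator: the size of the
#' species panel and CpG universe, the strength of the planted trait signal,
#' the noise structure at species and sample level, the confounders that the
#' downstream analyses are designed to probe (tissue offsets, sex effects in
#' a minority of species, age trends in selected species-tissue strata), probe
#' dropout, the trait-evolution model on the phylogeny, and an optional
#' low-divergence "breed-like" clade.
#'
#' Effects are planted on the beta scale: informative CpGs carry a logistic
#' link between the species mean beta value and log maximum life span, with
#' slope `effect_scale` (logit units per log-year). Sex and age effects are
#' beta offsets applied to the informative CpGs along the sign of each CpG's
#' trait slope, so that they project coherently onto model predictions.
#'
#' Recorded maximum life spans in the generated trait table are divided by
#' `anage_shortfall` (default 1.3) to emulate the systematic understatement of
#' curated life-span records that the analysis pipeline compensates with its
#' multiplicative correction; set it to 1 to disable.
#'
#' @param n_species number of species (tree tips); at least 10.
#' @param n_cpgs size of the CpG universe.
#' @param n_informative number of CpGs carrying the planted trait signal.
#' @param effect_scale slope of the logistic link between species mean beta
#'   and centred log maximum life span, in logit units per log-year.
#' @param noise_sd_species SD of idiosyncratic (phylogeny-independent)
#'   species-level beta noise added after the logistic link.
#' @param noise_sd_phylo tip-marginal SD of the phylogenetically correlated
#'   species-level beta noise, evolved by Brownian motion along the tree
#'   (closely related species share methylation signatures beyond their
#'   traits).
#' @param noise_sd_sample SD of within-species (per-sample) beta noise.
#' @param tissues named numeric vector of per-tissue beta offsets; names are
#'   the tissue labels.
#' @param n_sex_dimorphic number of species with a planted sex effect.
#' @param sex_effect magnitude of the planted female-minus-male beta offset at
#'   informative CpGs (sign randomised per species).
#' @param n_age_strata number of (species, tissue) strata with a planted age
#'   trend.
#' @param age_slope beta change per year of age at informative CpGs in the
#'   planted strata.
#' @param dropout_rate probability that a (species, CpG) pair fails detection;
#'   in `[0, 1)`.
#' @param brownian_sigma Brownian-motion rate of log maximum life span on the
#'   tree (log-years per square-root unit branch length).
#' @param root_lifespan maximum life span (years) at the tree root.
#' @param trait_link list with components `gestation` and `maturity`, each a
#'   numeric vector `c(intercept, slope, sd)` linking the log trait to centred
#'   log maximum life span.
#' @param weight_link numeric vector `c(intercept, slope, sd)` linking log
#'   adult weight (grams) to centred log maximum life span.
#' @param missing_lifespan_rate fraction of species whose recorded maximum
#'   life span is withheld (to exercise phylogenetic imputation).
#' @param anage_shortfall divisor applied to true maximum life span when
#'   writing the recorded trait table.
#' @param breed_clade `NULL`, or a list `list(size=, trait_sd=, meth_sd=)`
#'   describing a low-divergence clade: its members share a clade-level
#'   methylation signature (within-clade beta SD `meth_sd`) while their traits
#'   vary around the clade mean with SD `trait_sd` (log scale).
#' @param seed integer seed from which all generator randomness flows.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_dataset()], [simulate_tree()], [simulate_traits()],
#'   [simulate_methylation()]
#' @export
sim_config <- function(n_species = 120L,
                       n_cpgs = 3000L,
                       n_informative = 300L,
                       effect_scale = 0.4,
                       noise_sd_species = 0.05,
                       noise_sd_phylo = 0.04,
                       noise_sd_sample = 0.03,
                       tissues = c(blood = 0.02, liver = 0, skin = -0.02,
                                   muscle = 0.01),
                       n_sex_dimorphic = 8L,
                       sex_effect = 0.04,
                       n_age_strata = 10L,
                       age_slope = 0.003,
                       dropout_rate = 0.05,
                       brownian_sigma = 0.6,
                       root_lifespan = 20,
                       trait_link = list(
                         gestation = c(intercept = log(60), slope = 0.8, sd = 0.25),
                         maturity  = c(intercept = log(2),  slope = 0.9, sd = 0.30)),
                       weight_link = c(intercept = log(5000), slope = 1.5, sd = 1.0),
                       missing_lifespan_rate = 0.05,
                       anage_shortfall = 1.3,
                       breed_clade = NULL,
                       seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              n_cpgs = as.integer(n_cpgs),
              n_informative = as.integer(n_informative),
              effect_scale = effect_scale,
              noise_sd_species = noise_sd_species,
              noise_sd_phylo = noise_sd_phylo,
              noise_sd_sample = noise_sd_sample,
              tissues = tissues,
              n_sex_dimorphic = as.integer(n_sex_dimorphic),
              sex_effect = sex_effect,
              n_age_strata = as.integer(n_age_strata),
              age_slope = age_slope,
              dropout_rate = dropout_rate,
              brownian_sigma = brownian_sigma,
              root_lifespan = root_lifespan,
              trait_link = trait_link,
              weight_link = weight_link,
              missing_lifespan_rate = missing_lifespan_rate,
              anage_shortfall = anage_shortfall,
              breed_clade = breed_clade,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_species >= 10L,
            cfg$n_cpgs >= 1L,
            cfg$n_informative >= 0L)
  if (cfg$n_informative > cfg$n_cpgs)
    stop("n_informative must not exceed n_cpgs", call. = FALSE)
  sds <- c(cfg$noise_sd_species, cfg$noise_sd_phylo, cfg$noise_sd_sample,
           cfg$trait_link$gestation[["sd"]], cfg$trait_link$maturity[["sd"]],
           cfg$weight_link[["sd"]])
  if (any(sds < 0)) stop("all noise SDs must be >= 0", call. = FALSE)
  if (cfg$brownian_sigma < 0)
    stop("brownian_sigma must be >= 0", call. = FALSE)
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  if (length(cfg$tissues) < 1L || is.null(names(cfg$tissues)))
    stop("tissues must be a non-empty named vector of offsets", call. = FALSE)
  if (cfg$root_lifespan <= 0) stop("root_lifespan must be > 0", call. = FALSE)
  if (!is.null(cfg$breed_clade)) {
    bc <- cfg$breed_clade
    if (!all(c("size", "trait_sd", "meth_sd") %in% names(bc)))
      stop("breed_clade needs fields size, trait_sd, meth_sd", call. = FALSE)
    if (bc$size < 3 || bc$size > cfg$n_species / 2)
      stop("breed_clade size must be in [3, n_species/2]", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic methylation study configuration\n")
  cat(sprintf("  %d species, %d CpGs (%d informative), seed %d\n",
              x$n_species, x$n_cpgs, x$n_informative, x$seed))
  cat(sprintf("  effect %.2f logit/log-yr; noise SD %.3f (species) / %.3f (phylo) / %.3f (sample)\n",
              x$effect_scale, x$noise_sd_species, x$noise_sd_phylo, x$noise_sd_sample))
  cat(sprintf("  tissues: %s\n", paste(names(x$tissues), collapse = ", ")))
  cat(sprintf("  %d sex-dimorphic species (effect %.3f); %d age-trend strata (slope %.4f/yr)\n",
              x$n_sex_dimorphic, x$sex_effect, x$n_age_strata, x$age_slope))
  cat(sprintf("  dropout %.2f; Brownian sigma %.2f; root life span %.1f yr\n",
              x$dropout_rate, x$brownian_sigma, x$root_lifespan))
  if (!is.null(x$breed_clade))
    cat(sprintf("  breed clade: %d members, trait SD %.2f, methylation SD %.3f\n",
                x$breed_clade$size, x$breed_clade$trait_sd, x$breed_clade$meth_sd))
  invisible(x)
}
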