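#' Multiplicative correction of recorded maximum life spans
#'
#' Recorded maximum life spans for most species derive from few observations
#' and systematically understate the species' potential. This applies a
#' multiplicative correction `factor` (default 1.3) to the maximum life span
#' of every species except those in `exempt` (by default humans and mice,
#' whose records come from extensive observation), and marks the rows as
#' corrected. Rows already flagged as corrected are left untouched, making
#' the operation idempotent.
#'
#' @param traits trait table with columns `species`, `max_lifespan_yr` and
#'   (optionally) `lifespan_corrected`.
#' @param factor multiplicative correction, > 0.
#' @param exempt species whose records are taken at face value.
#' @return The trait table with corrected `max_lifespan_yr` and
#'   `lifespan_corrected` set.
#' @export
apply_lifespan_correction <- function(traits, factor = 1.3,
                                      exempt = c("Homo sapiens",
                                                 "Mus musculus")) {
  if (factor <= 0) stop("correction factor must be > 0", call. = FALSE)
  if (is.null(traits$lifespan_corrected))
    traits$lifespan_corrected <- FALSE
  idx <- !(traits$species %in% exempt) & !traits$lifespan_corrected &
    !is.na(traits$max_lifespan_yr)
  traits$max_lifespan_yr[idx] <- traits$max_lifespan_yr[idx] * factor
  traits$lifespan_corrected[idx | traits$species %in% exempt] <- TRUE
  traits
}

#' Natural-log trait transform and its inverse
#'
#' Life-history traits are strongly right-skewed; all modelling is done on
#' the natural-log scale. `to_log` refuses non-positive values;
#' `from_log(to_log(x))` returns `x` to machine precision.
#'
#' @param x trait values (years, days or grams), strictly positive for
#'   `to_log`.
#' @return Log-scale (resp. natural-scale) values.
#' @export
to_log <- function(x) {
  if (any(!is.na(x) & x <= 0))
    stop("trait values must be strictly positive", call. = FALSE)
  log(x)
}

#' @rdname to_log
#' @export
from_log <- function(x) exp(x)

#' Mean/SD calibration of predictions
#'
#' Affinely rescales predictions so that their mean and SD match those of the
#' observed trait values on the training data:
#' `y' = (y - mean(y)) / sd(y) * sd(obs) + mean(obs)`. The returned state
#' lets the same map be applied to new predictions, e.g. individual samples.
#'
#' @param predictions log-scale predictions on training data.
#' @param observed log-scale observed trait values, same length.
#' @return A list with `calibrated` (rescaled predictions) and `state`
#'   (class `calibration`, the four moments of the affine map).
#' @export
calibrate_predictions <- function(predictions, observed) {
  if (length(predictions) != length(observed) || length(observed) < 2L)
    stop("predictions and observed must have equal length >= 2",
         call. = FALSE)
  sp <- stats::sd(predictions)
  if (!is.finite(sp) || sp == 0)
    stop("degenerate predictor: predictions have zero SD", call. = FALSE)
  state <- structure(list(pred_mean = mean(predictions), pred_sd = sp,
                          obs_mean = mean(observed),
                          obs_sd = stats::sd(observed)),
                     class = "calibration")
  list(calibrated = apply_calibration(state, predictions), state = state)
}

#' @rdname calibrate_predictions
#' @param state a `calibration` state.
#' @param new new log-scale predictions to rescale.
#' @export
apply_calibration <- function(state, new) {
  stopifnot(inherits(state, "calibration"))
  (new - state$pred_mean) / state$pred_sd * state$obs_sd + state$obs_mean
}

#' Phylogenetic K = 1 imputation of missing maximum life spans
#'
#' Each species with a missing maximum life span receives the value of its
#' patristically nearest species with an observed value (ties broken by
#' lexicographic species name). Imputed rows are flagged and record their
#' source species so downstream analyses can exclude them.
#'
#' @param traits trait table with `species` and `max_lifespan_yr`.
#' @param tree phylogeny covering all species in `traits`.
#' @return The trait table with missing life spans filled,
#'   `lifespan_imputed` set and `lifespan_imputed_from` recording donors.
#' @export
impute_lifespan <- function(traits, tree) {
  if (!all(traits$species %in% tree$tip.label))
    stop("tree must cover every species in the trait table", call. = FALSE)
  missing <- which(is.na(traits$max_lifespan_yr))
  if (length(missing) == 0L) return(traits)
  observed <- traits$species[!is.na(traits$max_lifespan_yr)]
  if (length(observed) == 0L)
    stop("all maximum life spans missing; nothing to impute from",
         call. = FALSE)
  D <- tree_distances(tree)
  if (is.null(traits$lifespan_imputed)) traits$lifespan_imputed <- FALSE
  if (is.null(traits$lifespan_imputed_from))
    traits$lifespan_imputed_from <- NA_character_
  donors_sorted <- sort(observed)  # lexicographic tie-break
  for (i in missing) {
    d <- D[traits$species[i], donors_sorted]
    donor <- donors_sorted[which.min(d)]
    traits$max_lifespan_yr[i] <-
      traits$max_lifespan_yr[traits$species == donor]
    traits$lifespan_imputed[i] <- TRUE
    traits$lifespan_imputed_from[i] <- donor
  }
  traits
}
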