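#' Fit a sparse methylation predictor of a log life-history trait
#'
#' Trains an elastic-net linear model of a log-transformed life-history
#' trait on per-stratum mean beta values. Predictors are standardized (zero
#' mean, unit SD) before penalized fitting and the coefficients are returned
#' on the original beta scale; the penalty strength is chosen by internal
#' k-fold cross-validation on the training strata, minimizing mean squared
#' error. After fitting, the model's predictions are calibrated so their
#' mean and SD on the training data match the observed trait distribution;
#' the calibration is stored and applied to any new prediction.
#'
#' Optionally, one-hot taxonomic-order indicators can be appended as
#' candidate predictors alongside the CpGs; their selection status is
#' retained in the fitted object, allowing the "does the penalized model
#' prefer CpGs over taxonomy?" comparison.
#'
#' @param x strata x CpGs design matrix (an [aggregate_methylation()] result
#'   or a plain numeric matrix with CpG column names). No missing cells.
#' @param y numeric vector of log trait values, aligned with the rows of
#'   `x`; at least 10 strata, non-constant.
#' @param trait label for the modelled trait (e.g. `"max_lifespan"`).
#' @param alpha elastic-net mixing parameter in `(0, 1]` (1 = lasso);
#'   default 0.5.
#' @param nfolds internal cross-validation folds for penalty selection.
#' @param taxonomy optional character vector of taxonomic-order labels per
#'   row of `x`; when supplied, order indicators enter as candidate
#'   predictors.
#' @param seed optional integer seed for the internal fold assignment; when
#'   `NULL` the current RNG stream is used.
#' @return An object of class `trait_predictor` with components `intercept`,
#'   `coef` (named vector of nonzero CpG coefficients on the beta scale),
#'   `taxonomy_coef`, `cpgs` (the candidate CpG universe), `col_means`
#'   (training means, used to impute missing cells at prediction time),
#'   `calibration`, `lambda`, `alpha` and `trait`.
#' @seealso [predict.trait_predictor()], [loso_cv()], [loco_cv()]
#' @export
trait_predictor <- function(x, y, trait = "trait", alpha = 0.5, nfolds = 10L,
                            taxonomy = NULL, seed = NULL) {
  X <- design_matrix(x)
  n <- nrow(X)
  if (n < 10L) stop("insufficient data: need at least 10 strata",
                    call. = FALSE)
  if (length(y) != n) stop("y must align with the rows of x", call. = FALSE)
  if (anyNA(X) || anyNA(y))
    stop("design matrix and response must be complete", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("degenerate response: y is constant", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  if (nfolds < 2L) stop("nfolds must be at least 2", call. = FALSE)

  cpgs <- colnames(X)
  tax_cols <- character(0)
  if (!is.null(taxonomy)) {
    if (length(taxonomy) != n)
      stop("taxonomy labels must align with the rows of x", call. = FALSE)
    ind <- stats::model.matrix(~ ord - 1,
                               data.frame(ord = factor(taxonomy)))
    colnames(ind) <- paste0("taxon:", levels(factor(taxonomy)))
    tax_cols <- colnames(ind)
    X <- cbind(X, ind)
  }

  if (!is.null(seed)) set.seed(as.integer(seed))
  foldid <- sample(rep(seq_len(nfolds), length.out = n))
  cv <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                          standardize = TRUE, family = "gaussian",
                          grouped = n >= 3L * nfolds)
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1L]
  intercept <- cf[["(Intercept)"]]
  betas <- cf[-1L]
  nz <- betas[betas != 0]
  coef_cpg <- nz[names(nz) %in% cpgs]
  coef_tax <- betas[names(betas) %in% tax_cols]  # keep zeros: selection status

  fitted_raw <- drop(intercept + X %*% betas)
  calibration <- tryCatch(calibrate_predictions(fitted_raw, y)$state,
                          error = function(e) NULL)

  structure(list(trait = trait,
                 intercept = unname(intercept),
                 coef = coef_cpg,
                 taxonomy_coef = coef_tax,
                 cpgs = cpgs,
                 col_means = colMeans(X[, cpgs, drop = FALSE]),
                 col_sds = apply(X[, cpgs, drop = FALSE], 2L, stats::sd),
                 calibration = calibration,
                 lambda = cv$lambda.min,
                 alpha = alpha,
                 nfolds = as.integer(nfolds),
                 n_obs = n,
                 fitted = if (is.null(calibration)) fitted_raw
                          else apply_calibration(calibration, fitted_raw)),
            class = "trait_predictor")
}

design_matrix <- function(x) {
  if (inherits(x, "agg_beta")) x$beta
  else if (is.matrix(x)) x
  else as.matrix(x)
}

#' Predict log traits for new strata or individual samples
#'
#' Applies a fitted [trait_predictor()] to new beta values: a plain matrix,
#' an aggregated matrix, or sample-level [meth_data()]. Model CpGs missing
#' from the input (absent columns or `NA` cells) are imputed with the
#' model's stored training means. The model's stored mean/SD calibration is
#' applied unless `calibrated = FALSE`.
#'
#' @param object a `trait_predictor`.
#' @param newdata matrix, `agg_beta` or `meth_data` with CpG columns.
#' @param calibrated apply the stored calibration map (default `TRUE`).
#' @param taxonomy optional order labels per row, for models fitted with
#'   taxonomy indicators.
#' @param ... unused.
#' @return Numeric vector of log-scale predictions, named by row.
#' @export
predict.trait_predictor <- function(object, newdata, calibrated = TRUE,
                                    taxonomy = NULL, ...) {
  X <- if (inherits(newdata, "meth_data")) newdata$beta
       else design_matrix(newdata)
  used <- names(object$coef)
  raw <- rep(object$intercept, nrow(X))
  names(raw) <- rownames(X)
  if (length(used)) {
    sub <- matrix(rep(object$col_means[used], each = nrow(X)),
                  nrow = nrow(X), dimnames = list(rownames(X), used))
    have <- intersect(used, colnames(X))
    sub[, have] <- X[, have, drop = FALSE]
    miss <- is.na(sub)
    if (any(miss))
      sub[miss] <- rep(object$col_means[used], each = nrow(X))[miss]
    raw <- raw + drop(sub %*% object$coef[used])
  }
  nz_tax <- object$taxonomy_coef[object$taxonomy_coef != 0]
  if (length(nz_tax)) {
    if (is.null(taxonomy))
      warning("model uses taxonomy indicators but none supplied; treated as 0")
    else
      raw <- raw + ifelse(paste0("taxon:", taxonomy) %in% names(nz_tax),
                          nz_tax[paste0("taxon:", taxonomy)], 0)
  }
  if (calibrated && !is.null(object$calibration))
    raw <- apply_calibration(object$calibration, raw)
  raw
}

#' Apply a species-level model to individual samples
#'
#' Applies the fitted species-level predictor to every individual sample,
#' carrying the sample metadata through. Samples missing more than 20% of
#' the model's CpGs are flagged `low_confidence` but still predicted (with
#' training-mean imputation).
#'
#' @param model a [trait_predictor()].
#' @param md a [meth_data()] object.
#' @param calibrated apply the stored calibration (default `TRUE`).
#' @return `data.frame`: the sample sheet plus `predicted` (log scale) and
#'   `low_confidence`.
#' @export
predict_samples <- function(model, md, calibrated = TRUE) {
  stopifnot(inherits(model, "trait_predictor"), inherits(md, "meth_data"))
  pred <- predict(model, md, calibrated = calibrated)
  used <- names(model$coef)
  frac_missing <- if (length(used))
    rowMeans(is.na(md$beta[, intersect(used, colnames(md$beta)),
                           drop = FALSE]))
  else rep(0, nrow(md$beta))
  out <- md$samples
  out$predicted <- unname(pred)
  out$low_confidence <- frac_missing > 0.2
  out
}

#' @export
print.trait_predictor <- function(x, ...) {
  cat(sprintf("Elastic-net predictor of log %s (alpha = %.2f)\n",
              x$trait, x$alpha))
  cat(sprintf("  %d strata, %d candidate CpGs, %d nonzero coefficients\n",
              x$n_obs, length(x$cpgs), length(x$coef)))
  if (length(x$taxonomy_coef))
    cat(sprintf("  taxonomy indicators: %d candidates, %d selected\n",
                length(x$taxonomy_coef), sum(x$taxonomy_coef != 0)))
  cat(sprintf("  lambda = %.4g; calibrated: %s\n", x$lambda,
              !is.null(x$calibration)))
  invisible(x)
}

#' @export
summary.trait_predictor <- function(object, ...) {
  print(object)
  top <- sort(abs(object$coef), decreasing = TRUE)
  k <- min(10L, length(top))
  if (k > 0) {
    cat("  largest coefficients (|beta scale|):\n")
    for (nm in names(top)[seq_len(k)])
      cat(sprintf("    %s  % .4f\n", nm, object$coef[[nm]]))
  }
  invisible(object)
}

#' @export
coef.trait_predictor <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coef,
    object$taxonomy_coef[object$taxonomy_coef != 0])
}

#' Serialize a fitted predictor to JSON (and back)
#'
#' The JSON mirrors published coefficient tables: trait, intercept, one
#' record per CpG with its coefficient, plus the standardization and
#' calibration state, so externally published coefficient sets in the same
#' shape can be loaded and applied.
#'
#' @param model a `trait_predictor`.
#' @param path file path to write to.
#' @return `write_model`: the path, invisibly. `read_model`: the
#'   reconstructed `trait_predictor`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "trait_predictor"))
  obj <- list(trait = model$trait,
              intercept = model$intercept,
              cpgs = data.frame(id = names(model$coef),
                                coef = unname(model$coef)),
              taxonomy = data.frame(id = names(model$taxonomy_coef),
                                    coef = unname(model$taxonomy_coef)),
              standardization = list(mean = as.list(model$col_means),
                                     sd = as.list(model$col_sds)),
              calibration = if (!is.null(model$calibration))
                unclass(model$calibration),
              config = list(alpha = model$alpha, lambda = model$lambda,
                            nfolds = model$nfolds, n_obs = model$n_obs),
              universe = model$cpgs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @param path file path to read from.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calib <- if (!is.null(obj$calibration))
    structure(obj$calibration, class = "calibration")
  coefs <- stats::setNames(obj$cpgs$coef, obj$cpgs$id)
  if (length(coefs) == 0L) coefs <- stats::setNames(numeric(0), character(0))
  tax <- if (!is.null(obj$taxonomy$id))
    stats::setNames(obj$taxonomy$coef, obj$taxonomy$id)
  else stats::setNames(numeric(0), character(0))
  structure(list(trait = obj$trait,
                 intercept = obj$intercept,
                 coef = coefs,
                 taxonomy_coef = tax,
                 cpgs = obj$universe,
                 col_means = unlist(obj$standardization$mean),
                 col_sds = unlist(obj$standardization$sd),
                 calibration = calib,
                 lambda = obj$config$lambda,
                 alpha = obj$config$alpha,
                 nfolds = obj$config$nfolds,
                 n_obs = obj$config$n_obs,
                 fitted = NULL),
            class = "trait_predictor")
}
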