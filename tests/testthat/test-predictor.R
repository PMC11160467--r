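noise_design <- function(n = 30, p = 50, seed = 5) {
  set.seed(seed)
  X <- matrix(runif(n * p, 0.2, 0.8), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("cg%02d", 1:p)))
  X
}

test_that("a single exactly predictive CpG is recovered nearly perfectly", {
  X <- noise_design()
  y <- X[, "cg05"] * 4 + 1
  fit <- trait_predictor(X, y, seed = 1)
  expect_true("cg05" %in% names(fit$coef))
  expect_gt(cor(fit$fitted, y), 0.999)
  expect_lt(median(abs(fit$fitted - y)), 0.05)
})

test_that("degenerate fits are rejected", {
  X <- noise_design()
  expect_error(trait_predictor(X, rep(2, nrow(X))), "degenerate")
  expect_error(trait_predictor(X[1:8, ], rnorm(8)), "insufficient")
  expect_error(trait_predictor(X, rnorm(nrow(X)), alpha = 0), "alpha")
})

test_that("near-null signal yields a sparse, near-constant model", {
  X <- noise_design(seed = 7)
  set.seed(8)
  y <- rnorm(nrow(X))
  fit <- trait_predictor(X, y, seed = 9)
  # internal CV on pure noise should keep almost nothing
  expect_lt(length(fit$coef), 10)
})

test_that("predictions are consistent, deterministic, and mean-imputed when missing", {
  X <- noise_design()
  y <- X[, "cg05"] * 4 + 1 + rnorm(30, 0, 0.1)
  fit <- trait_predictor(X, y, seed = 2)
  # applying to the training rows reproduces the fitted values
  expect_equal(unname(predict(fit, X)), unname(fit$fitted))
  # duplicated rows give identical predictions
  X2 <- X[c(1, 1, 2), ]
  p2 <- predict(fit, X2)
  expect_equal(p2[[1]], p2[[2]])
  # an NA cell falls back to the training mean of that CpG
  X3 <- X[1:2, ]
  X3[1, names(fit$coef)[1]] <- NA
  X4 <- X[1:2, ]
  X4[1, names(fit$coef)[1]] <- fit$col_means[names(fit$coef)[1]]
  expect_equal(predict(fit, X3), predict(fit, X4))
})

test_that("an all-zero coefficient model predicts the calibrated constant", {
  mod <- structure(list(trait = "t", intercept = 2.5,
                        coef = setNames(numeric(0), character(0)),
                        taxonomy_coef = setNames(numeric(0), character(0)),
                        cpgs = c("cg1", "cg2"),
                        col_means = c(cg1 = 0.5, cg2 = 0.5),
                        col_sds = c(cg1 = 0.1, cg2 = 0.1),
                        calibration = NULL, lambda = 1, alpha = 0.5,
                        nfolds = 10L, n_obs = 20L, fitted = NULL),
                   class = "trait_predictor")
  X <- noise_design(n = 12)[, 1:2]
  colnames(X) <- c("cg1", "cg2")
  expect_equal(unname(predict(mod, X)), rep(2.5, 12))
})

test_that("the nonzero set is enriched for planted CpGs", {
  st <- small_study()
  fit <- trait_predictor(st$des$x, st$des$y, seed = 4)
  precision <- mean(names(fit$coef) %in% st$ds$truth$informative)
  base_rate <- length(st$ds$truth$informative) / ncol(st$des$x)
  expect_gt(precision, 2 * base_rate)
})

test_that("taxonomy indicators lose to CpGs on strongly CpG-driven data", {
  st <- default_study()
  fit <- cached("default_fit_tax",
                trait_predictor(st$des$x, st$des$y,
                                taxonomy = st$des$orders, seed = 6))
  expect_gt(length(fit$taxonomy_coef), 0)
  expect_true(all(fit$taxonomy_coef == 0))
})

test_that("model JSON serialization round-trips predictions", {
  st <- small_study()
  fit <- trait_predictor(st$des$x, st$des$y, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$coef, fit$coef)
  expect_equal(unname(predict(back, st$des$x)),
               unname(predict(fit, st$des$x)))
})

test_that("per-sample application carries metadata and flags sparse samples", {
  st <- small_study()
  fit <- trait_predictor(st$des$x, st$des$y, seed = 4)
  preds <- predict_samples(fit, st$ds$meth)
  expect_identical(nrow(preds), nrow(st$ds$meth$samples))
  expect_true(all(c("species", "tissue", "sex", "age_yr", "predicted",
                    "low_confidence") %in% names(preds)))
  # force > 20% of the model CpGs missing for one sample
  md <- st$ds$meth
  used <- intersect(names(fit$coef), colnames(md$beta))
  md$beta[1, used[seq_len(ceiling(0.5 * length(used)))]] <- NA
  flagged <- predict_samples(fit, md)
  expect_true(flagged$low_confidence[1])
  expect_false(is.na(flagged$predicted[1]))
})
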