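test_that("accuracy metrics follow the product-moment formula", {
  obs <- c(1, 2, 3, 4, 10)
  pred <- c(1.2, 1.9, 3.3, 3.6, 9.1)
  m <- accuracy_metrics(obs, pred)
  # hand-computed product-moment correlation
  r_hand <- sum((obs - mean(obs)) * (pred - mean(pred))) /
    sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  expect_equal(m$r, r_hand)
  expect_equal(m$mae, median(abs(obs - pred)))
  t_stat <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(m$p, 2 * pt(-abs(t_stat), 3))
  expect_equal(accuracy_metrics(obs, obs)$r, 1)
  expect_equal(accuracy_metrics(obs, obs)$mae, 0)
  cen <- obs - mean(obs)
  expect_equal(accuracy_metrics(obs, -cen)$r, -1)
  expect_error(accuracy_metrics(obs, rep(1, 5)), "zero variance")
  expect_error(accuracy_metrics(1:2, 1:2), "at least 3")
})

test_that("sex verdict matches the exhaustive truth table for up to 3 tissues", {
  p_levels <- c(0.001, 0.01, 0.02, 0.5)
  d_levels <- c(-0.4, 0.3)
  for (k in 1:3) {
    grid_p <- do.call(expand.grid, rep(list(p_levels), k))
    grid_d <- do.call(expand.grid, rep(list(d_levels), k))
    for (i in seq_len(nrow(grid_p))) for (j in seq_len(nrow(grid_d))) {
      pv <- as.numeric(grid_p[i, ]); dv <- as.numeric(grid_d[j, ])
      expect_identical(sex_verdict(pv, dv), oracle_verdict(pv, dv))
    }
  }
  expect_identical(sex_verdict(numeric(0), numeric(0)), ".")
})

test_that("species-level sex difference applies the consistency rule", {
  mk <- function(sp, tissue, f_shift, n = 8) {
    data.frame(species = sp, tissue = tissue,
               sex = rep(c("female", "male"), each = n),
               predicted = c(seq(1, 2, length.out = n) + f_shift,
                             seq(1, 2, length.out = n)))
  }
  # both tissues strongly positive -> "+"
  df <- rbind(mk("A", "blood", 5), mk("A", "liver", 5))
  out <- sex_difference(df)
  expect_identical(out$species$verdict[out$species$species == "A"], "+")
  # opposite significant directions -> "."
  df2 <- rbind(mk("B", "blood", 5), mk("B", "liver", -5))
  out2 <- sex_difference(df2)
  expect_identical(out2$species$verdict, ".")
  # a significant tissue plus an opposite non-significant one: only
  # significant tissues vote
  df3 <- rbind(mk("C", "blood", 5), mk("C", "liver", -0.01))
  out3 <- sex_difference(df3)
  expect_identical(out3$species$verdict, "+")
  # below-threshold p gives "."
  df4 <- mk("D", "blood", 0.2, n = 4)
  out4 <- sex_difference(df4)
  if (out4$tissues$p[1] > 0.01) expect_identical(out4$species$verdict, ".")
  # tissues with fewer than min_n per sex are skipped entirely
  df5 <- mk("E", "blood", 5, n = 1)
  out5 <- sex_difference(df5)
  expect_identical(nrow(out5$tissues), 0L)
  expect_identical(out5$species$verdict, ".")
})

test_that("the rank-sum p-value matches exact enumeration for small groups", {
  set.seed(10)
  for (rep in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    w <- wilcox.test(x, y, alternative = "two.sided")
    expect_equal(w$p.value, oracle_wilcox_p(x, y), tolerance = 1e-12)
  }
})

test_that("age association respects its preconditions and detects planted trends", {
  set.seed(11)
  # a 3-sample stratum is skipped
  df <- data.frame(species = "A", tissue = "t", age_yr = c(1, 2, 3),
                   predicted = rnorm(3))
  expect_identical(nrow(age_association(df)), 0L)
  # constant ages are skipped
  df2 <- data.frame(species = "A", tissue = "t", age_yr = rep(2, 6),
                    predicted = rnorm(6))
  expect_identical(nrow(age_association(df2)), 0L)
  # a strong planted trend is found
  age <- runif(12, 0, 10)
  df3 <- data.frame(species = "A", tissue = "t", age_yr = age,
                    predicted = 0.1 * age + rnorm(12, 0, 0.05))
  out <- age_association(df3)
  expect_identical(nrow(out), 1L)
  expect_gt(out$r, 0)
  expect_lt(out$p, 0.05)
})

test_that("weight adjustment reproduces the two-stage residual computation", {
  set.seed(12)
  n <- 12
  w <- rnorm(n)
  pred <- rnorm(n)
  obs <- 0.8 * pred + 0.3 * w + rnorm(n, 0, 0.2)
  res <- weight_adjusted_analysis(obs, pred, w)
  r1 <- resid(lm(obs ~ w)); r2 <- resid(lm(pred ~ w))
  expect_equal(res$adjusted_r, cor(r1, r2))
  expect_identical(res$coefficients$term,
                   c("(Intercept)", "predicted", "log_weight"))
  # weight independent of both: adjusted ~ unadjusted
  set.seed(13)
  pred2 <- rnorm(200); obs2 <- pred2 + rnorm(200, 0, 0.5); w2 <- rnorm(200)
  res2 <- weight_adjusted_analysis(obs2, pred2, w2)
  expect_lt(abs(res2$adjusted_r - cor(obs2, pred2)), 0.05)
  # prediction fully mediated by weight: adjusted ~ 0
  w3 <- rnorm(200); pred3 <- 2 * w3 + rnorm(200, 0, 1e-8)
  obs3 <- w3 + rnorm(200, 0, 0.3)
  res3 <- suppressWarnings(weight_adjusted_analysis(obs3, pred3, w3))
  expect_lt(abs(res3$adjusted_r), 0.1)
  expect_true(res3$collinear)
})

test_that("group contrasts are null-calibrated and sensitive to planted shifts", {
  set.seed(14)
  # label permutation of one sample set: Z near 0
  v <- rnorm(40)
  out <- group_comparison(v, rep(c("ctrl", "trt"), 20), control = "ctrl")
  expect_lt(abs(out$z), 2.5)
  # planted +0.5 shift, n = 20/20, noise SD 0.3: clearly significant
  pred <- c(rnorm(20, 0, 0.3), rnorm(20, 0.5, 0.3))
  grp <- rep(c("ctrl", "trt"), each = 20)
  out2 <- group_comparison(pred, grp, control = "ctrl", expected_sign = 1)
  expect_true(out2$significant)
  expect_gt(out2$z, 0)
  expect_true(out2$concordant)
  # single-group stratum skipped
  out3 <- group_comparison(c(pred, rnorm(4)), c(grp, rep("ctrl", 4)),
                           c(rep("a", 40), rep("b", 4)), control = "ctrl")
  expect_identical(out3$stratum, "a")
})

test_that("age acceleration residuals are orthogonal to age", {
  set.seed(15)
  age <- runif(30, 0, 20)
  pred <- 0.05 * age + rnorm(30, 0, 0.3)
  acc <- ageaccel(pred, age)
  expect_lt(abs(mean(acc)), 1e-9)
  expect_lt(abs(cor(acc, age)), 1e-9)
  # exact linear fit leaves zero residuals
  expect_equal(ageaccel(2 * age + 1, age), rep(0, 30), tolerance = 1e-9)
  # age-independent predictions: residuals are the centred predictions
  pred2 <- rep(c(1, 2), 15)
  acc2 <- ageaccel(pred2, age)
  expect_equal(acc2, pred2 - mean(pred2) -
                 (age - mean(age)) * cov(pred2, age) / var(age))
  expect_error(ageaccel(pred, rep(3, 30)), "constant")
})

test_that("breed analysis derives maximum life span as 1.33 x the median", {
  set.seed(16)
  breeds <- c("GreatDane", "Beagle", "ToyPoodle")
  preds <- data.frame(breed = rep(breeds, each = 5),
                      predicted = log(13) + rnorm(15, 0, 1e-6))
  info <- data.frame(breed = breeds,
                     median_lifespan_yr = c(6.3, 12, 14.6),
                     weight_g = c(64000, 10000, 2300))
  out <- breed_analysis(preds, info)
  tab <- out$table
  expect_equal(tab$derived_max_yr[tab$breed == "GreatDane"], 8.379)
  expect_equal(log(tab$derived_max_yr[tab$breed == "GreatDane"]), 2.126,
               tolerance = 1e-3)
  expect_equal(tab$derived_max_yr[tab$breed == "ToyPoodle"], 19.418)
  expect_identical(tab$n, rep(5L, 3))
  # near-constant predictions: no correlation with breed life span
  expect_lt(abs(out$cor_lifespan), 0.999)
  expect_gt(out$p_lifespan, 0.05)
})
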