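cv_fixture <- function(n = 14, p = 40, seed = 3) {
  set.seed(seed)
  X <- matrix(runif(n * p, 0.2, 0.8), n, p,
              dimnames = list(sprintf("sp%02d", 1:n), sprintf("cg%02d", 1:p)))
  y <- setNames(2 * X[, 1] - X[, 2] + rnorm(n, 0, 0.05), rownames(X))
  list(X = X, y = y)
}

test_that("LOSO builds one fold per species and predicts each stratum once", {
  f <- cv_fixture()
  cv <- loso_cv(f$X, f$y, nfolds = 4, seed = 1)
  expect_identical(sort(unique(cv$predictions$fold)), sort(rownames(f$X)))
  expect_identical(nrow(cv$predictions), nrow(f$X))
  expect_false(anyDuplicated(cv$predictions$stratum) > 0)
  # summary metrics recompute from the per-stratum rows
  m <- accuracy_metrics(cv$predictions$observed, cv$predictions$predicted)
  expect_equal(m$r, cv$metrics$r)
  expect_equal(m$mae, cv$metrics$mae)
})

test_that("LOSO never leaks the held-out species into its own training", {
  f <- cv_fixture()
  cv1 <- loso_cv(f$X, f$y, nfolds = 4, seed = 7)
  y2 <- f$y
  y2["sp03"] <- y2["sp03"] + 100  # only this species' response changes
  cv2 <- loso_cv(f$X, y2, nfolds = 4, seed = 7)
  p1 <- cv1$predictions$predicted[cv1$predictions$species == "sp03"]
  p2 <- cv2$predictions$predicted[cv2$predictions$species == "sp03"]
  expect_equal(p1, p2)
})

test_that("tissue-aware LOSO holds out all strata of a species together", {
  st <- small_study()
  des <- prepare_design(st$ds, mode = "species_tissue")
  cv <- suppressWarnings(loso_cv(des$x, des$y, species = des$species,
                                 seed = 5))
  expect_identical(sort(unique(cv$predictions$fold)),
                   sort(unique(des$species)))
  expect_identical(nrow(cv$predictions), nrow(des$x))
  by_sp <- table(cv$predictions$species, cv$predictions$fold)
  # every stratum of a species carries that species' fold id
  expect_true(all(by_sp[cbind(rownames(by_sp), rownames(by_sp))] ==
                  table(des$species)[rownames(by_sp)]))
})

test_that("LOCO folds follow the modified leave-one-clade-out rule", {
  sizes <- c(25, 21, 20, 5, 1)
  orders <- rep(sprintf("ord%d", seq_along(sizes)), times = sizes)
  species <- sprintf("sp%03d", seq_len(sum(sizes)))
  set.seed(2)
  y <- setNames(runif(length(species), 1, 5), species)
  folds <- loco_folds(y, orders)
  expect_identical(length(folds), 5L)
  for (f in folds) {
    members <- species[orders == f$fold]
    if (length(members) > 20) {
      expect_identical(length(f$keep), 2L)
      ym <- y[members]
      expect_setequal(f$keep, c(names(which.min(ym)), names(which.max(ym))))
      expect_setequal(f$test, setdiff(members, f$keep))
    } else {
      expect_identical(f$keep, character(0))
      expect_setequal(f$test, members)  # size-20 order fully held out
    }
  }
  # every species tested at most once; retained extremes never tested
  tested <- unlist(lapply(folds, `[[`, "test"))
  expect_false(anyDuplicated(tested) > 0)
  kept <- unlist(lapply(folds, `[[`, "keep"))
  expect_length(intersect(tested, kept), 0)
})

test_that("LOCO min/max ties break lexicographically", {
  orders <- rep("big", 22)
  species <- sprintf("sp%02d", 1:22)
  y <- setNames(c(rep(1, 3), rep(5, 2), runif(17, 2, 4)), species)
  folds <- loco_folds(y, orders)
  expect_identical(folds[[1]]$keep, c("sp01", "sp04"))
})

test_that("LOCO excludes imputed species from training and testing", {
  st <- small_study()
  des <- st$des
  traits <- des$traits
  traits$lifespan_imputed[match(des$species[1:4], traits$species)] <- TRUE
  cv <- loco_cv(des$x, des$y, orders = des$orders, traits = traits,
                nfolds = 5, seed = 2)
  expect_length(intersect(cv$predictions$species, des$species[1:4]), 0)
})

test_that("species splits are disjoint, exhaustive and seeded", {
  species <- sprintf("sp%03d", 1:100)
  sp1 <- split_train_test(species, 0.7, seed = 5)
  sp2 <- split_train_test(species, 0.7, seed = 5)
  expect_identical(sp1, sp2)
  expect_identical(length(sp1$train), 70L)
  expect_identical(length(sp1$test), 30L)
  expect_setequal(c(sp1$train, sp1$test), species)
  expect_length(intersect(sp1$train, sp1$test), 0)
  sp3 <- split_train_test(species, 0.7, seed = 6)
  expect_false(identical(sp1$train, sp3$train))
})
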