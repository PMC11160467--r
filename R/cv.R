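#' Leave-one-species-out cross-validation of a trait predictor
#'
#' Iteratively refits the elastic-net predictor with one species entirely
#' held out (in tissue-aware mode, all strata of that species leave
#' together) and predicts the held-out strata with the fold's own model and
#' calibration. The held-out prediction never uses the species' own rows.
#'
#' @param x strata x CpGs matrix or [aggregate_methylation()] result.
#' @param y log trait values aligned with the rows of `x`.
#' @param species species label per row; defaults to the `agg_beta` strata
#'   (or the rownames of a plain matrix).
#' @param trait,alpha,nfolds passed to [trait_predictor()].
#' @param seed integer seed; all fold randomness flows from it.
#' @return A `trait_cv` object: `predictions` (one row per stratum with
#'   `stratum`, `species`, `fold`, `observed`, `predicted`) and `metrics`
#'   (Pearson R, two-sided p, median absolute error).
#' @export
loso_cv <- function(x, y, species = NULL, trait = "trait", alpha = 0.5,
                    nfolds = 10L, seed = 1L) {
  X <- design_matrix(x)
  if (is.null(species))
    species <- if (inherits(x, "agg_beta")) x$strata$species else rownames(X)
  if (is.null(species) || length(species) != nrow(X))
    stop("species labels must align with the rows of x", call. = FALSE)
  sp_set <- unique(species)
  if (length(sp_set) < 10L)
    stop("insufficient data: need at least 10 species", call. = FALSE)
  set.seed(as.integer(seed))
  rows <- lapply(sp_set, function(sp) {
    test <- which(species == sp)
    fit <- trait_predictor(X[-test, , drop = FALSE], y[-test], trait = trait,
                           alpha = alpha, nfolds = nfolds)
    pred <- predict(fit, X[test, , drop = FALSE])
    data.frame(stratum = rownames(X)[test], species = sp, fold = sp,
               observed = y[test], predicted = unname(pred),
               stringsAsFactors = FALSE)
  })
  new_trait_cv(do.call(rbind, rows), scheme = "loso")
}

#' Fold construction for the modified leave-one-clade-out scheme
#'
#' One fold per taxonomic order. Orders with more than 20 species keep
#' exactly two members in training — those with the minimum and the maximum
#' trait value (ties broken by lexicographic species name) — and the rest
#' form the test set; orders with 20 or fewer species are held out
#' completely. The retained species of large orders are never tested.
#'
#' @param y named vector of (log) trait values, one per species.
#' @param orders taxonomic order label per species (aligned with `y`).
#' @param large size above which an order retains its extreme members.
#' @return List of folds, each `list(fold = order, test = species,
#'   keep = retained species)`.
#' @export
loco_folds <- function(y, orders, large = 20L) {
  species <- names(y)
  if (is.null(species)) stop("y must be named by species", call. = FALSE)
  if (length(orders) != length(y))
    stop("orders must align with y", call. = FALSE)
  lapply(split(species, orders), function(members) {
    lab <- orders[match(members[1L], species)]
    if (length(members) > large) {
      ym <- y[members]
      # ties at either extreme break by lexicographic species name
      keep <- c(members[order(ym, members)][1L],
                members[order(-ym, members)][1L])
      list(fold = unname(lab), test = setdiff(members, keep), keep = keep)
    } else {
      list(fold = unname(lab), test = members, keep = character(0))
    }
  })
}

#' Leave-one-clade-out cross-validation
#'
#' Cross-validates the predictor over taxonomic orders under the modified
#' scheme of [loco_folds()]. Species whose trait value was imputed are
#' excluded from the analysis entirely (training and testing) when a trait
#' table with imputation flags is supplied, so the comparison against the
#' phylogenetic baseline is not biased in its favour.
#'
#' @inheritParams loso_cv
#' @param orders named species -> taxonomic order map (or a vector aligned
#'   with the rows of `x`).
#' @param traits optional trait table with `lifespan_imputed` flags.
#' @param large order size above which only the extreme members stay in
#'   training.
#' @return A `trait_cv` object; fold ids are order labels.
#' @export
loco_cv <- function(x, y, orders, traits = NULL, trait = "trait",
                    alpha = 0.5, nfolds = 10L, seed = 1L, large = 20L) {
  X <- design_matrix(x)
  species <- if (inherits(x, "agg_beta")) x$strata$species else rownames(X)
  if (!is.null(names(orders))) orders <- unname(orders[species])
  if (!is.null(traits) && !is.null(traits$lifespan_imputed)) {
    imputed <- traits$species[traits$lifespan_imputed]
    keep <- !(species %in% imputed)
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
    orders <- orders[keep]
    species <- species[keep]
  }
  ysp <- stats::setNames(y[match(unique(species), species)], unique(species))
  folds <- loco_folds(ysp, orders[match(names(ysp), species)], large = large)
  set.seed(as.integer(seed))
  rows <- lapply(folds, function(f) {
    if (length(f$test) == 0L) return(NULL)
    test <- which(species %in% f$test)
    fit <- trait_predictor(X[-test, , drop = FALSE], y[-test], trait = trait,
                           alpha = alpha, nfolds = nfolds)
    pred <- predict(fit, X[test, , drop = FALSE])
    data.frame(stratum = rownames(X)[test], species = species[test],
               fold = f$fold, observed = y[test], predicted = unname(pred),
               stringsAsFactors = FALSE)
  })
  res <- new_trait_cv(do.call(rbind, rows), scheme = "loco",
                      extra = list(folds = folds))
  res
}

#' Random species-level train/test partition
#'
#' Splits the species list into disjoint, exhaustive train and test sets
#' (all strata of a species fall on the same side).
#'
#' @param species character vector of species.
#' @param fraction training fraction (default 0.7).
#' @param seed integer seed.
#' @return `list(train =, test =)` of species names.
#' @export
split_train_test <- function(species, fraction = 0.7, seed = 1L) {
  species <- unique(species)
  if (length(species) < 10L)
    stop("need at least 10 species to split", call. = FALSE)
  set.seed(as.integer(seed))
  n_train <- round(fraction * length(species))
  train <- sample(species, n_train)
  list(train = sort(train), test = sort(setdiff(species, train)))
}

new_trait_cv <- function(rows, scheme, extra = list()) {
  rownames(rows) <- NULL
  if (anyDuplicated(rows$stratum))
    stop("internal error: a stratum was predicted more than once",
         call. = FALSE)
  metrics <- accuracy_metrics(rows$observed, rows$predicted)
  structure(c(list(predictions = rows, metrics = metrics, scheme = scheme),
              extra),
            class = "trait_cv")
}

#' @export
print.trait_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("%s cross-validation: %d strata, %d folds\n", x$scheme,
              nrow(x$predictions), length(unique(x$predictions$fold))))
  cat(sprintf("  Pearson R = %.3f (p = %.3g), MAE = %.3f\n",
              m$r, m$p, m$mae))
  invisible(x)
}

#' @export
summary.trait_cv <- function(object, ...) {
  print(object)
  by_fold <- tapply(abs(object$predictions$observed -
                        object$predictions$predicted),
                    object$predictions$fold, stats::median)
  cat("  per-fold median |error| quartiles: ",
      paste(sprintf("%.3f", stats::quantile(by_fold, c(.25, .5, .75))),
            collapse = " / "), "\n")
  invisible(object)
}
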