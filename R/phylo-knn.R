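#' Patristic distance matrix of a phylogeny
#'
#' Pairwise distances between tips, each the sum of branch lengths along the
#' path connecting the two tips.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return Symmetric species x species matrix with zero diagonal.
#' @export
tree_distances <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have complete branch lengths", call. = FALSE)
  ape::cophenetic.phylo(tree)
}

#' Phylogenetic k-nearest-neighbour trait prediction
#'
#' Predicts a species' log trait as the unweighted mean of the trait values
#' of its `k` patristically nearest training species. With `k = 1` this is
#' the "closest taxonomic neighbour" baseline against which the methylation
#' predictor is compared. Distance ties are broken by lexicographic species
#' name, making predictions deterministic.
#'
#' @param distances symmetric patristic distance matrix covering training
#'   species and targets.
#' @param y named vector of log trait values for the training species.
#' @param targets species to predict; must be disjoint from the training set.
#' @param k number of neighbours, between 1 and `length(y)`.
#' @return Named vector of predictions for `targets`.
#' @export
knn_predict <- function(distances, y, targets, k = 1L) {
  train <- names(y)
  if (is.null(train) || length(train) == 0L)
    stop("y must be a non-empty named vector of training values",
         call. = FALSE)
  if (k < 1L || k > length(train))
    stop("k must be between 1 and the training-set size", call. = FALSE)
  if (any(targets %in% train))
    stop("target species present in the training set (leakage)",
         call. = FALSE)
  missing <- setdiff(c(train, targets), rownames(distances))
  if (length(missing))
    stop("distance matrix lacks species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  # iterated minimum extraction with name tie-break
  vapply(targets, function(tg) {
    d <- distances[tg, train]
    nm <- train
    picked <- numeric(k)
    for (j in seq_len(k)) {
      cand <- which(d == min(d))
      pick <- cand[order(nm[cand])[1L]]
      picked[j] <- y[[nm[pick]]]
      d <- d[-pick]
      nm <- nm[-pick]
    }
    mean(picked)
  }, numeric(1L))
}

#' Cross-validate the phylogenetic k-NN baseline
#'
#' Runs the k-NN predictor under the same fold structures as the methylation
#' predictor: leave-one-species-out, or the modified leave-one-clade-out
#' scheme (see [loco_folds()]).
#'
#' @param tree phylogeny covering the species in `y` (or a precomputed
#'   distance matrix).
#' @param y named vector of log trait values.
#' @param scheme `"loso"` or `"loco"`.
#' @param orders named species -> taxonomic order map (required for
#'   `"loco"`).
#' @param k number of neighbours.
#' @return A `trait_cv` object (see [loso_cv()]).
#' @export
knn_cv <- function(tree, y, scheme = c("loso", "loco"), orders = NULL,
                   k = 1L) {
  scheme <- match.arg(scheme)
  D <- if (is.matrix(tree)) tree else tree_distances(tree)
  species <- names(y)
  if (scheme == "loso") {
    folds <- lapply(species, function(sp) list(fold = sp, test = sp))
  } else {
    if (is.null(orders)) stop("loco scheme needs an orders map", call. = FALSE)
    folds <- loco_folds(y, orders[species])
  }
  rows <- lapply(folds, function(f) {
    train <- setdiff(species, f$test)
    if (!is.null(f$keep)) train <- union(train, f$keep)
    pred <- knn_predict(D, y[train], f$test, k = k)
    data.frame(stratum = f$test, species = f$test, fold = f$fold,
               observed = unname(y[f$test]), predicted = unname(pred),
               stringsAsFactors = FALSE)
  })
  new_trait_cv(do.call(rbind, rows), scheme = paste0("knn-", scheme),
               extra = list(k = k))
}
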