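#' Simulate phylogenetically autocorrelated life-history traits
#'
#' Log maximum life span evolves by Brownian motion along the tree from a
#' root value of `log(root_lifespan)`, at rate `brownian_sigma`. Log
#' gestation time, log age at sexual maturity and log adult weight are then
#' linear in centred log maximum life span plus independent Gaussian noise,
#' reproducing the strong cross-correlations (and right skew on the natural
#' scale) of real mammalian trait tables.
#'
#' The recorded `max_lifespan_yr` column is the true value divided by
#' `anage_shortfall` (emulating understated curated records; the analysis
#' pipeline's multiplicative correction undoes this), and a fraction
#' `missing_lifespan_rate` of species have it withheld (`NA`) to exercise
#' phylogenetic imputation. If `breed_clade` is configured, the members of
#' one clade of (approximately) the requested size have their log maximum
#' life span redrawn around the clade mean with SD `trait_sd`, creating
#' within-clade trait variance that the shared clade methylation signature
#' (see [simulate_methylation()]) does not track.
#'
#' @param tree a phylogeny from [simulate_tree()] (tips = species universe).
#' @param config a [sim_config()] object.
#' @return A `data.frame` with columns `species`, `order`, `max_lifespan_yr`,
#'   `gestation_d`, `maturity_yr`, `weight_g`, `breed_clade`,
#'   `lifespan_corrected`, `lifespan_imputed`, `lifespan_imputed_from`.
#'   The generative truth (true log traits per species) is attached as
#'   attribute `"truth"`.
#' @export
simulate_traits <- function(tree, config) {
  validate_sim_config(config)
  if (config$brownian_sigma < 0)
    stop("brownian_sigma must be >= 0", call. = FALSE)
  species <- tree$tip.label
  n <- length(species)
  set.seed(config$seed + 1L)

  log_mls <- brownian_tips(tree, root = log(config$root_lifespan),
                           sigma = config$brownian_sigma)

  in_breed <- rep(FALSE, n)
  names(in_breed) <- species
  if (!is.null(config$breed_clade)) {
    members <- pick_clade(tree, config$breed_clade$size)
    in_breed[members] <- TRUE
    m <- length(members)
    log_mls[members] <- mean(log_mls[members]) +
      stats::rnorm(m, 0, config$breed_clade$trait_sd)
  }

  centred <- log_mls - log(config$root_lifespan)
  gl <- config$trait_link$gestation
  ml <- config$trait_link$maturity
  wl <- config$weight_link
  log_gest <- gl[["intercept"]] + gl[["slope"]] * centred +
    stats::rnorm(n, 0, gl[["sd"]])
  log_mat <- ml[["intercept"]] + ml[["slope"]] * centred +
    stats::rnorm(n, 0, ml[["sd"]])
  log_wt <- wl[["intercept"]] + wl[["slope"]] * centred +
    stats::rnorm(n, 0, wl[["sd"]])

  recorded <- exp(log_mls) / config$anage_shortfall
  n_missing <- floor(config$missing_lifespan_rate * n)
  if (n_missing > 0) {
    missing <- sample(species, n_missing)
    recorded[match(missing, species)] <- NA_real_
  }

  orders <- if (!is.null(tree$orders)) unname(tree$orders[species])
            else rep(NA_character_, n)
  traits <- data.frame(species = species,
                       order = orders,
                       max_lifespan_yr = recorded,
                       gestation_d = exp(log_gest),
                       maturity_yr = exp(log_mat),
                       weight_g = exp(log_wt),
                       breed_clade = unname(in_breed),
                       lifespan_corrected = FALSE,
                       lifespan_imputed = FALSE,
                       lifespan_imputed_from = NA_character_,
                       stringsAsFactors = FALSE)
  attr(traits, "tree") <- tree
  attr(traits, "truth") <- data.frame(species = species,
                                      log_mls = unname(log_mls),
                                      log_gestation = log_gest,
                                      log_maturity = log_mat,
                                      log_weight = log_wt,
                                      stringsAsFactors = FALSE)
  traits
}

# Brownian motion along edges, preorder from the root; returns tip values
# named by tip label.
brownian_tips <- function(tree, root, sigma) {
  n_tip <- ape::Ntip(tree)
  ord <- ape::reorder.phylo(tree, "cladewise")
  val <- numeric(n_tip + tree$Nnode)
  val[n_tip + 1L] <- root
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1L]
    ch <- ord$edge[k, 2L]
    val[ch] <- val[p] + stats::rnorm(1L, 0, sigma * sqrt(ord$edge.length[k]))
  }
  stats::setNames(val[seq_len(n_tip)], tree$tip.label)
}

# Tips of the internal clade whose size is closest to `size` (at least 3).
pick_clade <- function(tree, size) {
  n_tip <- ape::Ntip(tree)
  parts <- ape::prop.part(tree)
  sizes <- lengths(parts)
  ok <- which(sizes >= 3 & sizes <= n_tip / 2)
  if (length(ok) == 0L) stop("no clade of usable size in tree", call. = FALSE)
  best <- ok[which.min(abs(sizes[ok] - size))]
  tree$tip.label[parts[[best]]]
}
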