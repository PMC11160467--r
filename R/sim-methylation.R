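#' Simulate methylation, detection p-values and planted truth
#'
#' Generates a sample design (2-8 samples per species spread over 1-4
#' tissues, ages uniform on `[0, 0.8 x maximum life span]`), then beta values
#' under the generative model:
#'
#' * informative CpGs: species mean beta = `plogis(baseline + slope x centred
#'   log maximum life span)`, slope magnitude `effect_scale` with random sign;
#' * non-informative CpGs: trait-independent species baselines;
#' * species-level noise on the beta scale with two components: an
#'   idiosyncratic per-species signature (SD `noise_sd_species`) and a
#'   phylogenetically correlated part evolved by Brownian motion along the
#'   tree (tip SD `noise_sd_phylo`) — closely related species share
#'   methylation signatures beyond what their traits explain, as
#'   phylo-epigenetic structure in real data does, which is what makes
#'   extrapolation to unseen clades harder than interpolation between
#'   relatives;
#' * a per-tissue beta offset; planted sex effects (beta offset
#'   `sex_effect` at informative CpGs along each CpG's slope sign, sign
#'   randomised per dimorphic species) and planted age trends (`age_slope`
#'   beta/year, same projection) in designated species-tissue strata;
#' * per-sample Gaussian noise (`noise_sd_sample`), then a hard clip to
#'   `[0, 1]`.
#'
#' Sex-dimorphic species receive 12 samples (6 per sex) in a single tissue so
#' the within-stratum rank tests downstream are informative; age-trend
#' species receive 8 samples in the designated tissue. Members of a
#' configured breed clade all share the methylation signature implied by the
#' clade mean trait (within-clade SD `meth_sd`), decoupling their individual
#' traits from their methylation.
#'
#' Each (species, CpG) pair fails detection with probability `dropout_rate`;
#' failing pairs get a median detection p drawn from Uniform(0.1, 1) and
#' their beta values set to `NA`, others from Uniform(0, 1e-4).
#'
#' @param traits trait table from [simulate_traits()] (must carry its
#'   `"truth"` attribute).
#' @param config a [sim_config()] object.
#' @param tree the phylogeny used for the species-level noise; defaults to
#'   the tree attached by [simulate_traits()]. When `NULL`, species-level
#'   noise is drawn independently per species instead.
#' @return A list with components `meth` (a [meth_data()] object),
#'   `detection` (species x CpGs matrix of median detection p-values) and
#'   `truth` (planted truth: informative CpG ids, per-CpG slope/sign,
#'   dimorphic species with effect signs, age-trend strata, true log traits).
#' @export
simulate_methylation <- function(traits, config, tree = attr(traits, "tree")) {
  validate_sim_config(config)
  truth_traits <- attr(traits, "truth")
  if (is.null(truth_traits))
    stop("traits must come from simulate_traits() (missing truth attribute)",
         call. = FALSE)
  species <- traits$species
  n <- length(species)
  if (n == 0L) stop("empty sample design", call. = FALSE)
  set.seed(config$seed + 2L)

  cpgs <- sprintf("cg%05d", seq_len(config$n_cpgs))
  informative <- sort(sample.int(config$n_cpgs, config$n_informative))
  sign_j <- sample(c(-1, 1), config$n_informative, replace = TRUE)
  slope_j <- config$effect_scale * sign_j
  baseline <- stats::runif(config$n_cpgs, -1, 1)

  log_mls <- stats::setNames(truth_traits$log_mls, truth_traits$species)
  centred <- log_mls - mean(log_mls)
  in_breed <- traits$breed_clade
  # breed members express the clade mean trait, not their own
  centred_expr <- centred
  if (any(in_breed)) centred_expr[in_breed] <- mean(centred[in_breed])

  # species mean beta
  eta <- matrix(baseline, nrow = n, ncol = config$n_cpgs, byrow = TRUE)
  eta[, informative] <- eta[, informative] +
    outer(unname(centred_expr), slope_j)
  M <- stats::plogis(eta)
  noise <- matrix(stats::rnorm(n * config$n_cpgs, 0,
                               config$noise_sd_species), nrow = n)
  if (!is.null(tree) && config$noise_sd_phylo > 0)
    noise <- noise + bm_noise_matrix(tree, config$n_cpgs,
                                     config$noise_sd_phylo)[species, , drop = FALSE]
  # breed-clade members barely diverge from each other epigenetically
  if (any(in_breed) && !is.null(config$breed_clade)) {
    clade_noise <- colMeans(noise[in_breed, , drop = FALSE])
    noise[in_breed, ] <- matrix(clade_noise, nrow = sum(in_breed),
                                ncol = config$n_cpgs, byrow = TRUE) +
      stats::rnorm(sum(in_breed) * config$n_cpgs, 0,
                   config$breed_clade$meth_sd)
  }
  M <- M + noise
  dimnames(M) <- list(species, cpgs)

  # planted sex and age effects
  eligible <- species[!in_breed]
  dimorphic <- sort(sample(eligible, min(config$n_sex_dimorphic,
                                         length(eligible))))
  sex_sign <- stats::setNames(sample(c(-1, 1), length(dimorphic),
                                     replace = TRUE), dimorphic)
  age_pool <- setdiff(eligible, dimorphic)
  age_species <- sort(sample(age_pool, min(config$n_age_strata,
                                           length(age_pool))))
  tissue_names <- names(config$tissues)
  age_tissue <- stats::setNames(sample(tissue_names, length(age_species),
                                       replace = TRUE), age_species)

  # sample design
  mls_years <- exp(log_mls)
  design <- lapply(species, function(sp) {
    if (sp %in% dimorphic) {
      k <- 12L
      tis <- rep(sample(tissue_names, 1L), k)
      sex <- rep(c("female", "male"), each = 6L)
    } else if (sp %in% age_species) {
      k <- 8L
      tis <- rep(age_tissue[[sp]], k)
      sex <- sample(c("female", "male"), k, replace = TRUE)
    } else {
      k <- sample(2:8, 1L)
      pool <- sample(tissue_names, sample.int(min(4L, length(tissue_names)), 1L))
      tis <- sample(pool, k, replace = TRUE)
      sex <- sample(c("female", "male"), k, replace = TRUE)
    }
    data.frame(species = sp, tissue = tis, sex = sex,
               age_yr = stats::runif(k, 0, 0.8 * mls_years[[sp]]),
               stringsAsFactors = FALSE)
  })
  samples <- do.call(rbind, design)
  samples$sample_id <- sprintf("s%04d", seq_len(nrow(samples)))
  samples <- samples[, c("sample_id", "species", "tissue", "sex", "age_yr")]

  # sample-level beta
  sp_idx <- match(samples$species, species)
  beta <- M[sp_idx, , drop = FALSE]
  beta <- beta + config$tissues[samples$tissue]
  is_f <- samples$sex == "female"
  dim_idx <- which(samples$species %in% dimorphic)
  if (length(dim_idx) && config$sex_effect != 0) {
    shift <- sex_sign[samples$species[dim_idx]] * config$sex_effect *
      ifelse(is_f[dim_idx], 0.5, -0.5)
    beta[dim_idx, informative] <- beta[dim_idx, informative] +
      outer(unname(shift), sign_j)
  }
  age_idx <- which(samples$species %in% age_species &
                   samples$tissue == age_tissue[samples$species])
  if (length(age_idx) && config$age_slope != 0) {
    shift <- config$age_slope * samples$age_yr[age_idx]
    beta[age_idx, informative] <- beta[age_idx, informative] +
      outer(shift, sign_j)
  }
  beta <- beta + stats::rnorm(length(beta), 0, config$noise_sd_sample)
  beta <- pmin(pmax(beta, 0), 1)
  rownames(beta) <- samples$sample_id

  # detection p-values and dropout
  fail <- matrix(stats::runif(n * config$n_cpgs) < config$dropout_rate,
                 nrow = n, dimnames = list(species, cpgs))
  detection <- matrix(stats::runif(n * config$n_cpgs, 0, 1e-4),
                      nrow = n, dimnames = list(species, cpgs))
  detection[fail] <- stats::runif(sum(fail), 0.1, 1)
  beta[fail[sp_idx, , drop = FALSE]] <- NA_real_

  truth <- list(informative = cpgs[informative],
                slope = stats::setNames(slope_j, cpgs[informative]),
                sign = stats::setNames(sign_j, cpgs[informative]),
                baseline = stats::setNames(baseline, cpgs),
                dimorphic = data.frame(species = dimorphic,
                                       sign = unname(sex_sign[dimorphic]),
                                       stringsAsFactors = FALSE),
                age_strata = data.frame(species = age_species,
                                        tissue = unname(age_tissue[age_species]),
                                        slope = rep(config$age_slope,
                                                    length(age_species)),
                                        stringsAsFactors = FALSE),
                traits = truth_traits)

  list(meth = meth_data(beta, samples), detection = detection, truth = truth)
}

# Species-level noise evolved by Brownian motion along the tree, one
# independent realisation per CpG; scaled so the marginal SD at the tips
# equals sd_tip (ultrametric trees). Returns a species x n_cpgs matrix.
bm_noise_matrix <- function(tree, n_cpgs, sd_tip) {
  n_tip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(n_tip)])
  sigma <- sd_tip / sqrt(height)
  ord <- ape::reorder.phylo(tree, "cladewise")
  val <- matrix(0, nrow = n_tip + tree$Nnode, ncol = n_cpgs)
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1L]
    ch <- ord$edge[k, 2L]
    val[ch, ] <- val[p, ] +
      stats::rnorm(n_cpgs, 0, sigma * sqrt(ord$edge.length[k]))
  }
  out <- val[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}
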