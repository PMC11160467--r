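#' Filter CpGs by median detection p-value across species
#'
#' Within each species the CpG median detection p-values are
#' Benjamini-Hochberg adjusted across CpGs; a CpG is retained when its
#' adjusted p-value falls below `fdr` in at least
#' `ceiling(species_fraction x n_species)` species. Missing detection values
#' count against the probe (treated as p = 1). This reproduces the
#' "detectable in most species" probe reduction that precedes model fitting.
#'
#' @param detection species x CpGs matrix of median detection p-values
#'   (rownames = species, colnames = CpG ids).
#' @param fdr FDR threshold for a probe to count as detected in a species.
#' @param species_fraction minimum fraction of species in which a probe must
#'   be detected.
#' @return Character vector of retained CpG ids, in input column order.
#' @export
filter_probes <- function(detection, fdr = 0.05, species_fraction = 0.85) {
  if (!is.matrix(detection) || nrow(detection) == 0L || ncol(detection) == 0L)
    stop("detection must be a non-empty species x CpG matrix", call. = FALSE)
  if (nrow(detection) < 2L)
    stop("detection must cover at least 2 species", call. = FALSE)
  stopifnot(fdr > 0, fdr < 1, species_fraction > 0, species_fraction < 1)
  p <- detection
  p[is.na(p)] <- 1
  q <- t(apply(p, 1L, stats::p.adjust, method = "BH"))
  n_sig <- colSums(q < fdr)
  need <- ceiling(species_fraction * nrow(detection))
  colnames(detection)[n_sig >= need]
}

#' Aggregate sample-level methylation into per-stratum means
#'
#' Averages beta values within strata defined either by species
#' (tissue-agnostic: one observation per species) or by (species, tissue)
#' (tissue-aware). Missing values are ignored in the mean; any stratum cell
#' with no observed value after aggregation is imputed with the column mean
#' over strata, so the resulting design matrix is complete.
#'
#' @param md a [meth_data()] object.
#' @param mode `"species"` or `"species_tissue"`.
#' @return A list of class `agg_beta`: `beta` (strata x CpGs matrix, rownames
#'   = stratum keys), `strata` (`data.frame` with `stratum`, `species`,
#'   `tissue` and `n_samples`), `mode`.
#' @export
aggregate_methylation <- function(md, mode = c("species", "species_tissue")) {
  mode <- match.arg(mode)
  stopifnot(inherits(md, "meth_data"))
  if (nrow(md$beta) == 0L) stop("empty methylation matrix", call. = FALSE)
  key <- if (mode == "species") md$samples$species
         else paste(md$samples$species, md$samples$tissue, sep = "|")
  groups <- split(seq_len(nrow(md$beta)), key)
  agg <- t(vapply(groups, function(idx)
    colMeans(md$beta[idx, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(md$beta))))
  agg[is.nan(agg)] <- NA_real_
  # column-mean imputation of strata with no observed value
  if (anyNA(agg)) {
    cm <- colMeans(agg, na.rm = TRUE)
    if (anyNA(cm) || any(is.nan(cm)))
      stop("some CpGs have no observed value in any stratum", call. = FALSE)
    na_idx <- which(is.na(agg), arr.ind = TRUE)
    agg[na_idx] <- cm[na_idx[, 2L]]
  }
  first <- vapply(groups, `[`, integer(1L), 1L)
  strata <- data.frame(stratum = names(groups),
                       species = md$samples$species[first],
                       tissue = if (mode == "species") NA_character_
                                else md$samples$tissue[first],
                       n_samples = lengths(groups),
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(beta = agg, strata = strata, mode = mode),
            class = "agg_beta")
}

#' @export
print.agg_beta <- function(x, ...) {
  cat(sprintf("agg_beta (%s): %d strata x %d CpGs\n", x$mode,
              nrow(x$beta), ncol(x$beta)))
  invisible(x)
}

#' Restrict to samples from young animals
#'
#' Keeps samples whose age is known and satisfies both `age < age at sexual
#' maturity` of their species and `age < 5` years — the restriction used to
#' build a life-span predictor from young animals only. Species left with no
#' qualifying sample drop out of the result.
#'
#' @param md a [meth_data()] object.
#' @param traits trait table providing `species` and `maturity_yr`.
#' @return A [meth_data()] subset (possibly with zero rows).
#' @export
select_young <- function(md, traits) {
  stopifnot(inherits(md, "meth_data"))
  if (!all(md$samples$species %in% traits$species))
    stop("traits must cover every species in the methylation data",
         call. = FALSE)
  maturity <- traits$maturity_yr[match(md$samples$species, traits$species)]
  age <- md$samples$age_yr
  keep <- !is.na(age) & !is.na(maturity) & age < maturity & age < 5
  subset_meth(md, which(keep))
}
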