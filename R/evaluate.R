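#' Accuracy summary of log-scale predictions
#'
#' The three headline numbers reported for every predictor evaluation:
#' Pearson correlation R (product-moment), its two-sided unadjusted p-value
#' (t transform of R), and the median absolute error.
#'
#' @param observed,predicted log-scale vectors of equal length >= 3.
#' @return `list(r, p, mae, n)`.
#' @export
accuracy_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3L)
    stop("need equal-length vectors of at least 3 values", call. = FALSE)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- stats::cor.test(observed, predicted, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       mae = stats::median(abs(observed - predicted)),
       n = length(observed))
}

#' Species verdict from per-tissue sex differences
#'
#' Implements the tissue-consistency rule: a species is called `"+"` when at
#' least one tissue shows a significant female-minus-male difference
#' (p <= `alpha`) and every significant tissue has a positive difference;
#' `"-"` symmetrically; `"."` otherwise (no significant tissue, or
#' significant tissues in opposite directions). Only significant tissues
#' vote on the direction.
#'
#' @param pvals per-tissue two-sided p-values.
#' @param diffs per-tissue female-minus-male mean differences.
#' @param alpha significance threshold (default 0.01).
#' @return One of `"+"`, `"-"`, `"."`.
#' @export
sex_verdict <- function(pvals, diffs, alpha = 0.01) {
  stopifnot(length(pvals) == length(diffs))
  sig <- which(!is.na(pvals) & pvals <= alpha)
  if (length(sig) == 0L) return(".")
  s <- sign(diffs[sig])
  if (all(s > 0)) "+" else if (all(s < 0)) "-" else "."
}

#' Sex differences in predicted traits, by species
#'
#' For each (species, tissue) stratum with at least `min_n` samples of each
#' sex, tests the female-male difference in predicted log trait with a
#' two-sided Wilcoxon rank-sum test (exact for small untied samples, normal
#' approximation with tie correction otherwise), then combines tissues into
#' a per-species verdict with [sex_verdict()].
#'
#' @param preds `data.frame` of per-sample predictions with columns
#'   `species`, `tissue`, `sex` and `predicted` (e.g. from
#'   [predict_samples()]).
#' @param min_n minimum samples per sex for a tissue to be tested.
#' @param alpha per-tissue significance threshold.
#' @param p_adjust optional multiplicity correction applied to the tissue
#'   p-values before the verdict (`"none"`, default, matches the unadjusted
#'   reporting convention; any other value is passed to
#'   [stats::p.adjust()]).
#' @return A list of class `sexdiff`: `species` (`data.frame` with
#'   `species`, `verdict`, `n_tissues_tested`) and `tissues` (per-tissue
#'   `n_female`, `n_male`, `diff` = female - male, `p`).
#' @export
sex_difference <- function(preds, min_n = 2L, alpha = 0.01,
                           p_adjust = "none") {
  req <- c("species", "tissue", "sex", "predicted")
  stopifnot(all(req %in% names(preds)))
  tiss <- list()
  for (sp in unique(preds$species)) {
    sub <- preds[preds$species == sp, ]
    for (ti in unique(sub$tissue)) {
      f <- sub$predicted[sub$tissue == ti & sub$sex == "female"]
      m <- sub$predicted[sub$tissue == ti & sub$sex == "male"]
      if (length(f) < min_n || length(m) < min_n) next
      w <- suppressWarnings(stats::wilcox.test(f, m,
                                               alternative = "two.sided"))
      tiss[[length(tiss) + 1L]] <-
        data.frame(species = sp, tissue = ti, n_female = length(f),
                   n_male = length(m), diff = mean(f) - mean(m),
                   p = w$p.value, stringsAsFactors = FALSE)
    }
  }
  tissues <- if (length(tiss)) do.call(rbind, tiss)
             else data.frame(species = character(0), tissue = character(0),
                             n_female = integer(0), n_male = integer(0),
                             diff = numeric(0), p = numeric(0))
  if (p_adjust != "none" && nrow(tissues) > 0L)
    tissues$p <- stats::p.adjust(tissues$p, method = p_adjust)
  verdicts <- vapply(unique(preds$species), function(sp) {
    tt <- tissues[tissues$species == sp, ]
    sex_verdict(tt$p, tt$diff, alpha = alpha)
  }, character(1L))
  species <- data.frame(species = unique(preds$species),
                        verdict = unname(verdicts),
                        n_tissues_tested =
                          as.integer(table(factor(tissues$species,
                                           levels = unique(preds$species)))),
                        stringsAsFactors = FALSE)
  structure(list(species = species, tissues = tissues, alpha = alpha),
            class = "sexdiff")
}

#' @export
print.sexdiff <- function(x, ...) {
  tab <- table(factor(x$species$verdict, levels = c("+", "-", ".")))
  cat(sprintf("Sex-difference verdicts (alpha = %.2g): +%d / -%d / .%d over %d species\n",
              x$alpha, tab[["+"]], tab[["-"]], tab[["."]],
              nrow(x$species)))
  invisible(x)
}

#' Correlation of per-sample predictions with chronological age
#'
#' Within each (species, tissue) stratum with at least `min_n` samples of
#' known age, the Pearson correlation between predicted log trait and age,
#' with its two-sided unadjusted p-value. Strata with constant age are
#' skipped.
#'
#' @param preds per-sample predictions with `species`, `tissue`, `age_yr`
#'   and `predicted`.
#' @param min_n minimum samples with known age per stratum (default 4).
#' @return `data.frame` with one row per tested stratum: `species`,
#'   `tissue`, `n`, `r`, `p`.
#' @export
age_association <- function(preds, min_n = 4L) {
  req <- c("species", "tissue", "age_yr", "predicted")
  stopifnot(all(req %in% names(preds)))
  key <- paste(preds$species, preds$tissue, sep = "|")
  out <- lapply(split(seq_len(nrow(preds)), key), function(idx) {
    sub <- preds[idx, ]
    sub <- sub[!is.na(sub$age_yr), ]
    if (nrow(sub) < min_n) return(NULL)
    if (stats::sd(sub$age_yr) == 0 || stats::sd(sub$predicted) == 0)
      return(NULL)  # undefined correlation: stratum skipped
    ct <- stats::cor.test(sub$predicted, sub$age_yr, method = "pearson")
    data.frame(species = sub$species[1L], tissue = sub$tissue[1L],
               n = nrow(sub), r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(species = character(0), tissue = character(0),
                      n = integer(0), r = numeric(0), p = numeric(0))
  rownames(res) <- NULL
  res
}

#' Weight-adjusted accuracy of life-span predictions
#'
#' Fits ordinary least squares of observed log maximum life span on the
#' epigenetic prediction and log adult weight, reporting the Wald p-value of
#' each covariate, and computes the weight-adjusted correlation as the
#' partial correlation of observed and predicted given weight (the
#' correlation of the two residual vectors after regressing each on
#' weight).
#'
#' @param observed,predicted log maximum life span (observed and predicted).
#' @param log_weight log adult weight, same length.
#' @return List with `coefficients` (estimate/SE/p per covariate),
#'   `adjusted_r` (partial correlation), `adjusted_p` (its two-sided
#'   p-value) and `collinear` (`TRUE` when |cor(predicted, weight)| >
#'   0.999).
#' @export
weight_adjusted_analysis <- function(observed, predicted, log_weight) {
  cc <- stats::complete.cases(observed, predicted, log_weight)
  observed <- observed[cc]; predicted <- predicted[cc]
  log_weight <- log_weight[cc]
  if (length(observed) < 10L)
    stop("need at least 10 complete cases", call. = FALSE)
  collinear <- abs(stats::cor(predicted, log_weight)) > 0.999
  if (collinear)
    warning("predicted and weight nearly collinear; Wald tests unreliable")
  fit <- stats::lm(observed ~ predicted + log_weight)
  sm <- summary(fit)$coefficients
  r1 <- stats::resid(stats::lm(observed ~ log_weight))
  r2 <- stats::resid(stats::lm(predicted ~ log_weight))
  ct <- stats::cor.test(r1, r2)
  list(coefficients = data.frame(term = rownames(sm),
                                 estimate = sm[, 1L], se = sm[, 2L],
                                 p = sm[, 4L], row.names = NULL,
                                 stringsAsFactors = FALSE),
       adjusted_r = unname(ct$estimate), adjusted_p = ct$p.value,
       n = length(observed), collinear = collinear)
}

#' Two-group contrasts of predictions within strata
#'
#' For each stratum (e.g. tissue within an intervention experiment), a
#' two-group ordinary-least-squares Wald statistic
#' `Z = (mean_treatment - mean_control) / SE`, referred to the standard
#' normal under the null, with a two-sided p-value. Strata with fewer than
#' `min_n` samples in either group are skipped.
#'
#' @param predicted per-sample predicted log trait.
#' @param group two-level factor or character (treatment/control).
#' @param stratum stratum label per sample (default: one stratum).
#' @param control level of `group` to treat as the reference.
#' @param expected_sign optional +1/-1 expected direction; concordance is
#'   reported per stratum.
#' @param min_n minimum samples per group within a stratum.
#' @return `data.frame` per tested stratum: `stratum`, `n_treat`, `n_ctrl`,
#'   `z`, `p`, `significant` (p < 0.05) and, when `expected_sign` is given,
#'   `concordant`.
#' @export
group_comparison <- function(predicted, group, stratum = NULL,
                             control = NULL, expected_sign = NULL,
                             min_n = 2L) {
  if (is.null(stratum)) stratum <- rep("all", length(predicted))
  group <- as.character(group)
  levs <- unique(group)
  if (length(levs) != 2L)
    stop("group must have exactly two levels", call. = FALSE)
  if (is.null(control)) control <- levs[1L]
  treat <- setdiff(levs, control)
  out <- lapply(split(seq_along(predicted), stratum), function(idx) {
    g <- group[idx]; p <- predicted[idx]
    nt <- sum(g == treat); nc <- sum(g == control)
    if (nt < min_n || nc < min_n) return(NULL)  # skipped stratum
    fit <- stats::lm(p ~ factor(g, levels = c(control, treat)))
    est <- summary(fit)$coefficients
    z <- est[2L, 1L] / est[2L, 2L]
    pv <- 2 * stats::pnorm(-abs(z))
    row <- data.frame(stratum = stratum[idx][1L], n_treat = nt, n_ctrl = nc,
                      z = z, p = pv, significant = pv < 0.05,
                      stringsAsFactors = FALSE)
    if (!is.null(expected_sign))
      row$concordant <- sign(z) == sign(expected_sign)
    row
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(stratum = character(0), n_treat = integer(0),
                      n_ctrl = integer(0), z = numeric(0), p = numeric(0),
                      significant = logical(0))
  rownames(res) <- NULL
  res
}

#' Age acceleration: age-adjusted prediction residuals
#'
#' The raw residual from regressing the predicted (log) trait on
#' chronological age. By construction the residuals have zero mean and zero
#' correlation with age.
#'
#' @param predicted per-sample predictions.
#' @param age chronological ages (years), non-constant, length >= 3.
#' @return Numeric residual vector.
#' @export
ageaccel <- function(predicted, age) {
  if (length(predicted) != length(age) || length(age) < 3L)
    stop("need aligned vectors of length >= 3", call. = FALSE)
  if (stats::sd(age) == 0)
    stop("age must not be constant", call. = FALSE)
  unname(stats::resid(stats::lm(predicted ~ age)))
}

#' Breed-level aggregation of life-span predictions
#'
#' Averages per-sample predicted log maximum life span within breeds, derives
#' each breed's maximum life span from its median (`max = 1.33 x median`)
#' and correlates the breed means with log derived maximum life span and
#' with log average adult weight (all base-e logs).
#'
#' @param preds per-sample predictions with columns `breed` and `predicted`
#'   (log scale).
#' @param breed_info `data.frame` with `breed`, `median_lifespan_yr` and
#'   `weight_g` (average adult weight).
#' @param factor multiplier from median to maximum life span (default 1.33).
#' @return List with `table` (per-breed `n`, `mean_predicted`,
#'   `median_lifespan_yr`, `derived_max_yr`, `weight_g`), `cor_lifespan`,
#'   `p_lifespan`, `cor_weight`, `p_weight`.
#' @export
breed_analysis <- function(preds, breed_info, factor = 1.33) {
  stopifnot(all(c("breed", "predicted") %in% names(preds)),
            all(c("breed", "median_lifespan_yr", "weight_g") %in%
                  names(breed_info)))
  mean_pred <- tapply(preds$predicted, preds$breed, mean)
  tab <- data.frame(breed = names(mean_pred),
                    n = as.integer(table(preds$breed)[names(mean_pred)]),
                    mean_predicted = unname(mean_pred),
                    stringsAsFactors = FALSE)
  tab <- merge(tab, breed_info, by = "breed")
  tab$derived_max_yr <- factor * tab$median_lifespan_yr
  if (nrow(tab) < 3L) stop("need at least 3 breeds", call. = FALSE)
  ct_l <- stats::cor.test(tab$mean_predicted, log(tab$derived_max_yr))
  ct_w <- stats::cor.test(tab$mean_predicted, log(tab$weight_g))
  list(table = tab,
       cor_lifespan = unname(ct_l$estimate), p_lifespan = ct_l$p.value,
       cor_weight = unname(ct_w$estimate), p_weight = ct_w$p.value)
}
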