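#' Sample-level methylation data with metadata
#'
#' Light container pairing a samples-by-CpGs matrix of beta values (fractions
#' in `[0, 1]`, `NA` allowed for failed probes) with its sample sheet.
#'
#' @param beta numeric matrix, rows = samples, columns = CpGs; `rownames`
#'   are sample ids and `colnames` CpG ids.
#' @param samples `data.frame` with columns `sample_id`, `species`, `tissue`,
#'   `sex` (one of `"female"`, `"male"`, `"unknown"`) and `age_yr` (years,
#'   `NA` allowed), aligned with the rows of `beta`.
#' @return An object of class `meth_data`.
#' @export
meth_data <- function(beta, samples) {
  if (!is.matrix(beta)) beta <- as.matrix(beta)
  req <- c("sample_id", "species", "tissue", "sex", "age_yr")
  if (!all(req %in% names(samples)))
    stop("samples must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(beta) != nrow(samples))
    stop("beta and samples disagree on the number of samples", call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("sample ids must be unique", call. = FALSE)
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0, 1]", call. = FALSE)
  if (!all(samples$sex %in% c("female", "male", "unknown")))
    stop("sex must be female, male or unknown", call. = FALSE)
  rownames(beta) <- samples$sample_id
  structure(list(beta = beta, samples = as.data.frame(samples)),
            class = "meth_data")
}

#' @export
print.meth_data <- function(x, ...) {
  cat(sprintf("meth_data: %d samples x %d CpGs; %d species, %d tissues\n",
              nrow(x$beta), ncol(x$beta),
              length(unique(x$samples$species)),
              length(unique(x$samples$tissue))))
  if (anyNA(x$beta))
    cat(sprintf("  %.2f%% missing beta values\n", 100 * mean(is.na(x$beta))))
  invisible(x)
}

#' @export
dim.meth_data <- function(x) dim(x$beta)

# Row subset preserving the pairing.
subset_meth <- function(x, idx) {
  meth_data(x$beta[idx, , drop = FALSE], x$samples[idx, , drop = FALSE])
}
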