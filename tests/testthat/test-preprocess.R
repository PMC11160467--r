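det_matrix <- function(p, n_sp, n_cg) {
  matrix(p, nrow = n_sp, ncol = n_cg,
         dimnames = list(sprintf("sp%02d", seq_len(n_sp)),
                         sprintf("cg%02d", seq_len(n_cg))))
}

test_that("uniformly significant or non-significant detection gives all or nothing", {
  expect_identical(filter_probes(det_matrix(0, 5, 8)),
                   sprintf("cg%02d", 1:8))
  expect_identical(filter_probes(det_matrix(1, 5, 8)), character(0))
})

test_that("probe filter matches brute-force enumeration on randomized fixtures", {
  for (seed in 1:10) {
    set.seed(seed)
    det <- det_matrix(0, 10, 20)
    det[] <- ifelse(runif(200) < 0.3, runif(200, 0.05, 1), runif(200, 0, 1e-4))
    expect_identical(filter_probes(det), oracle_filter(det))
  }
})

test_that("probe filter is permutation-invariant and monotone in species_fraction", {
  set.seed(4)
  det <- det_matrix(0, 10, 20)
  det[] <- ifelse(runif(200) < 0.3, runif(200, 0.05, 1), runif(200, 0, 1e-4))
  keep <- filter_probes(det)
  perm <- sample(ncol(det))
  keep_perm <- filter_probes(det[, perm])
  expect_setequal(keep, keep_perm)
  # output order follows input column order
  expect_identical(keep_perm, intersect(colnames(det)[perm], keep))
  lax <- filter_probes(det, species_fraction = 0.5)
  strict <- filter_probes(det, species_fraction = 0.95)
  expect_true(all(strict %in% lax))
  expect_true(all(keep %in% lax))
})

test_that("missing detection values count against the probe", {
  det <- det_matrix(1e-6, 10, 4)
  det[1:3, 2] <- NA  # 7/10 species < ceiling(0.85*10) = 9
  expect_identical(filter_probes(det), sprintf("cg%02d", c(1, 3, 4)))
})

test_that("aggregation means are exact and tissue-aware strata enumerate correctly", {
  md <- tiny_meth()
  sp <- aggregate_methylation(md, "species")
  expect_equal(sp$beta["A", "cg1"], 0.3)  # mean(0.2, 0.4)
  expect_equal(sp$beta["B", "cg2"], 0.6)  # mean(0.5, 0.7)
  expect_identical(sp$strata$n_samples, c(2L, 2L))
  st <- aggregate_methylation(md, "species_tissue")
  # group-by oracle
  expected <- unique(paste(md$samples$species, md$samples$tissue, sep = "|"))
  expect_setequal(rownames(st$beta), expected)
  expect_equal(st$beta["A|blood", "cg1"], 0.2)  # single sample: identity
})

test_that("stratum means stay within the contributing samples' range", {
  st <- small_study()
  agg <- aggregate_methylation(st$ds$meth, "species_tissue")
  key <- paste(st$ds$meth$samples$species, st$ds$meth$samples$tissue, sep = "|")
  for (k in sample(rownames(agg$beta), 5)) {
    rows <- which(key == k)
    sub <- st$ds$meth$beta[rows, , drop = FALSE]
    lo <- suppressWarnings(apply(sub, 2, min, na.rm = TRUE))
    hi <- suppressWarnings(apply(sub, 2, max, na.rm = TRUE))
    ok <- is.finite(lo)  # CpGs observed in at least one sample
    expect_true(all(agg$beta[k, ok] >= lo[ok] - 1e-12 &
                    agg$beta[k, ok] <= hi[ok] + 1e-12))
  }
})

test_that("aggregating an already aggregated matrix is idempotent", {
  st <- small_study()
  agg <- aggregate_methylation(st$ds$meth, "species")
  md2 <- meth_data(agg$beta,
                   data.frame(sample_id = agg$strata$stratum,
                              species = agg$strata$species,
                              tissue = "pooled", sex = "unknown",
                              age_yr = NA_real_))
  agg2 <- aggregate_methylation(md2, "species")
  expect_equal(agg2$beta[rownames(agg$beta), ], agg$beta)
})

test_that("young-animal selection applies both age conditions", {
  beta <- matrix(0.5, 4, 2, dimnames = list(NULL, c("cg1", "cg2")))
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        species = c("A", "B", "C", "A"),
                        tissue = "blood", sex = "unknown",
                        age_yr = c(4, 6, 2, NA))
  md <- meth_data(beta, samples)
  traits <- data.frame(species = c("A", "B", "C"),
                       maturity_yr = c(6, 10, 1.5))
  young <- select_young(md, traits)
  # age 4 < maturity 6 and < 5: kept; age 6 violates < 5; age 2 >= maturity
  # 1.5; unknown age dropped
  expect_identical(young$samples$sample_id, "s1")
  # idempotence
  expect_identical(select_young(young, traits)$samples$sample_id, "s1")
})

test_that("degenerate preprocessing inputs are rejected", {
  expect_error(filter_probes(det_matrix(0, 1, 3)), "2 species")
  expect_error(aggregate_methylation(tiny_meth(), "bogus"))
})
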