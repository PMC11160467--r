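#' Simulate a complete synthetic methylation study
#'
#' Convenience wrapper chaining [simulate_tree()], [simulate_traits()] and
#' [simulate_methylation()] into a single dataset whose members share one
#' species universe.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `sim_dataset`: a list with components `tree`
#'   (phylogeny with `orders`), `traits` (recorded trait table), `meth`
#'   ([meth_data()]), `detection` (species x CpGs median detection
#'   p-values) and `truth` (planted ground truth).
#' @examples
#' ds <- simulate_dataset(sim_config(n_species = 20, n_cpgs = 100,
#'                                   n_informative = 20, seed = 7))
#' ds
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  tree <- simulate_tree(config$n_species, seed = config$seed)
  traits <- simulate_traits(tree, config)
  sim <- simulate_methylation(traits, config, tree = tree)
  attr(traits, "truth") <- NULL
  attr(traits, "tree") <- NULL
  structure(list(tree = tree, traits = traits, meth = sim$meth,
                 detection = sim$detection, truth = sim$truth,
                 config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d species, %d samples x %d CpGs (%d informative)\n",
              length(x$tree$tip.label), nrow(x$meth$beta), ncol(x$meth$beta),
              length(x$truth$informative)))
  cat(sprintf("  orders: %d (%s)\n", length(unique(x$tree$orders)),
              paste(range(table(x$tree$orders)), collapse = "-")))
  cat(sprintf("  %d sex-dimorphic species, %d age-trend strata, %d breed-clade species\n",
              nrow(x$truth$dimorphic), nrow(x$truth$age_strata),
              sum(x$traits$breed_clade)))
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the Newick tree, the beta matrix, sample sheet, trait table and
#' detection-p table as CSV, and the planted truth as JSON.
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             beta = file.path(dir, "beta.csv"),
             samples = file.path(dir, "samples.csv"),
             traits = file.path(dir, "traits.csv"),
             detection = file.path(dir, "detection.csv"),
             truth = file.path(dir, "truth.json"))
  tr <- dataset$tree
  ape::write.tree(tr, paths[["tree"]])
  utils::write.csv(data.frame(species = names(tr$orders),
                              order = unname(tr$orders)),
                   file.path(dir, "orders.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$meth$beta), paths[["beta"]])
  utils::write.csv(dataset$meth$samples, paths[["samples"]], row.names = FALSE)
  utils::write.csv(dataset$traits, paths[["traits"]], row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$detection), paths[["detection"]])
  jsonlite::write_json(dataset$truth, paths[["truth"]], dataframe = "columns",
                       digits = NA)
  invisible(paths)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir directory containing the files written by [write_dataset()].
#' @return A list with components `tree`, `traits`, `meth`, `detection` and
#'   `truth` (truth as plain lists, as deserialised from JSON).
#' @export
read_dataset <- function(dir) {
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  ords <- utils::read.csv(file.path(dir, "orders.csv"),
                          stringsAsFactors = FALSE)
  tree$orders <- stats::setNames(ords$order, ords$species)
  beta <- as.matrix(utils::read.csv(file.path(dir, "beta.csv"),
                                    row.names = 1, check.names = FALSE))
  samples <- utils::read.csv(file.path(dir, "samples.csv"),
                             stringsAsFactors = FALSE)
  detection <- as.matrix(utils::read.csv(file.path(dir, "detection.csv"),
                                         row.names = 1, check.names = FALSE))
  traits <- utils::read.csv(file.path(dir, "traits.csv"),
                            stringsAsFactors = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(tree = tree, traits = traits, meth = meth_data(beta, samples),
       detection = detection, truth = truth)
}
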