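# Shared fixtures. Heavy end-to-end objects (the default synthetic study and
# its cross-validation runs) are computed once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# The default study conditions: 120 species, 3000 CpGs, 300 informative,
# seed 1, with the standard preprocessing applied.
default_study <- function() {
  cached("default_study", {
    ds <- simulate_dataset(sim_config(seed = 1))
    des <- prepare_design(ds, trait = "max_lifespan", mode = "species")
    list(ds = ds, des = des)
  })
}

default_loso <- function() {
  cached("default_loso", {
    st <- default_study()
    loso_cv(st$des$x, st$des$y, species = st$des$species,
            trait = "max_lifespan", seed = 2)
  })
}

default_loco <- function() {
  cached("default_loco", {
    st <- default_study()
    loco_cv(st$des$x, st$des$y, orders = st$des$orders,
            traits = st$des$traits, trait = "max_lifespan", seed = 3)
  })
}

default_fit <- function() {
  cached("default_fit", {
    st <- default_study()
    trait_predictor(st$des$x, st$des$y, trait = "max_lifespan", seed = 11)
  })
}

default_sample_preds <- function() {
  cached("default_sample_preds", {
    st <- default_study()
    predict_samples(default_fit(), st$ds$meth)
  })
}

# Breed-clade study: low within-clade methylation divergence, non-trivial
# within-clade trait SD.
breed_study <- function() {
  cached("breed_study", {
    ds <- simulate_dataset(sim_config(seed = 1,
      breed_clade = list(size = 12, trait_sd = 0.3, meth_sd = 0.002)))
    des <- prepare_design(ds, trait = "max_lifespan", mode = "species")
    list(ds = ds, des = des)
  })
}

# A small, fast study for structural tests.
small_study <- function() {
  cached("small_study", {
    ds <- simulate_dataset(sim_config(n_species = 30, n_cpgs = 300,
                                      n_informative = 60,
                                      missing_lifespan_rate = 0,
                                      seed = 42))
    des <- prepare_design(ds, trait = "max_lifespan", mode = "species")
    list(ds = ds, des = des)
  })
}

# Hand-built methylation fixture: 2 species x 2 tissues, known beta values.
tiny_meth <- function() {
  beta <- matrix(c(0.2, 0.4, 0.6, 0.8,
                   0.1, 0.3, 0.5, 0.7), nrow = 4,
                 dimnames = list(NULL, c("cg1", "cg2")))
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        species = c("A", "A", "B", "B"),
                        tissue = c("blood", "liver", "blood", "blood"),
                        sex = c("female", "male", "female", "male"),
                        age_yr = c(1, 2, 3, NA),
                        stringsAsFactors = FALSE)
  meth_data(beta, samples)
}
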