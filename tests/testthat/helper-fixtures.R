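# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# default synthetic bundle (the study conditions) and its feature stage
default_bundle <- function(sigma = 0.2, seed = 1) {
  memo(sprintf("bundle_%g_%d", sigma, seed),
       generate_dataset(list(sigma = sigma), seed = seed))
}

default_features <- function(sigma = 0.2, seed = 1, mode = "distance", constant = 0) {
  memo(sprintf("feat_%g_%d_%s_%g", sigma, seed, mode, constant), {
    b <- default_bundle(sigma, seed)
    pipeline_features(b$model, b$fluxes, b$abundance,
                      cv_threshold = 0.5, mode = mode, constant = constant)
  })
}

# labels of the default bundle restricted to pairs that survived filtering
default_labels <- function(sigma = 0.2, seed = 1, mode = "distance") {
  feat <- default_features(sigma, seed, mode)
  b <- default_bundle(sigma, seed)
  lab <- b$labels
  lab[paste(lab$metabolite, lab$protein, sep = ":") %in%
        rownames(feat$pair_features), , drop = FALSE]
}

# 3-reaction linear chain: uptake -> A -> B -> biomass
chain_model <- function(uptake_ub = 10) {
  metabolic_model(
    metabolites = data.frame(id = c("A_c", "B_c"), compartment = "c"),
    reactions = data.frame(
      id = c("UPT", "R1", "BIOMASS"),
      lower_bound = 0, upper_bound = c(uptake_ub, 1000, 1000),
      gpr = c("", "g1", ""),
      objective_weight = c(0, 0, 1)),
    stoich = list(UPT = c(A_c = 1), R1 = c(A_c = -1, B_c = 1),
                  BIOMASS = c(B_c = -1)))
}

# chain plus a futile cycle B <-> C that cannot contribute to biomass
cycle_model <- function() {
  metabolic_model(
    metabolites = data.frame(id = c("A_c", "B_c", "C_c"), compartment = "c"),
    reactions = data.frame(
      id = c("UPT", "R1", "CYC1", "CYC2", "BIOMASS"),
      lower_bound = 0, upper_bound = c(10, 1000, 1000, 1000, 1000),
      gpr = "", objective_weight = c(0, 0, 0, 0, 1)),
    stoich = list(UPT = c(A_c = 1), R1 = c(A_c = -1, B_c = 1),
                  CYC1 = c(B_c = -1, C_c = 1), CYC2 = c(C_c = -1, B_c = 1),
                  BIOMASS = c(B_c = -1)))
}

# two alternative pathways of different length from A to the precursor:
# short (1 step) and long (2 steps); 6 reactions total
two_path_model <- function() {
  metabolic_model(
    metabolites = data.frame(id = c("A_c", "B_c", "C_c", "P_c"), compartment = "c"),
    reactions = data.frame(
      id = c("UPT", "SHORT", "LONG1", "LONG2", "JOIN", "BIOMASS"),
      lower_bound = 0, upper_bound = c(10, 4, 1000, 1000, 1000, 1000),
      gpr = "", objective_weight = c(0, 0, 0, 0, 0, 1)),
    stoich = list(UPT = c(A_c = 1),
                  SHORT = c(A_c = -1, P_c = 1),
                  LONG1 = c(A_c = -1, B_c = 1), LONG2 = c(B_c = -1, C_c = 1),
                  JOIN = c(C_c = -1, P_c = 1),
                  BIOMASS = c(P_c = -1)))
}

# gaussian two-class feature matrix with pair-style rownames
separable_features <- function(n_per_class = 40, p = 6, gap = 4, seed = 42) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p), n_per_class),
             matrix(rnorm(n_per_class * p, mean = gap), n_per_class))
  colnames(X) <- paste0("f", seq_len(p))
  rownames(X) <- paste0("m", seq_len(2 * n_per_class), ":p", seq_len(2 * n_per_class))
  list(features = X,
       labels = setNames(rep(c(0L, 1L), each = n_per_class), rownames(X)))
}

random_fingerprints <- function(n, seed = 1, bits = 12) {
  set.seed(seed)
  fp <- t(vapply(seq_len(n), function(i) {
    b <- rep(FALSE, 64); b[sample(64, bits)] <- TRUE; b
  }, logical(64)))
  rownames(fp) <- paste0("m", seq_len(n))
  fp
}
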