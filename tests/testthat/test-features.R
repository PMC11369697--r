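# Flux sums, eta, CV filter and pair-feature construction.

test_that("flux_sum computes half the total absolute flux per metabolite", {
  m <- metabolic_model(
    metabolites = data.frame(id = c("A_c", "B_c"), compartment = "c"),
    reactions = data.frame(
      id = c("R1", "R2", "R3"), lower_bound = 0, upper_bound = 100,
      gpr = "", objective_weight = c(0, 0, 1)),
    stoich = list(R1 = c(A_c = 2, B_c = 1), R2 = c(A_c = -1),
                  R3 = c(A_c = -1, B_c = -1)))
  v <- matrix(c(3, 4, 2), 3, 1, dimnames = list(c("R1", "R2", "R3"), "c1"))
  fs <- flux_sum(m, v, "c")
  expect_equal(fs$raw["A_c", "c1"], 0.5 * (2 * 3 + 4 + 2))  # = 6, hand sum
  expect_equal(fs$raw["B_c", "c1"], 0.5 * (3 + 2))
  expect_error(flux_sum(m, v, "mitochondrion"), "valid: c")
})

test_that("produced equals consumed equals the flux sum at steady state", {
  b <- default_bundle()
  S <- stoich_matrix(b$model)
  v <- b$fluxes$values
  for (k in sample(rownames(b$fluxsums$raw), 10)) {
    sv <- S[k, rownames(v)]
    flux <- sweep(v, 1, sv, `*`)
    production <- colSums(pmax(flux, 0))
    consumption <- colSums(pmax(-flux, 0))
    expect_equal(production, consumption, tolerance = 1e-6)
    expect_equal(b$fluxsums$raw[k, ], production, tolerance = 1e-6)
  }
})

test_that("metabolite untouched by active reactions has zero flux sum and is dropped", {
  m <- chain_model()
  m$metabolites <- rbind(m$metabolites, data.frame(id = "ORPHAN_c", compartment = "c"))
  m$stoich$R1 <- c(A_c = -1, B_c = 1, ORPHAN_c = 0)
  m <- metabolic_model(m$metabolites, m$reactions, m$stoich)
  v <- matrix(5, 3, 2, dimnames = list(c("UPT", "R1", "BIOMASS"), c("c1", "c2")))
  fs <- flux_sum(m, v, "c")
  expect_equal(unname(fs$raw["ORPHAN_c", ]), c(0, 0))
  expect_true("ORPHAN_c" %in% fs$dropped)
  expect_false("ORPHAN_c" %in% rownames(fs$normalized))
})

test_that("max_normalize scales to [0, 1] with max 1 and rejects zero profiles", {
  expect_equal(max_normalize(c(2, 4, 1)), c(0.5, 1, 0.25))
  expect_equal(max_normalize(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(max_normalize(max_normalize(c(2, 4, 1))),
               max_normalize(c(2, 4, 1)))  # idempotent
  expect_error(max_normalize(c(0, 0, 0)), "drop")
})

test_that("compute_eta reproduces kapp, kcat and eta element-wise", {
  # hand-checkable case: kapp profile (2, 4, 1)
  v <- matrix(c(2, 4, 1), 1, 3, dimnames = list("R", paste0("c", 1:3)))
  E <- matrix(1, 1, 3, dimnames = dimnames(v))
  et <- compute_eta(v, E)
  expect_equal(et$kcat[["R"]], 4)
  expect_equal(unname(et$eta["R", ]), c(0.5, 1, 0.25))

  # random matrices against a direct double-loop oracle
  set.seed(3)
  v <- matrix(abs(rnorm(30)), 5, 6,
              dimnames = list(paste0("R", 1:5), paste0("c", 1:6)))
  v[2, 3] <- 0                      # zero flux -> kapp 0, eta 0
  E <- matrix(runif(30, 0.5, 2), 5, 6, dimnames = dimnames(v))
  et <- compute_eta(v, E)
  for (i in rownames(et$eta)) {
    kapp_i <- abs(v[i, ]) / E[i, ]
    for (j in colnames(et$eta))
      expect_equal(et$eta[i, j], kapp_i[[j]] / max(kapp_i),
                   info = paste(i, j))
  }
  expect_equal(et$eta[2, 3][[1]], 0)
  expect_true(all(et$eta >= 0 & et$eta <= 1))
  # kcat is the row maximum, so each row's maximum eta is exactly 1
  expect_equal(unname(apply(et$eta, 1, max)), rep(1, 5))
  expect_equal(et$eta, et$eta_normalized)
})

test_that("compute_eta drops undefined entries but keeps partially measured reactions", {
  v <- matrix(1:8, 2, 4, dimnames = list(c("R1", "R2"), paste0("c", 1:4)))
  E <- matrix(1, 2, 4, dimnames = dimnames(v))
  E[2, 2] <- 0                      # undefined in one condition
  et <- compute_eta(v, E)
  # greedy completion drops the single offending condition, not the reaction
  expect_equal(et$dropped_conditions, "c2")
  expect_setequal(rownames(et$eta), c("R1", "R2"))
  expect_error(compute_eta(v, matrix(0, 2, 4, dimnames = dimnames(v))),
               "no reaction")
})

test_that("cv_filter uses the sample CV and is monotone in the threshold", {
  eta <- list(eta_normalized = rbind(
    Rflat = c(1, 1, 1, 1),
    Rspiky = c(1, 0, 0, 0)))
  fs <- list(normalized = rbind(
    Mok = c(1, 0.1, 0.05, 0),
    Mflat = c(1, 0.9, 1, 0.95)))
  colnames(eta$eta_normalized) <- colnames(fs$normalized) <- paste0("c", 1:4)
  rep1 <- cv_filter(eta, fs, threshold = 1)
  # CV of (1,0,0,0): mean 0.25, sd 0.5 -> 2
  expect_equal(unname(rep1$cv_eta["Rspiky"]), 2)
  expect_equal(unname(rep1$cv_eta["Rflat"]), 0)
  expect_equal(rep1$retained,
               data.frame(metabolite = "Mok", reaction = "Rspiky"))
  expect_equal(nrow(rep1$removed), 3)
  expect_true(all(c("retained", "removed") %in% names(rep1)))

  rep0 <- cv_filter(eta, fs, threshold = 0)
  expect_equal(nrow(rep0$retained), 4)  # vacuous filter keeps everything

  # monotonicity: raising the threshold never adds a retained pair
  prev <- nrow(rep0$retained)
  for (thr in c(0.5, 1, 1.5, 3)) {
    cur <- nrow(cv_filter(eta, fs, threshold = thr)$retained)
    expect_lte(cur, prev)
    prev <- cur
  }
  expect_error(cv_filter(list(eta_normalized = eta$eta_normalized[, 1, drop = FALSE]),
                         list(normalized = fs$normalized[, 1, drop = FALSE])),
               "fewer than 2")
})

test_that("distance features match the double-loop oracle and unit-square bounds", {
  expect_equal(distance_features(c(0, 1), c(0, 1)), sqrt(2))
  expect_equal(distance_features(c(0.3, 0.3, 0.3), c(0.7, 0.7, 0.7)),
               c(0, 0, 0))
  # paper-scale feature lengths J(J-1)/2
  for (J in c(12, 19, 26, 31)) {
    eta <- runif(J); M <- runif(J)
    expect_length(distance_features(eta, M), J * (J - 1) / 2)
  }
  set.seed(5)
  eta <- runif(5); M <- runif(5)
  got <- distance_features(eta, M)
  oracle <- c()
  for (n in 1:4) for (m in (n + 1):5)
    oracle <- c(oracle, sqrt((eta[n] - eta[m])^2 + (M[n] - M[m])^2))
  expect_equal(got, oracle)
  expect_true(all(got >= 0 & got <= sqrt(2)))
  expect_error(distance_features(runif(3), runif(4)), "mismatch")
})

test_that("distance features are stable under condition reordering", {
  set.seed(8)
  J <- 7
  eta <- runif(J); M <- runif(J)
  perm <- sample(J)
  # reorder conditions, then re-sort the (n, m) entries back: same multiset
  expect_equal(sort(distance_features(eta[perm], M[perm])),
               sort(distance_features(eta, M)))
})

test_that("constant ablation replaces the flux-sum difference by c", {
  eta <- c(1, 0.5, 0.25)
  expect_equal(constant_ablation_features(eta, 0),
               c(0.5, 0.75, 0.25))        # |eta_n - eta_m|
  expect_equal(constant_ablation_features(c(0.4, 0.4, 0.4), 0.3),
               rep(0.3, 3))
  set.seed(6)
  e <- runif(6)
  got <- constant_ablation_features(e, 0.5)
  oracle <- c()
  for (n in 1:5) for (m in (n + 1):6)
    oracle <- c(oracle, sqrt((e[n] - e[m])^2 + 0.25))
  expect_equal(got, oracle)
})

test_that("concatenated features join the two profiles in condition order", {
  expect_equal(concatenated_features(c(1, 0.5, 0.25), c(0.2, 1, 0.4)),
               c(1, 0.5, 0.25, 0.2, 1, 0.4))
  expect_length(concatenated_features(runif(26), runif(26)), 52)
  expect_error(concatenated_features(runif(3), runif(2)), "mismatch")
})

test_that("build_pair_features rows match the single-pair operations", {
  feat <- default_features()
  X <- feat$features
  pairs <- attr(X, "pairs")
  conds <- attr(X, "conditions")
  expect_equal(ncol(X), length(conds) * (length(conds) - 1) / 2)
  expect_equal(nrow(X),
               length(unique(pairs$metabolite)) * length(unique(pairs$reaction)))
  en <- feat$eta$eta_normalized; mn <- feat$fluxsums$normalized
  for (i in sample(nrow(X), 8)) {
    expect_equal(unname(X[i, ]),
                 unname(distance_features(en[pairs$reaction[i], conds],
                                          mn[pairs$metabolite[i], conds])),
                 info = rownames(X)[i])
  }
  expect_true(all(X >= 0 & X <= sqrt(2) + 1e-12))

  # concatenated and constant modes agree with their single-pair operations
  Xc <- build_pair_features(feat$eta, feat$fluxsums, feat$report,
                            mode = "concatenated")
  expect_equal(ncol(Xc), 2 * length(conds))
  i <- 3
  expect_equal(unname(Xc[i, ]),
               unname(concatenated_features(en[pairs$reaction[i], conds],
                                            mn[pairs$metabolite[i], conds])))
  Xa <- build_pair_features(feat$eta, feat$fluxsums, feat$report,
                            mode = "constant", constant = 0.3)
  expect_equal(unname(Xa[i, ]),
               unname(constant_ablation_features(en[pairs$reaction[i], conds], 0.3)))
})
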