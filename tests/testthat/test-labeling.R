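# Gold-standard construction strategies.

test_that("positives_from_scores uses a strict threshold", {
  scores <- data.frame(metabolite = c("m1", "m2", "m3"),
                       protein = c("p1", "p2", "p3"),
                       score = c(501L, 500L, 499L))
  pos <- positives_from_scores(scores)
  expect_equal(pos, data.frame(metabolite = "m1", protein = "p1"))
  expect_equal(nrow(positives_from_scores(scores[0, ])), 0)
  expect_equal(nrow(positives_from_scores(scores, threshold = 0)), 3)
  expect_error(positives_from_scores(transform(scores, score = c(1, 2, 1001))),
               "\\[0, 1000\\]")
})

test_that("potential-negative voting keeps the t/subset/vote bookkeeping", {
  set.seed(2)
  # 4 positives, 12 assumed negatives -> t = 3, subsets of 4, votes in [0, 2]
  X <- rbind(matrix(rnorm(4 * 6, mean = 3), 4), matrix(rnorm(12 * 6), 12))
  pairs <- data.frame(metabolite = paste0("m", 1:16), protein = paste0("p", 1:16))
  rownames(X) <- paste(pairs$metabolite, pairs$protein, sep = ":")
  out <- potential_negative_labeling(X, pairs[1:4, ], pairs[5:16, ], seed = 1)
  expect_equal(out$t, 3)
  expect_equal(as.integer(table(out$subsets)), rep(4L, 3))
  expect_true(all(out$votes >= 0 & out$votes <= out$t - 1))
  expect_length(out$votes, 12)
  lab <- out$labels
  expect_equal(sum(lab$label == 1), 4)
  # selected negatives are assumed negatives voted t-1 by the held-out SVMs
  sel <- paste(lab$metabolite[lab$label == 0], lab$protein[lab$label == 0], sep = ":")
  expect_setequal(sel, names(out$votes)[out$votes == out$t - 1])
  # positives and negatives disjoint
  expect_equal(anyDuplicated(paste(lab$metabolite, lab$protein)), 0)
})

test_that("linearly separable assumed negatives are all selected", {
  set.seed(4)
  n_pos <- 10; n_neg <- 40
  X <- rbind(matrix(rnorm(n_pos * 4, mean = 5), n_pos),
             matrix(rnorm(n_neg * 4, mean = 0), n_neg))
  pairs <- data.frame(metabolite = paste0("m", seq_len(n_pos + n_neg)),
                      protein = "p")
  rownames(X) <- paste(pairs$metabolite, pairs$protein, sep = ":")
  out <- potential_negative_labeling(X, pairs[1:n_pos, ],
                                     pairs[-(1:n_pos), ], seed = 1)
  expect_equal(sum(out$labels$label == 0), n_neg)
  # cross-check with a single classifier trained on everything
  fit <- e1071::svm(x = X, y = factor(c(rep(1, n_pos), rep(0, n_neg))))
  expect_true(all(predict(fit, X[-(1:n_pos), ]) == "0"))
})

test_that("assumed negatives distributed like positives are rarely selected", {
  set.seed(9)
  n_pos <- 20; n_neg <- 80
  X_pos <- matrix(rnorm(n_pos * 4, mean = 3), n_pos)
  # planted subset: first 20 assumed negatives drawn from the positive class
  X_neg <- rbind(matrix(rnorm(20 * 4, mean = 3), 20),
                 matrix(rnorm(60 * 4, mean = 0), 60))
  X <- rbind(X_pos, X_neg)
  pairs <- data.frame(metabolite = paste0("m", seq_len(n_pos + n_neg)), protein = "p")
  rownames(X) <- paste(pairs$metabolite, pairs$protein, sep = ":")
  out <- potential_negative_labeling(X, pairs[1:n_pos, ], pairs[-(1:n_pos), ], seed = 1)
  planted <- names(out$votes)[1:20 + 0]  # votes are named in assumed-negative order
  planted_rate <- mean(out$votes[paste0("m", 21:40, ":p")] == out$t - 1)
  rest_rate <- mean(out$votes[paste0("m", 41:100, ":p")] == out$t - 1)
  expect_lt(planted_rate, rest_rate - 0.3)
})

test_that("t < 2 is rejected", {
  X <- matrix(rnorm(24), 6)
  pairs <- data.frame(metabolite = paste0("m", 1:6), protein = "p")
  rownames(X) <- paste(pairs$metabolite, pairs$protein, sep = ":")
  expect_error(potential_negative_labeling(X, pairs[1:3, ], pairs[4:6, ], seed = 1),
               "t >= 2")
})

test_that("random STITCH labelling requires both members in the positive set", {
  scores <- data.frame(metabolite = c("m1", "m2"), protein = c("p1", "p2"),
                       score = c(900L, 800L))
  universe <- data.frame(
    metabolite = c("m1", "m2", "m1", "m2", "m3", "m1"),
    protein = c("p1", "p2", "p2", "p1", "p1", "p3"))
  lab <- random_stitch_labeling(scores, universe)
  ids <- paste(lab$metabolite, lab$protein, sep = ":")
  expect_setequal(ids[lab$label == 1], c("m1:p1", "m2:p2"))
  expect_setequal(ids[lab$label == 0], c("m1:p2", "m2:p1"))  # both members positive
  expect_false("m3:p1" %in% ids)   # m3 absent from positives: unlabelled
  expect_false("m1:p3" %in% ids)
  # the rule, asserted directly on the negatives
  neg <- lab[lab$label == 0, ]
  expect_true(all(neg$metabolite %in% lab$metabolite[lab$label == 1]))
  expect_true(all(neg$protein %in% lab$protein[lab$label == 1]))
})

test_that("tanimoto matches a popcount oracle and its edge conventions", {
  a <- rep(FALSE, 64); a[1:2] <- TRUE
  b <- rep(FALSE, 64); b[c(1, 3)] <- TRUE
  expect_equal(tanimoto(a, b), 1 / 3)
  expect_equal(tanimoto(a, a), 1)
  d <- rep(FALSE, 64); d[10:12] <- TRUE
  expect_equal(tanimoto(a, d), 0)
  expect_warning(z <- tanimoto(rep(FALSE, 64), rep(FALSE, 64)), "all-zero")
  expect_equal(z, 0)
  expect_error(tanimoto(rep(TRUE, 32), a), "64 bits")

  # oracle: popcount through the packed-integer route
  popcount <- function(bits) {
    sum(vapply(packBits(c(bits, rep(FALSE, 0)), type = "integer"),
               function(w) sum(intToBits(w) == as.raw(1)), numeric(1)))
  }
  set.seed(10)
  for (i in 1:200) {
    x <- runif(64) < 0.3; y <- runif(64) < 0.3
    u <- popcount(x | y)
    expected <- if (u == 0) 0 else popcount(x & y) / u
    got <- if (u == 0) suppressWarnings(tanimoto(x, y)) else tanimoto(x, y)
    expect_equal(got, expected)
    expect_equal(got, if (u == 0) 0 else tanimoto(y, x))  # symmetry
  }
})

test_that("tanimoto labelling nominates zero-similarity metabolites as negatives", {
  fp <- matrix(FALSE, 3, 64, dimnames = list(c("m1", "m2", "m3"), NULL))
  fp["m1", 1:4] <- TRUE
  fp["m2", 33:36] <- TRUE   # disjoint from m1
  fp["m3", c(1, 40)] <- TRUE  # shares a bit with m1
  pos <- data.frame(metabolite = "m1", protein = "p1")
  lab <- tanimoto_labeling(pos, fp)
  ids <- paste(lab$metabolite, lab$protein, sep = ":")
  expect_setequal(ids[lab$label == 0], "m2:p1")
  # a positive pair is never relabelled negative
  pos2 <- data.frame(metabolite = c("m1", "m2"), protein = c("p1", "p1"))
  lab2 <- tanimoto_labeling(pos2, fp)
  expect_equal(lab2$label[lab2$metabolite == "m2" & lab2$protein == "p1"], 1L)
  expect_error(tanimoto_labeling(data.frame(metabolite = "m9", protein = "p"), fp),
               "m9")
  # no zero-similarity metabolites -> no negatives
  fp_all <- fp; fp_all[, 1] <- TRUE
  expect_equal(sum(tanimoto_labeling(pos, fp_all)$label == 0), 0)
})

test_that("random labelling is balanced, seeded, and uniform over many seeds", {
  pairs <- data.frame(metabolite = paste0("m", 1:10), protein = paste0("p", 1:10))
  lab <- random_labeling(pairs, seed = 7)
  expect_equal(sum(lab$label == 1), 5)
  expect_identical(random_labeling(pairs, seed = 7), lab)
  expect_false(identical(random_labeling(pairs, seed = 8)$label, lab$label))
  # each pair is positive about half the time across seeds
  freq <- rowMeans(vapply(1:400, function(s) random_labeling(pairs, s)$label,
                          integer(10)))
  expect_true(all(freq > 0.5 - 3 * sqrt(0.25 / 400) - 1e-9))
  expect_true(all(freq < 0.5 + 3 * sqrt(0.25 / 400) + 1e-9))
  expect_error(random_labeling(pairs[1, , drop = FALSE]), "at least 2")
})

test_that("direct labels load, deduplicate, and reject conflicts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("metabolite\tprotein\tlabel",
               "m1\tp1\t1", "m2\tp1\t0", "m3\tp2\t0", "m2\tp1\t0"), path)
  lab <- load_direct_labels(path)
  expect_equal(nrow(lab), 3)
  expect_equal(sum(lab$label), 1)
  expect_equal(lab$strategy[1], "direct")

  conflict <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("metabolite\tprotein\tlabel",
               "m1\tp1\t1", "m1\tp1\t0"), conflict)
  expect_error(load_direct_labels(conflict), "conflicting")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("metabolite\tprotein\tlabel", "m1\tp1\t2"), bad)
  expect_error(load_direct_labels(bad), "label")
})

test_that("fingerprint TSV round trip preserves all 64 bits", {
  fp <- random_fingerprints(5, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprints(fp, path)
  fp2 <- read_fingerprints(path)
  expect_equal(unname(fp2), unname(fp))
  expect_equal(rownames(fp2), rownames(fp))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("metabolite\tfingerprint", "m1\tzz00"), bad)
  expect_error(read_fingerprints(bad), "malformed")
})

test_that("every strategy keeps positives and negatives disjoint", {
  b <- default_bundle()
  feat <- default_features()
  universe <- unique(feat$triples[, c("metabolite", "protein")])
  strategies <- list(
    direct = b$labels,
    random = random_labeling(universe, seed = 3),
    stitch = random_stitch_labeling(b$scores, universe),
    tanimoto = tanimoto_labeling(
      positives_from_scores(b$scores)[
        positives_from_scores(b$scores)$metabolite %in% rownames(b$fingerprints), ],
      b$fingerprints))
  for (nm in names(strategies)) {
    lab <- strategies[[nm]]
    expect_equal(anyDuplicated(paste(lab$metabolite, lab$protein)), 0, info = nm)
    expect_true(all(lab$label %in% 0:1), info = nm)
  }
})
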