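# Gold-standard construction: positive sets from interaction scores and four
# negative-labelling strategies (PU-style potential negatives, score-based
# random labelling, fingerprint Tanimoto, and the random control).

pair_ids <- function(x) paste(x$metabolite, x$protein, sep = ":")

label_set <- function(metabolite, protein, label, strategy) {
  df <- data.frame(metabolite = as.character(metabolite),
                   protein = as.character(protein),
                   label = as.integer(label),
                   strategy = strategy, stringsAsFactors = FALSE)
  if (anyDuplicated(pair_ids(df))) stop("a pair carries more than one label")
  if (!all(df$label %in% 0:1)) stop("labels must be 0/1")
  class(df) <- c("label_set", "data.frame")
  df
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("label_set (%s): %d positives, %d negatives\n",
              x$strategy[1] %||% "?", sum(x$label == 1), sum(x$label == 0)))
  invisible(x)
}

#' Positive pairs from an interaction-score table
#'
#' Pairs whose confidence score is strictly greater than the threshold (the
#' STITCH convention: scores are integers in 0..1000, > 500 treated as
#' interacting).  All other pairs of the universe are "assumed negatives".
#'
#' @param scores data.frame with columns `metabolite`, `protein`, `score`.
#' @param threshold strict score cutoff (default 500).
#' @return data.frame of positive pairs (`metabolite`, `protein`).
#' @export
positives_from_scores <- function(scores, threshold = 500) {
  stopifnot(all(c("metabolite", "protein", "score") %in% names(scores)))
  if (nrow(scores) && (any(scores$score < 0) || any(scores$score > 1000)))
    stop("scores must lie in [0, 1000]")
  if (anyDuplicated(pair_ids(scores))) stop("duplicate (metabolite, protein) score keys")
  pos <- scores[scores$score > threshold, c("metabolite", "protein")]
  rownames(pos) <- NULL
  pos
}

#' Potential-negative labelling by held-out SVM voting
#'
#' PU-learning-style scheme.  The assumed negatives are partitioned into
#' `t = floor(n_negative / n_positive)` random subsets of near-equal size
#' (differing by at most 1).  For each subset, one RBF-kernel SVM is trained
#' on all positives (label 1) plus that subset (label 0); every assumed
#' negative is then scored by the `t - 1` classifiers that did not train on
#' it, by counting how many predict it negative.  Pairs voted negative by
#' all `t - 1` held-out classifiers become the selected negative set.
#'
#' @param features numeric matrix of pair features; rownames are
#'   `"metabolite:protein"` keys covering all pairs below.
#' @param positives data.frame (`metabolite`, `protein`) of positive pairs.
#' @param assumed_negatives data.frame of assumed-negative pairs.
#' @param seed integer seed for the partition.
#' @param svm_args list of extra arguments passed to [e1071::svm()]
#'   (kernel/cost defaults follow that function).
#' @return list with `labels` (a `label_set` of positives plus selected
#'   negatives), `t`, `votes` (named integer vector over assumed negatives),
#'   `subsets` (partition assignment).
#' @export
potential_negative_labeling <- function(features, positives, assumed_negatives,
                                        seed = 1, svm_args = list()) {
  pos_ids <- pair_ids(positives)
  neg_ids <- pair_ids(assumed_negatives)
  if (length(intersect(pos_ids, neg_ids)))
    stop("positives and assumed negatives overlap")
  missing <- setdiff(c(pos_ids, neg_ids), rownames(features))
  if (length(missing))
    stop("pairs without feature rows: ", paste(head(missing, 5), collapse = ", "))
  t <- length(neg_ids) %/% length(pos_ids)
  if (t < 2)
    stop("potential-negative labelling needs t >= 2 (got t = ", t,
         "); too few assumed negatives per positive")

  set.seed(seed)
  shuffled <- sample(neg_ids)
  subset_of <- setNames(rep_len(seq_len(t), length(neg_ids)), shuffled)

  votes <- setNames(integer(length(neg_ids)), neg_ids)
  X_pos <- features[pos_ids, , drop = FALSE]
  for (s in seq_len(t)) {
    in_s <- names(subset_of)[subset_of == s]
    X <- rbind(X_pos, features[in_s, , drop = FALSE])
    y <- factor(c(rep(1, length(pos_ids)), rep(0, length(in_s))), levels = c(0, 1))
    fit <- tryCatch(
      do.call(e1071::svm, c(list(x = X, y = y), svm_args)),
      error = function(e) stop("SVM training failed for subset ", s, ": ",
                               conditionMessage(e)))
    held_out <- setdiff(neg_ids, in_s)
    pred <- predict(fit, features[held_out, , drop = FALSE])
    votes[held_out] <- votes[held_out] + as.integer(pred == "0")
  }
  selected <- names(votes)[votes == t - 1L]
  labels <- label_set(
    metabolite = c(positives$metabolite,
                   assumed_negatives$metabolite[match(selected, neg_ids)]),
    protein = c(positives$protein,
                assumed_negatives$protein[match(selected, neg_ids)]),
    label = c(rep(1L, nrow(positives)), rep(0L, length(selected))),
    strategy = "potential-negative")
  list(labels = labels, t = t, votes = votes, subsets = subset_of)
}

#' Score-based ("random STITCH") labelling
#'
#' Positives are scored pairs above the threshold.  A remaining universe
#' pair is labelled negative iff both its metabolite and its protein occur
#' in at least one positive pair; all other pairs stay unlabelled.
#'
#' @param scores data.frame (`metabolite`, `protein`, `score`).
#' @param universe data.frame (`metabolite`, `protein`) of candidate pairs.
#' @param threshold strict score cutoff (default 500).
#' @return a `label_set` (unlabelled pairs are absent).
#' @export
random_stitch_labeling <- function(scores, universe, threshold = 500) {
  pos <- positives_from_scores(scores, threshold)
  pos_ids <- pair_ids(pos)
  rest <- universe[!pair_ids(universe) %in% pos_ids, , drop = FALSE]
  rest <- rest[!duplicated(pair_ids(rest)), , drop = FALSE]
  neg <- rest[rest$metabolite %in% pos$metabolite &
              rest$protein %in% pos$protein, , drop = FALSE]
  label_set(metabolite = c(pos$metabolite, neg$metabolite),
            protein = c(pos$protein, neg$protein),
            label = c(rep(1L, nrow(pos)), rep(0L, nrow(neg))),
            strategy = "random-stitch")
}

#' Tanimoto similarity of two 64-bit fingerprints
#'
#' `|a AND b| / |a OR b|` over the set bits.  Two all-zero fingerprints have
#' similarity 0 by convention (with a warning), since no substructure is
#' shared.
#'
#' @param a,b logical (or 0/1) vectors of length 64.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != 64 || length(b) != 64)
    stop("fingerprints must be exactly 64 bits")
  u <- sum(a | b)
  if (u == 0) {
    warning("two all-zero fingerprints; Tanimoto defined as 0")
    return(0)
  }
  sum(a & b) / u
}

#' Tanimoto-zero labelling of negatives
#'
#' For every positive pair (Met_i, Prot_j) and every other metabolite
#' Met_i' whose fingerprint has zero Tanimoto similarity to Met_i, the pair
#' (Met_i', Prot_j) is labelled negative unless it is itself a positive.
#'
#' @param positives data.frame (`metabolite`, `protein`).
#' @param fingerprints logical matrix, metabolites x 64 bits, rownames =
#'   metabolite ids; must cover all metabolites considered.
#' @return a `label_set`.
#' @export
tanimoto_labeling <- function(positives, fingerprints) {
  missing <- setdiff(unique(positives$metabolite), rownames(fingerprints))
  if (length(missing))
    stop("missing fingerprint for metabolite(s): ", paste(missing, collapse = ", "))
  fp <- fingerprints * 1L
  # pairs of metabolites with no shared bit: cross-product of bit matrices
  shared_bits <- fp %*% t(fp)
  pos_ids <- pair_ids(positives)
  neg <- list()
  for (i in seq_len(nrow(positives))) {
    m <- positives$metabolite[i]
    zero_sim <- rownames(fp)[shared_bits[m, ] == 0 & rownames(fp) != m]
    if (!length(zero_sim)) next
    cand <- paste(zero_sim, positives$protein[i], sep = ":")
    keep <- !(cand %in% pos_ids)
    if (any(keep))
      neg[[length(neg) + 1L]] <- data.frame(metabolite = zero_sim[keep],
                                            protein = positives$protein[i],
                                            stringsAsFactors = FALSE)
  }
  neg <- if (length(neg)) do.call(rbind, neg) else
    data.frame(metabolite = character(), protein = character())
  neg <- neg[!duplicated(pair_ids(neg)), , drop = FALSE]
  label_set(metabolite = c(positives$metabolite, neg$metabolite),
            protein = c(positives$protein, neg$protein),
            label = c(rep(1L, nrow(positives)), rep(0L, nrow(neg))),
            strategy = "tanimoto")
}

#' Balanced random labelling (control)
#'
#' Assigns exactly `floor(n / 2)` pairs the label 1 and the rest 0,
#' uniformly at random given the seed.  Used as the negative control:
#' classifiers trained on randomly labelled pairs should perform at chance.
#'
#' @param pairs data.frame (`metabolite`, `protein`).
#' @param seed integer seed.
#' @return a `label_set` with strategy `"random-control"`.
#' @export
random_labeling <- function(pairs, seed = 1) {
  n <- nrow(pairs)
  if (n < 2) stop("need at least 2 pairs to randomly label")
  set.seed(seed)
  lab <- integer(n)
  lab[sample(n, n %/% 2)] <- 1L
  label_set(pairs$metabolite, pairs$protein, lab, "random-control")
}

#' Load directly labelled pairs (PMI-DB-style TSV)
#'
#' @param path TSV with columns `metabolite`, `protein`, `label` (0/1).
#'   Consistent duplicates are deduplicated; conflicting duplicates are an
#'   error.
#' @return a `label_set` with strategy `"direct"`.
#' @export
load_direct_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("metabolite", "protein", "label") %in% names(tab)))
    stop("label TSV must have columns metabolite, protein, label")
  if (!all(tab$label %in% 0:1))
    stop("malformed label value(s): ",
         paste(unique(tab$label[!tab$label %in% 0:1]), collapse = ", "))
  ids <- pair_ids(tab)
  n_labels <- tapply(tab$label, ids, function(x) length(unique(x)))
  conflicts <- names(n_labels)[n_labels > 1]
  if (length(conflicts))
    stop("conflicting duplicate labels for: ", paste(conflicts, collapse = ", "))
  tab <- tab[!duplicated(ids), ]
  label_set(tab$metabolite, tab$protein, tab$label, "direct")
}

#' Write a label set to TSV
#' @param labels a `label_set`.
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  write.table(as.data.frame(labels), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read 64-bit fingerprints from TSV
#'
#' @param path TSV with columns `metabolite` and `fingerprint`
#'   (16 hexadecimal characters, most-significant bit first).
#' @return logical matrix, metabolites x 64.
#' @export
read_fingerprints <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character"))
  if (!all(c("metabolite", "fingerprint") %in% names(tab)))
    stop("fingerprint TSV must have columns metabolite, fingerprint")
  bad <- !grepl("^[0-9a-fA-F]{16}$", tab$fingerprint)
  if (any(bad))
    stop("malformed fingerprint for: ", paste(tab$metabolite[bad], collapse = ", "))
  bits <- t(vapply(tab$fingerprint, hex_to_bits, logical(64)))
  rownames(bits) <- tab$metabolite
  bits
}

#' Write fingerprints to TSV
#' @param fingerprints logical matrix, metabolites x 64.
#' @param path output path.
#' @export
write_fingerprints <- function(fingerprints, path) {
  hex <- apply(fingerprints, 1, bits_to_hex)
  write.table(data.frame(metabolite = rownames(fingerprints), fingerprint = hex),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

hex_to_bits <- function(hex) {
  nib <- strtoi(strsplit(tolower(hex), "")[[1]], base = 16L)
  as.logical(unlist(lapply(nib, function(x) bitwAnd(x, c(8L, 4L, 2L, 1L)) > 0)))
}

bits_to_hex <- function(bits) {
  nib <- vapply(split(as.integer(bits), rep(1:16, each = 4)),
                function(b) sum(b * c(8L, 4L, 2L, 1L)), integer(1))
  paste(format.hexmode(nib), collapse = "")
}
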