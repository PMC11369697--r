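# Flux sums, eta values, CV filtering and per-pair feature construction.

#' Flux sums of metabolites in one compartment
#'
#' The flux sum of metabolite k in condition j is half the total absolute
#' flux through it: `M[k, j] = 0.5 * sum_r |S[k, r] * v[r, j]|`.  At steady
#' state this equals both the total production and the total consumption of
#' the metabolite, and serves as a proxy for its concentration/turnover.
#' Metabolites are grouped by compartment; one compartment is processed per
#' call.
#'
#' @param model a `metabolic_model`.
#' @param fluxes a `flux_table` (or reaction x condition matrix).
#' @param compartment compartment id, e.g. `"c"` for cytoplasm.
#' @return a `flux_sum_table`: `raw` and max-`normalized` metabolite x
#'   condition matrices, the `compartment` tag, and `dropped` (ids of
#'   all-zero metabolites, removed from `normalized`).
#' @export
flux_sum <- function(model, fluxes, compartment) {
  v <- if (inherits(fluxes, "flux_table")) fluxes$values else fluxes
  comps <- unique(model$metabolites$compartment)
  if (!compartment %in% comps)
    stop("unknown compartment '", compartment, "'; valid: ",
         paste(comps, collapse = ", "))
  mets <- model$metabolites$id[model$metabolites$compartment == compartment]
  S <- stoich_matrix(model)[mets, rownames(v), drop = FALSE]
  raw <- 0.5 * abs(S) %*% abs(v)
  dimnames(raw) <- list(mets, colnames(v))
  norm <- normalize_rows(raw)
  structure(list(raw = raw, normalized = norm$normalized,
                 compartment = compartment, dropped = norm$dropped),
            class = "flux_sum_table")
}

#' Max-normalize a non-negative profile
#'
#' Divides by the profile maximum so the output lies in `[0, 1]` with
#' maximum exactly 1.  Idempotent.  An all-zero profile cannot be
#' normalized and is signalled as droppable rather than silently returned.
#'
#' @param profile numeric vector of non-negative values.
#' @return normalized vector.
#' @export
max_normalize <- function(profile) {
  m <- max(profile)
  if (!is.finite(m) || m <= 0)
    stop("all-zero (or undefined) profile cannot be max-normalized; drop it")
  profile / m
}

# Row-wise max normalization; all-zero rows are dropped and reported.
normalize_rows <- function(mat) {
  mx <- apply(mat, 1, max)
  keep <- is.finite(mx) & mx > 0
  list(normalized = mat[keep, , drop = FALSE] / mx[keep],
       dropped = rownames(mat)[!keep])
}

#' Apparent catalytic rates, in vivo k_cat proxies and eta values
#'
#' For each reaction i and condition j, `kapp[i, j] = |v[i, j]| / E[i, j]`
#' (undefined where the enzyme abundance E is zero or missing); the in vivo
#' `kcat[i]` proxy is the maximum of `kapp[i, ]` across conditions; and
#' `eta[i, j] = kapp[i, j] / kcat[i] = |v| / (E * kcat)`, the fraction of the
#' enzyme's capacity realized as flux, in `[0, 1]`.  Because kcat is the row
#' maximum, the max-normalized `eta_normalized` equals `eta` up to floating
#' tolerance.
#'
#' Reactions with no defined kapp entry or with kcat = 0 are dropped and
#' reported.  Distance features need complete profiles, so remaining
#' undefined entries are removed greedily: whichever single reaction (row) or
#' condition (column) carries the largest fraction of undefined entries is
#' dropped, repeatedly, until the matrix is complete; removals are logged in
#' `dropped_reactions` / `dropped_conditions`.
#'
#' @param fluxes a `flux_table` or reaction x condition matrix.
#' @param enzyme_abundance reaction x condition matrix from
#'   [reaction_enzyme_abundance()]; `NA` = undefined.
#' @return an `eta_table`: `kapp`, `kcat`, `eta`, `eta_normalized`,
#'   `dropped_reactions`, `dropped_conditions`.
#' @export
compute_eta <- function(fluxes, enzyme_abundance) {
  v <- if (inherits(fluxes, "flux_table")) fluxes$values else fluxes
  E <- enzyme_abundance
  shared <- intersect(colnames(v), colnames(E))
  if (!length(shared)) stop("flux and abundance tables share no conditions")
  rxns <- intersect(rownames(v), rownames(E))
  v <- abs(v[rxns, shared, drop = FALSE])
  E <- E[rxns, shared, drop = FALSE]
  kapp <- v / E
  kapp[is.na(E) | E <= 0] <- NA_real_

  defined <- rowSums(!is.na(kapp)) > 0
  kcat <- apply(kapp, 1, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  keep <- defined & !is.na(kcat) & is.finite(kcat) & kcat > 0
  dropped_rxn <- rownames(kapp)[!keep]
  kapp <- kapp[keep, , drop = FALSE]
  kcat <- kcat[keep]
  if (!nrow(kapp)) stop("no reaction has a defined, non-zero kapp profile")

  eta <- kapp / kcat

  dropped_cond <- character()
  while (anyNA(eta)) {
    row_na <- rowMeans(is.na(eta)); col_na <- colMeans(is.na(eta))
    if (max(row_na) >= max(col_na)) {
      r <- rownames(eta)[which.max(row_na)]
      dropped_rxn <- c(dropped_rxn, r)
      eta <- eta[setdiff(rownames(eta), r), , drop = FALSE]
    } else {
      cj <- colnames(eta)[which.max(col_na)]
      dropped_cond <- c(dropped_cond, cj)
      eta <- eta[, setdiff(colnames(eta), cj), drop = FALSE]
    }
    if (!nrow(eta) || !ncol(eta)) stop("no complete eta profiles remain")
  }
  # re-anchor the per-row maximum at 1 on the kept conditions
  eta_norm <- normalize_rows(eta)
  eta <- eta[rownames(eta_norm$normalized), , drop = FALSE]
  dropped_rxn <- c(dropped_rxn, eta_norm$dropped)
  kapp <- kapp[rownames(eta), colnames(eta), drop = FALSE]
  kcat <- kcat[rownames(eta)]
  structure(list(kapp = kapp, kcat = kcat, eta = eta,
                 eta_normalized = eta_norm$normalized,
                 dropped_reactions = dropped_rxn,
                 dropped_conditions = dropped_cond),
            class = "eta_table")
}

#' Coefficient-of-variation filter on metabolite-reaction pairs
#'
#' Computes the CV (sample standard deviation / mean, over conditions) of
#' every normalized eta profile and flux-sum profile, and retains a
#' (metabolite, reaction) pair iff both CVs are at or above the threshold.
#' Flat profiles carry no information for the classifiers, which is the
#' rationale for the filter.
#'
#' @param eta an `eta_table`.
#' @param fluxsums a `flux_sum_table`.
#' @param threshold minimum CV (default 1).
#' @return a `filter_report`: `cv_eta`, `cv_fluxsum`, `retained` and
#'   `removed` pair data.frames (`removed` has a `reason`), `conditions`
#'   (the shared condition order used), `threshold`.
#' @export
cv_filter <- function(eta, fluxsums, threshold = 1) {
  conds <- intersect(colnames(eta$eta_normalized), colnames(fluxsums$normalized))
  if (length(conds) < 2)
    stop("CV undefined: fewer than 2 shared conditions")
  en <- eta$eta_normalized[, conds, drop = FALSE]
  mn <- fluxsums$normalized[, conds, drop = FALSE]
  cv <- function(x) sd(x) / mean(x)
  cv_eta <- apply(en, 1, cv)
  cv_M <- apply(mn, 1, cv)

  pairs <- expand.grid(metabolite = rownames(mn), reaction = rownames(en),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ok_eta <- cv_eta[pairs$reaction] >= threshold
  ok_M <- cv_M[pairs$metabolite] >= threshold
  keep <- ok_eta & ok_M
  reason <- ifelse(!ok_eta & !ok_M, "cv_eta and cv_fluxsum below threshold",
            ifelse(!ok_eta, "cv_eta below threshold", "cv_fluxsum below threshold"))
  retained <- pairs[keep, , drop = FALSE]
  removed <- cbind(pairs[!keep, , drop = FALSE], reason = reason[!keep])
  rownames(retained) <- rownames(removed) <- NULL
  structure(list(cv_eta = cv_eta, cv_fluxsum = cv_M, retained = retained,
                 removed = removed, conditions = conds, threshold = threshold),
            class = "filter_report")
}

# index pairs (n, m), n < m, row-major over the upper triangle (diagonal
# excluded), shared by all pairwise feature constructions
upper_pairs <- function(J) {
  idx <- which(upper.tri(matrix(0, J, J)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Distance-matrix features for one metabolite-reaction pair
#'
#' Each condition j defines a point `(eta[j], M[j])` in the unit square.
#' The feature vector concatenates, row-major, the upper triangle (diagonal
#' excluded) of the condition-by-condition Euclidean distance matrix,
#' giving `J * (J - 1) / 2` entries, each in `[0, sqrt(2)]`.
#'
#' @param eta_profile normalized eta profile (length J).
#' @param fluxsum_profile normalized flux-sum profile (length J, same
#'   condition order).
#' @return numeric feature vector of length `J * (J - 1) / 2`.
#' @export
distance_features <- function(eta_profile, fluxsum_profile) {
  if (length(eta_profile) != length(fluxsum_profile))
    stop("profile length mismatch")
  p <- upper_pairs(length(eta_profile))
  sqrt((eta_profile[p[, 1]] - eta_profile[p[, 2]])^2 +
       (fluxsum_profile[p[, 1]] - fluxsum_profile[p[, 2]])^2)
}

#' Constant-replacement ablation of the distance features
#'
#' Replaces the flux-sum difference in the distance construction with a
#' constant `c`, probing whether the eta profile alone carries the signal:
#' entries become `sqrt((eta[n] - eta[m])^2 + c^2)`.
#'
#' @param eta_profile normalized eta profile.
#' @param c the constant (default 0, reducing to `|eta[n] - eta[m]|`).
#' @return numeric feature vector, same layout as [distance_features()].
#' @export
constant_ablation_features <- function(eta_profile, c = 0) {
  p <- upper_pairs(length(eta_profile))
  sqrt((eta_profile[p[, 1]] - eta_profile[p[, 2]])^2 + c^2)
}

#' Concatenated-profile features
#'
#' The plain alternative to the distance construction: the normalized eta
#' and flux-sum profiles concatenated in condition order (length 2J).
#'
#' @inheritParams distance_features
#' @return numeric vector `c(eta_profile, fluxsum_profile)`.
#' @export
concatenated_features <- function(eta_profile, fluxsum_profile) {
  if (length(eta_profile) != length(fluxsum_profile))
    stop("profile length mismatch")
  c(eta_profile, fluxsum_profile)
}

#' Build the pair-feature matrix
#'
#' One row per retained (metabolite, reaction) pair -- the Cartesian product
#' of retained metabolites and reactions from the filter report -- in the
#' requested mode: `"distance"` (pairwise-distance upper triangle,
#' `J(J-1)/2` columns), `"concatenated"` (`2J` columns) or `"constant"`
#' (distance layout with the flux-sum difference replaced by `constant`).
#'
#' @param eta an `eta_table`.
#' @param fluxsums a `flux_sum_table`.
#' @param report a `filter_report` produced from the same tables.
#' @param mode feature mode.
#' @param constant the ablation constant (mode `"constant"` only).
#' @return numeric matrix with rownames `"metabolite:reaction"` and
#'   attributes `mode`, `conditions` and `pairs` (the pair data.frame).
#' @export
build_pair_features <- function(eta, fluxsums, report,
                                mode = c("distance", "concatenated", "constant"),
                                constant = 0) {
  mode <- match.arg(mode)
  pairs <- report$retained
  if (!nrow(pairs)) stop("no retained pairs to build features for")
  conds <- report$conditions
  en <- eta$eta_normalized[, conds, drop = FALSE]
  mn <- fluxsums$normalized[, conds, drop = FALSE]
  J <- length(conds)
  rxns <- unique(pairs$reaction); mets <- unique(pairs$metabolite)

  if (mode == "concatenated") {
    X <- cbind(en[pairs$reaction, , drop = FALSE], mn[pairs$metabolite, , drop = FALSE])
    colnames(X) <- c(paste0("eta_", conds), paste0("fluxsum_", conds))
  } else {
    p <- upper_pairs(J)
    d_eta2 <- (en[, p[, 1], drop = FALSE] - en[, p[, 2], drop = FALSE])^2
    if (mode == "distance") {
      d_M2 <- (mn[, p[, 1], drop = FALSE] - mn[, p[, 2], drop = FALSE])^2
      X <- sqrt(d_eta2[pairs$reaction, , drop = FALSE] +
                d_M2[pairs$metabolite, , drop = FALSE])
    } else {
      X <- sqrt(d_eta2[pairs$reaction, , drop = FALSE] + constant^2)
    }
    colnames(X) <- paste0("D_", conds[p[, 1]], "_", conds[p[, 2]])
  }
  if (anyNA(X)) stop("undefined feature values; profiles must be complete")
  rownames(X) <- paste(pairs$metabolite, pairs$reaction, sep = ":")
  structure(X, mode = mode, conditions = conds, pairs = pairs,
            constant = if (mode == "constant") constant else NULL,
            class = c("pair_feature_matrix", class(X)))
}

#' Export a pair-feature matrix to TSV with a JSON sidecar
#'
#' The TSV has a `pair` key column (`metabolite:reaction`) and one column
#' per feature; the sidecar records mode, condition order and provenance.
#'
#' @param features a `pair_feature_matrix`.
#' @param path output TSV path; the sidecar is written to `<path>.json`.
#' @export
write_features <- function(features, path) {
  write_matrix_tsv(features, path, "pair")
  meta <- list(mode = attr(features, "mode"),
               conditions = attr(features, "conditions"),
               constant = attr(features, "constant"),
               n_pairs = nrow(features), n_features = ncol(features))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
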