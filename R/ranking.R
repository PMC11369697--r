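#' Rank metabolites by the number of distinct regulated reactions
#'
#' Given the metabolite-protein-reaction triples predicted as interacting,
#' counts, per metabolite, the number of distinct reactions it is predicted
#' to regulate through the catalysing enzymes.
#'
#' @param predicted_positives data.frame with columns `metabolite`,
#'   `protein`, `reaction` (may be empty).
#' @return data.frame (`metabolite`, `n_reactions`, `reactions`
#'   semicolon-joined), sorted by decreasing count, ties broken by
#'   metabolite id.
#' @export
rank_metabolites <- function(predicted_positives) {
  if (!nrow(predicted_positives))
    return(data.frame(metabolite = character(), n_reactions = integer(),
                      reactions = character(), stringsAsFactors = FALSE))
  stopifnot(all(c("metabolite", "reaction") %in% names(predicted_positives)))
  sets <- tapply(predicted_positives$reaction, predicted_positives$metabolite,
                 function(r) sort(unique(r)), simplify = FALSE)
  out <- data.frame(metabolite = names(sets),
                    n_reactions = vapply(sets, length, integer(1)),
                    reactions = vapply(sets, paste, character(1), collapse = ";"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$n_reactions, out$metabolite), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Aggregate out-of-fold CV predictions into positive triples
#'
#' A pair counts as predicted positive when it was predicted interacting in
#' at least `min_fraction` of the repetitions that tested it.
#'
#' @param result a `cv_result`.
#' @param triples data.frame (`metabolite`, `protein`, `reaction`) keyed
#'   like the feature rows (`metabolite:protein`).
#' @param min_fraction minimum positive-prediction fraction (default 0.5).
#' @return data.frame of positive (`metabolite`, `protein`, `reaction`)
#'   triples.
#' @export
predicted_positive_triples <- function(result, triples, min_fraction = 0.5) {
  preds <- result$predictions
  pos_pairs <- preds$pair[preds$positive_fraction >= min_fraction]
  keys <- paste(triples$metabolite, triples$protein, sep = ":")
  out <- triples[keys %in% pos_pairs, , drop = FALSE]
  rownames(out) <- NULL
  out
}
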