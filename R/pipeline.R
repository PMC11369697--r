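# Workflow orchestration: the feature stage shared by all entry points,
# labelling-strategy dispatch, and the file-based pipeline with metadata
# sidecars.

#' Compute all pair features from model, fluxes and proteomics
#'
#' The feature stage of the workflow: maps gene abundances to reactions
#' through the GPR rules, computes eta values and compartment flux sums,
#' applies the CV filter, builds the metabolite-reaction feature matrix and
#' expands it to metabolite-protein keyed rows via the GPR mapping.
#'
#' @param model a `metabolic_model`.
#' @param fluxes a `flux_table`.
#' @param abundance gene x condition abundance matrix.
#' @param compartment compartment to analyse (default `"c"`, cytoplasm).
#' @param cv_threshold CV filter threshold (default 1).
#' @param mode feature mode (`"distance"`, `"concatenated"`, `"constant"`).
#' @param constant ablation constant for mode `"constant"`.
#' @return list with `eta`, `fluxsums`, `report`, `features`
#'   (metabolite-reaction keyed `pair_feature_matrix`), `triples`
#'   (metabolite/protein/reaction), and `pair_features`
#'   (metabolite-protein keyed matrix for classification).
#' @export
pipeline_features <- function(model, fluxes, abundance, compartment = "c",
                              cv_threshold = 1, mode = "distance", constant = 0) {
  E_rxn <- reaction_enzyme_abundance(model, abundance)
  eta <- compute_eta(fluxes, E_rxn)
  fs <- flux_sum(model, fluxes, compartment)
  report <- cv_filter(eta, fs, threshold = cv_threshold)
  features <- build_pair_features(eta, fs, report, mode = mode, constant = constant)
  triples <- map_pairs_to_proteins(model, attr(features, "pairs"))
  feat_key <- paste(triples$metabolite, triples$reaction, sep = ":")
  pair_features <- features[feat_key, , drop = FALSE]
  rownames(pair_features) <- paste(triples$metabolite, triples$protein, sep = ":")
  keep <- !duplicated(rownames(pair_features))
  pair_features <- pair_features[keep, , drop = FALSE]
  list(eta = eta, fluxsums = fs, report = report, features = features,
       triples = triples, pair_features = pair_features)
}

#' Read an interaction-score table (STITCH-style TSV)
#'
#' @param path TSV with columns `metabolite`, `protein` and `score` (or
#'   `combined_score`).
#' @return data.frame (`metabolite`, `protein`, `score`).
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if ("combined_score" %in% names(tab) && !"score" %in% names(tab))
    tab$score <- tab$combined_score
  if (!all(c("metabolite", "protein", "score") %in% names(tab)))
    stop("score TSV must have columns metabolite, protein, score/combined_score")
  tab[, c("metabolite", "protein", "score")]
}

#' Build a label set by the requested strategy
#'
#' @param strategy one of `"direct"`, `"potential"`, `"random-stitch"`,
#'   `"tanimoto"`, `"random"`.
#' @param universe data.frame (`metabolite`, `protein`) of candidate pairs
#'   (typically the rows of the pair feature matrix).
#' @param pair_features metabolite-protein keyed feature matrix (needed for
#'   `"potential"`).
#' @param scores score data.frame (for score-based strategies).
#' @param fingerprints fingerprint matrix (for `"tanimoto"`).
#' @param direct_labels a `label_set` (for `"direct"`).
#' @param seed integer seed.
#' @param threshold score threshold (default 500).
#' @return a `label_set`, restricted to pairs present in the universe.
#' @export
build_labels <- function(strategy, universe, pair_features = NULL, scores = NULL,
                         fingerprints = NULL, direct_labels = NULL, seed = 1,
                         threshold = 500) {
  uni_ids <- pair_ids(universe)
  labels <- switch(strategy,
    direct = direct_labels,
    random = random_labeling(universe, seed = seed),
    `random-stitch` = random_stitch_labeling(scores, universe, threshold = threshold),
    tanimoto = tanimoto_labeling(
      positives_from_scores(scores, threshold), fingerprints),
    potential = {
      pos <- positives_from_scores(scores, threshold)
      pos <- pos[pair_ids(pos) %in% uni_ids, , drop = FALSE]
      an <- universe[!uni_ids %in% pair_ids(pos), , drop = FALSE]
      potential_negative_labeling(pair_features, pos, an, seed = seed)$labels
    },
    stop("unknown labelling strategy: ", strategy))
  out <- labels[pair_ids(labels) %in% uni_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

stage_meta <- function(out_dir, stage, params, inputs = character()) {
  meta <- list(stage = stage, params = params,
               inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, file.path(out_dir, paste0(stage, ".meta.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the full prediction pipeline
#'
#' Executes simulate (optional) -> fluxes -> features -> label -> train ->
#' rank, writing each stage's artifact and a JSON metadata sidecar
#' (parameters, input hashes, seed) into `out_dir`.  With
#' `resume = TRUE`, a stage whose artifact already exists is loaded instead
#' of recomputed.
#'
#' @param config named list: either `simulate` (a [generate_dataset()]
#'   config list, possibly empty) or input paths `model`, `conditions`,
#'   `abundance` (plus optional `fluxes` to skip pFBA, `scores`, `labels`,
#'   `fingerprints`); analysis parameters `compartment` (default `"c"`),
#'   `cv_threshold` (1), `feature_mode` (`"distance"`), `constant` (0),
#'   `strategy` (`"direct"`), `classifier` (`"rf"`), `folds` (5), `reps`
#'   (100), `grid` (NULL = defaults), `min_positive_fraction` (0.5); and
#'   `out_dir`, `seed`.
#' @param resume load existing stage artifacts instead of recomputing.
#' @return list with `metrics` (the `cv_result`), `ranking`, `labels`,
#'   and the feature-stage objects, invisibly.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  defaults <- list(compartment = "c", cv_threshold = 1, feature_mode = "distance",
                   constant = 0, strategy = "direct", classifier = "rf",
                   folds = 5, reps = 100, grid = NULL,
                   min_positive_fraction = 0.5, seed = 1, out_dir = "mpi_run")
  config <- modifyList(defaults, config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    data_dir <- file.path(out_dir, "data")
    if (!resume || !file.exists(file.path(data_dir, "model.json"))) {
      bundle <- generate_dataset(config$simulate, seed = config$seed)
      write_bundle(bundle, data_dir)
      stage_meta(out_dir, "simulate",
                 c(config$simulate, list(seed = config$seed)))
    }
    config$model <- file.path(data_dir, "model.json")
    config$conditions <- file.path(data_dir, "conditions.json")
    config$abundance <- file.path(data_dir, "abundance.tsv")
    config$scores <- file.path(data_dir, "scores.tsv")
    config$labels <- file.path(data_dir, "labels.tsv")
    config$fingerprints <- file.path(data_dir, "fingerprints.tsv")
  }
  for (key in c("model", "conditions", "abundance")) {
    if (is.null(config[[key]])) stop("config is missing required input '", key, "'")
    if (!file.exists(config[[key]]))
      stop("input file for '", key, "' not found: ", config[[key]])
  }

  model <- read_model(config$model)
  conditions <- read_conditions(config$conditions)
  abundance <- read_abundance(config$abundance)

  flux_path <- file.path(out_dir, "fluxes.tsv")
  if (!is.null(config$fluxes)) {
    fluxes <- read_fluxes(config$fluxes)
  } else if (resume && file.exists(flux_path)) {
    fluxes <- read_fluxes(flux_path)
  } else {
    fluxes <- pfba_all(model, conditions)
    write_fluxes(fluxes, flux_path)
    stage_meta(out_dir, "fluxes", list(seed = config$seed),
               c(config$model, config$conditions))
  }

  feat <- pipeline_features(model, fluxes, abundance,
                            compartment = config$compartment,
                            cv_threshold = config$cv_threshold,
                            mode = config$feature_mode,
                            constant = config$constant)
  write_features(feat$features, file.path(out_dir, "features.tsv"))
  stage_meta(out_dir, "features",
             list(compartment = config$compartment,
                  cv_threshold = config$cv_threshold,
                  mode = config$feature_mode, constant = config$constant),
             c(config$model, config$abundance))

  universe <- unique(feat$triples[, c("metabolite", "protein")])
  labels <- build_labels(
    config$strategy, universe, pair_features = feat$pair_features,
    scores = if (!is.null(config$scores)) read_scores(config$scores),
    fingerprints = if (!is.null(config$fingerprints))
      read_fingerprints(config$fingerprints),
    direct_labels = if (!is.null(config$labels)) load_direct_labels(config$labels),
    seed = config$seed)
  write_labels(labels, file.path(out_dir, "labels_used.tsv"))
  stage_meta(out_dir, "label", list(strategy = config$strategy, seed = config$seed))

  cfg <- cv_config(folds = config$folds, repetitions = config$reps,
                   model_kind = config$classifier, grid = config$grid,
                   seed = config$seed)
  metrics <- balanced_cv(feat$pair_features, labels, cfg)
  jsonlite::write_json(
    list(aggregate = metrics$aggregate, config = list(
      classifier = config$classifier, folds = config$folds,
      repetitions = config$reps, seed = config$seed,
      confusion_aggregation = "averaged over repetitions")),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(metrics$per_fold, file.path(out_dir, "metrics_per_fold.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(metrics$predictions, file.path(out_dir, "predictions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stage_meta(out_dir, "train",
             list(classifier = config$classifier, folds = config$folds,
                  reps = config$reps, seed = config$seed))

  pos_triples <- predicted_positive_triples(metrics, feat$triples,
                                            config$min_positive_fraction)
  ranking <- rank_metabolites(pos_triples)
  write.table(ranking, file.path(out_dir, "ranking.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stage_meta(out_dir, "rank",
             list(min_positive_fraction = config$min_positive_fraction))

  invisible(list(metrics = metrics, ranking = ranking, labels = labels,
                 features = feat))
}
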