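#' Construct a metabolic model
#'
#' Builds the in-memory model object used throughout the package: metabolite
#' and reaction tables, per-reaction stoichiometry, bounds, GPR rules and
#' objective weights.  Validation enforces the structural invariants
#' (declared metabolites, lb <= ub, non-empty compartments, at least one
#' objective reaction).
#'
#' @param metabolites data.frame with columns `id`, `compartment`.
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`, `gpr`, `objective_weight`.
#' @param stoich named list (one entry per reaction id) of named numeric
#'   vectors: metabolite id -> signed stoichiometric coefficient.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoich) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "compartment") %in% names(metabolites)),
            all(c("id", "lower_bound", "upper_bound", "gpr", "objective_weight")
                %in% names(reactions)))
  model <- structure(list(metabolites = metabolites, reactions = reactions,
                          stoich = stoich[reactions$id]), class = "metabolic_model")
  model$genes <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
  model$gpr_units <- lapply(reactions$gpr, parse_gpr)
  names(model$gpr_units) <- reactions$id
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; stops with an informative message on the
#'   first violated invariant.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites; rxns <- model$reactions
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(rxns$id)) stop("duplicate reaction ids")
  if (any(!nzchar(mets$compartment)) || anyNA(mets$compartment))
    stop("metabolite with empty compartment: ",
         paste(mets$id[!nzchar(mets$compartment) | is.na(mets$compartment)], collapse = ", "))
  for (r in rxns$id) {
    s <- model$stoich[[r]]
    if (is.null(s) || !length(s)) stop("reaction '", r, "' has no stoichiometry")
    unknown <- setdiff(names(s), mets$id)
    if (length(unknown))
      stop("reaction '", r, "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
  }
  bad <- rxns$lower_bound > rxns$upper_bound
  if (any(bad))
    stop("reaction '", rxns$id[which(bad)[1]], "' has lower_bound > upper_bound")
  if (all(rxns$objective_weight == 0))
    stop("model has no objective (biomass) reaction")
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (r in model$reactions$id) {
    s <- model$stoich[[r]]
    S[names(s), r] <- s
  }
  S
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model: %d metabolites (%d compartments), %d reactions, %d genes\n",
              nrow(x$metabolites), length(unique(x$metabolites$compartment)),
              nrow(x$reactions), length(x$genes)))
  invisible(x)
}

#' Read a metabolic model from BiGG-style JSON
#'
#' Supported dialect (a BiGG JSON subset):
#' `metabolites[{id, compartment}]` and `reactions[{id, metabolites,
#' lower_bound, upper_bound, gene_reaction_rule, objective_coefficient}]`.
#' Reaction and metabolite order is the file order.
#'
#' @param path path to the JSON file.
#' @param dialect currently only `"bigg-json"`.
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, dialect = "bigg-json") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed model JSON in '", path, "': ",
                                           conditionMessage(e)))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("malformed model file '", path, "': missing 'metabolites' or 'reactions'")
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) as.character(m$id), character(1)),
    compartment = vapply(doc$metabolites, function(m)
      as.character(m$compartment %||% ""), character(1)),
    stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = vapply(doc$reactions, function(r) as.character(r$id), character(1)),
    lower_bound = vapply(doc$reactions, function(r) as.numeric(r$lower_bound %||% -1000), numeric(1)),
    upper_bound = vapply(doc$reactions, function(r) as.numeric(r$upper_bound %||% 1000), numeric(1)),
    gpr = vapply(doc$reactions, function(r) as.character(r$gene_reaction_rule %||% ""), character(1)),
    objective_weight = vapply(doc$reactions, function(r)
      as.numeric(r$objective_coefficient %||% 0), numeric(1)),
    stringsAsFactors = FALSE)
  stoich <- lapply(doc$reactions, function(r) {
    s <- unlist(r$metabolites)
    if (is.null(s)) stop("malformed model file: reaction '", r$id, "' has no metabolites")
    storage.mode(s) <- "double"
    s
  })
  names(stoich) <- rxns$id
  metabolic_model(mets, rxns, stoich)
}

#' Write a metabolic model to BiGG-style JSON
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      list(id = model$metabolites$id[i],
           compartment = model$metabolites$compartment[i])),
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      list(id = r$id, metabolites = as.list(model$stoich[[r$id]]),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gene_reaction_rule = r$gpr, objective_coefficient = r$objective_weight)
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-reaction enzyme abundance from gene-level proteomics
#'
#' Maps a gene-level abundance table to reaction level through the GPR rules:
#' each AND-unit (enzyme complex) contributes the minimum of its members'
#' abundances, alternative units (isozymes) are summed.  Reactions with an
#' empty GPR, or with no unit fully measured in a given condition, are
#' `NA` (undefined) and excluded downstream.
#'
#' @param model a `metabolic_model`.
#' @param abundance numeric matrix, genes x conditions (non-negative).
#' @param policy abundance aggregation policy; only
#'   `"min-over-complex_sum-over-isozymes"` is implemented.
#' @return numeric matrix, reactions x conditions, with `NA` where undefined.
#' @export
reaction_enzyme_abundance <- function(model, abundance,
                                      policy = "min-over-complex_sum-over-isozymes") {
  policy <- match.arg(policy)
  stopifnot(is.matrix(abundance))
  if (any(abundance < 0, na.rm = TRUE)) stop("negative abundance entries")
  out <- matrix(NA_real_, nrow(model$reactions), ncol(abundance),
                dimnames = list(model$reactions$id, colnames(abundance)))
  for (r in model$reactions$id) {
    units <- model$gpr_units[[r]]
    if (!length(units)) next
    for (j in seq_len(ncol(abundance))) {
      contribs <- vapply(units, function(u) {
        if (!all(u %in% rownames(abundance))) return(NA_real_)
        v <- abundance[u, j]
        if (anyNA(v)) NA_real_ else min(v)
      }, numeric(1))
      if (all(is.na(contribs))) next
      out[r, j] <- sum(contribs, na.rm = TRUE)
    }
  }
  out
}

#' Expand metabolite-reaction pairs to metabolite-protein triples
#'
#' Uses the GPR rules to transform metabolite-reaction pairs into
#' metabolite-protein pairs: one triple per gene appearing in the reaction's
#' GPR.  Reactions with an empty GPR emit no triples.
#'
#' @param model a `metabolic_model`.
#' @param met_reaction_pairs data.frame with columns `metabolite`, `reaction`.
#' @return data.frame with columns `metabolite`, `protein`, `reaction`,
#'   in deterministic (input, then gene) order.
#' @export
map_pairs_to_proteins <- function(model, met_reaction_pairs) {
  stopifnot(all(c("metabolite", "reaction") %in% names(met_reaction_pairs)))
  missing_rxn <- setdiff(met_reaction_pairs$reaction, model$reactions$id)
  if (length(missing_rxn)) stop("unknown reaction(s): ", paste(missing_rxn, collapse = ", "))
  missing_met <- setdiff(met_reaction_pairs$metabolite, model$metabolites$id)
  if (length(missing_met)) stop("unknown metabolite(s): ", paste(missing_met, collapse = ", "))
  rows <- lapply(seq_len(nrow(met_reaction_pairs)), function(i) {
    r <- met_reaction_pairs$reaction[i]
    genes <- sort(unique(unlist(model$gpr_units[[r]])))
    if (!length(genes)) return(NULL)
    data.frame(metabolite = met_reaction_pairs$metabolite[i], protein = genes,
               reaction = r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(metabolite = character(), protein = character(),
                      reaction = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
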