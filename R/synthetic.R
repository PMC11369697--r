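# Synthetic study generator: a toy flux-consistent model, condition-varying
# fluxes, a planted metabolite->reaction regulatory ground truth expressed
# through Michaelis-Menten-style eta profiles, and back-computed proteomics,
# interaction scores, fingerprints and labels.

#' Generate a toy metabolic model
#'
#' Builds a flux-consistent model with one cytoplasm (`"c"`) and one
#' extracellular (`"e"`) compartment: a shared carbon source feeding a trunk
#' metabolite that splits into `n_branches` pathways.  Each branch has its
#' own primary substrate entering at the chain head (different carbon
#' sources, as in multi-condition proteomics studies), an upper chain that
#' forks into two sub-chains, each ending in its own biomass precursor,
#' each fed mid-way by its own auxiliary carbon source, with a side drain
#' on every interior metabolite and an overflow valve at its end; a trunk
#' sink disposes of unused shared carbon.  Conditions force
#' condition-specific uptake and drain fluxes through these, which is what
#' makes flux profiles vary non-proportionally across conditions, across
#' branches and along each pathway.  Every enzyme-catalysed reaction gets a
#' GPR rule: 80% single gene, 10% two-gene complex (`and`), 10% two-gene
#' isozyme pair (`or`).
#'
#' @param n_branches number of branches (>= 1).
#' @param seed integer seed.
#' @param chain_length enzyme-catalysed steps per branch (default 15),
#'   split into an upper chain and two equal sub-chains.
#' @return a `metabolic_model` with a `toy_layout` attribute describing the
#'   branch structure (used by [simulate_conditions()] and
#'   [synthetic_truth()]).
#' @export
make_toy_model <- function(n_branches = 4, seed = 1, chain_length = 15) {
  stopifnot(n_branches >= 1, chain_length >= 5)
  set.seed(seed)
  Ls <- max(2, (chain_length - max(1, round(chain_length / 4))) %/% 2)
  Lu <- chain_length - 2 * Ls            # upper-chain steps; sub-chains get Ls each
  biomass_coef <- runif(2 * n_branches, 0.5, 1)
  aux_entry <- pmin(Ls - 1, 2)           # auxiliary source enters mid-sub-chain

  mets <- data.frame(id = "glc_e", compartment = "e")
  mets <- rbind(mets, data.frame(id = paste0("sub", seq_len(n_branches), "_e"),
                                 compartment = "e"))
  for (b in seq_len(n_branches))
    mets <- rbind(mets, data.frame(id = sprintf("aux%d_%d_e", b, 1:2),
                                   compartment = "e"))
  mets <- rbind(mets, data.frame(id = "A_c", compartment = "c"))
  for (b in seq_len(n_branches)) {
    mets <- rbind(mets, data.frame(id = sprintf("X%d_%d_c", b, 0:Lu), compartment = "c"))
    for (s in 1:2)
      mets <- rbind(mets, data.frame(id = sprintf("Y%d_%d_%d_c", b, s, 1:Ls),
                                     compartment = "c"))
  }

  gene_n <- 0L
  next_gpr <- function() {
    u <- runif(1)
    n_genes <- if (u < 0.8) 1L else 2L
    ids <- sprintf("g%04d", gene_n + seq_len(n_genes))
    gene_n <<- gene_n + n_genes
    if (n_genes == 1L) ids else if (u < 0.9) paste(ids, collapse = " and ")
    else paste(ids, collapse = " or ")
  }

  rxns <- list(); stoich <- list()
  add <- function(id, s, lb = 0, ub = 1000, gpr = "", obj = 0) {
    rxns[[length(rxns) + 1L]] <<- data.frame(
      id = id, lower_bound = lb, upper_bound = ub, gpr = gpr,
      objective_weight = obj, stringsAsFactors = FALSE)
    stoich[[id]] <<- s
  }

  add("EX_glc", c(glc_e = -1), lb = -1000, ub = 0)
  add("GLCt", c(glc_e = -1, A_c = 1), gpr = next_gpr())
  add("SINK_A", c(A_c = -1))
  step_ids <- character(); drain_ids <- character()
  drain_branch <- integer()
  for (b in seq_len(n_branches)) {
    metX <- function(l) sprintf("X%d_%d_c", b, l)
    metY <- function(s, l) sprintf("Y%d_%d_%d_c", b, s, l)
    add(sprintf("EX_sub%d", b), setNames(-1, sprintf("sub%d_e", b)), lb = -1000, ub = 0)
    add(sprintf("SUB%dt", b),
        setNames(c(-1, 1), c(sprintf("sub%d_e", b), metX(0))), gpr = next_gpr())
    add(sprintf("FEED%d", b), setNames(c(-1, 1), c("A_c", metX(0))))
    for (l in seq_len(Lu)) {
      id <- sprintf("R%d_%d", b, l)
      add(id, setNames(c(-1, 1), c(metX(l - 1), metX(l))), gpr = next_gpr())
      step_ids <- c(step_ids, id)
    }
    for (s in 1:2) {
      add(sprintf("EX_aux%d_%d", b, s), setNames(-1, sprintf("aux%d_%d_e", b, s)),
          lb = -1000, ub = 0)
      add(sprintf("AUX%d_%dt", b, s),
          setNames(c(-1, 1), c(sprintf("aux%d_%d_e", b, s), metY(s, aux_entry))),
          gpr = next_gpr())
      for (l in seq_len(Ls)) {
        id <- sprintf("R%d_%d_%d", b, s, l)
        from <- if (l == 1) metX(Lu) else metY(s, l - 1)
        add(id, setNames(c(-1, 1), c(from, metY(s, l))), gpr = next_gpr())
        step_ids <- c(step_ids, id)
      }
      for (l in seq_len(Ls - 1)) {
        id <- sprintf("DRAIN%d_%d_%d", b, s, l)
        add(id, setNames(-1, metY(s, l)))
        drain_ids <- c(drain_ids, id); drain_branch <- c(drain_branch, b)
      }
      add(sprintf("OF%d_%d", b, s), setNames(-1, metY(s, Ls)))
    }
    for (l in seq_len(Lu)) {
      id <- sprintf("DRAINX%d_%d", b, l)
      add(id, setNames(-1, metX(l)))
      drain_ids <- c(drain_ids, id); drain_branch <- c(drain_branch, b)
    }
  }
  precursors <- unlist(lapply(seq_len(n_branches), function(b)
    sprintf("Y%d_%d_%d_c", b, 1:2, Ls)))
  add("BIOMASS", setNames(-biomass_coef, precursors), obj = 1)

  model <- metabolic_model(mets, do.call(rbind, rxns), stoich)
  attr(model, "toy_layout") <- list(
    n_branches = n_branches, chain_length = chain_length,
    sub_chain_length = Ls, upper_length = Lu, biomass_coef = biomass_coef,
    step_reactions = step_ids, drain_reactions = drain_ids,
    drain_branch = drain_branch)
  model
}

#' Simulate growth conditions
#'
#' Draws `J` conditions for a toy model.  Each branch's primary substrate
#' gets its own uptake series: jittered log-spaced levels spanning the full
#' `uptake_range` (one order of magnitude by default, like a designed
#' carbon-limitation series, so the spread is guaranteed for any seed),
#' shuffled independently per branch so branch flux profiles are mutually
#' decorrelated.  The shared trunk carbon source varies over a narrower
#' range; per-branch auxiliary sources are present with probability
#' `aux_prob` at a rate comparable to the branch's own uptake; and sparse
#' random side-drain fluxes consume a small fraction of each branch's
#' uptake (always coverable by the branch head inflow, keeping the LP
#' feasible).  A configurable fraction of conditions carries one random
#' single-gene knockout; candidate knockouts are retried a bounded number
#' of times and rejected if they make any GPR unsatisfiable (the structural
#' feasibility check), falling back to no knockout.
#'
#' @param model a toy model from [make_toy_model()].
#' @param J number of conditions (>= 3).
#' @param seed integer seed.
#' @param knockout_fraction fraction of conditions with a knockout.
#' @param uptake_range per-branch substrate uptake range, default `c(2, 20)`.
#' @param aux_prob probability each auxiliary source is available.
#' @param drain_budget range of the total drain fraction of a branch's
#'   uptake.
#' @return list of `mpi_condition` objects.
#' @export
simulate_conditions <- function(model, J = 12, seed = 1, knockout_fraction = 0.25,
                                uptake_range = c(2, 20), aux_prob = 0.7,
                                drain_budget = c(0.3, 0.6)) {
  stopifnot(J >= 3)
  layout <- attr(model, "toy_layout")
  if (is.null(layout)) stop("simulate_conditions needs a model from make_toy_model()")
  set.seed(seed)
  B <- layout$n_branches

  levels_of <- function(lo, hi)
    sample(exp(seq(log(lo), log(hi), length.out = J)) * exp(runif(J, -0.1, 0.1)))
  u_sub <- vapply(seq_len(B), function(b) levels_of(uptake_range[1], uptake_range[2]),
                  numeric(J))                       # J x B, independent per branch
  # the shared trunk source is deliberately minor: a large one would buffer
  # scarce branches and flatten every flux profile across conditions
  u_main <- levels_of(uptake_range[1] / 2, uptake_range[1] * 2)
  aux_rxns <- grep("^EX_aux", model$reactions$id, value = TRUE)
  aux_branch <- as.integer(sub("^EX_aux(\\d+)_\\d+$", "\\1", aux_rxns))

  lapply(seq_len(J), function(j) {
    aux_on <- runif(length(aux_rxns)) < aux_prob
    u_aux <- aux_on * u_sub[j, aux_branch] * runif(length(aux_rxns), 0.3, 1.2)
    rho <- runif(B, drain_budget[1], drain_budget[2])
    d <- numeric(length(layout$drain_reactions))
    for (b in seq_len(B)) {
      i <- which(layout$drain_branch == b)
      w <- rgamma(length(i), shape = 0.15)
      d[i] <- rho[b] * u_sub[j, b] * w / sum(w)
    }

    ko <- character()
    if (runif(1) < knockout_fraction) {
      for (try in 1:10) {
        g <- sample(model$genes, 1)
        ok <- all(vapply(model$gpr_units, gpr_satisfied, logical(1), knockouts = g))
        if (ok) { ko <- g; break }
      }
    }
    condition(
      id = sprintf("cond%02d", j),
      uptake_bounds = data.frame(
        reaction = c("EX_glc", sprintf("EX_sub%d", seq_len(B)), aux_rxns),
        lb = c(-u_main[j], -u_sub[j, ], -u_aux),
        ub = c(-u_main[j], -u_sub[j, ], -u_aux)),
      knockouts = ko,
      measured_flux_bounds = data.frame(reaction = layout$drain_reactions,
                                        lb = d, ub = d))
  })
}

#' Plant a regulatory ground truth
#'
#' Samples `n_interactions` regulated reactions (one regulator metabolite
#' per reaction, so the truth is identifiable in both metabolite-reaction
#' and metabolite-protein keys), each with a mode (activation or
#' inhibition), a Hill exponent `alpha` in 2..4 and a half-saturation `K`,
#' plus a true turnover number per enzyme-catalysed reaction and the
#' abundance noise level `sigma`.
#'
#' @param model a toy model from [make_toy_model()].
#' @param n_interactions number of regulated reactions (default 40).
#' @param seed integer seed.
#' @param sigma log-scale multiplicative abundance noise (default 0.2).
#' @return object of class `synthetic_truth` with `regulation` (data.frame
#'   `reaction`, `metabolite`, `mode`, `alpha`, `K`), `pairs` (the
#'   metabolite-protein expansion), `kcat` (named vector) and `sigma`.
#' @export
synthetic_truth <- function(model, n_interactions = 40, seed = 1, sigma = 0.2) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (n_interactions < 1) stop("empty truth: n_interactions must be >= 1")
  layout <- attr(model, "toy_layout")
  if (is.null(layout)) stop("synthetic_truth needs a model from make_toy_model()")
  set.seed(seed)
  candidates <- layout$step_reactions
  if (n_interactions > length(candidates))
    stop("n_interactions exceeds the ", length(candidates),
         " enzyme-catalysed chain reactions in the model")
  cyt <- model$metabolites$id[model$metabolites$compartment == "c"]
  regulated <- sample(candidates, n_interactions)
  mode <- sample(c("activation", "inhibition"), n_interactions, replace = TRUE)
  # inhibitors get a lower half-saturation so eta drops over most of the
  # regulator's range instead of sitting near its maximum (flat profiles
  # would be discarded by the CV filter, as in real data)
  K <- ifelse(mode == "activation", runif(n_interactions, 0.25, 0.55),
              runif(n_interactions, 0.15, 0.35))
  regulation <- data.frame(
    reaction = regulated,
    metabolite = sample(cyt, n_interactions, replace = TRUE),
    mode = mode,
    alpha = sample(2:4, n_interactions, replace = TRUE),
    K = K,
    stringsAsFactors = FALSE)
  enzymatic <- names(model$gpr_units)[lengths(model$gpr_units) > 0]
  kcat <- setNames(rlnorm(length(enzymatic), log(50), 0.5), enzymatic)
  pairs <- map_pairs_to_proteins(model, regulation)
  structure(list(regulation = regulation, pairs = pairs, kcat = kcat,
                 sigma = sigma, seed = seed), class = "synthetic_truth")
}

# Michaelis-Menten-style regulator response on the normalized flux sum
hill_eta <- function(mhat, mode, alpha, K) {
  num <- mhat^alpha
  if (mode == "activation") num / (K^alpha + num) else K^alpha / (K^alpha + num)
}

#' Generate the matched omics layers for a planted truth
#'
#' Runs pFBA for every condition, computes cytoplasmic flux sums, then
#' builds eta profiles: a regulated reaction's eta follows a
#' Michaelis-Menten-style response (activation `Mhat^a / (K^a + Mhat^a)`,
#' inhibition `K^a / (K^a + Mhat^a)`) to its regulator's max-normalized flux
#' sum, while unregulated reactions draw independent spiky log-normal
#' profiles clipped to (0, 1] (profile sd 1.5 on the log scale, so flat
#' profiles that the CV filter would discard are rare).  Protein abundances
#' are back-computed as `E = |v| / (kcat * eta)` times `exp(sigma * z)`
#' noise, distributed over genes by inverting the min-over-complex /
#' sum-over-isozymes policy; knocked-out genes get abundance 0.  Interaction
#' scores are drawn in 501..1000 for truth pairs and 100..500 for decoys,
#' fingerprints are random 64-bit patterns in two disjoint-half clusters (so
#' zero-similarity pairs exist), and the direct label table mirrors the
#' truth.
#'
#' @param model a toy model from [make_toy_model()].
#' @param conditions conditions from [simulate_conditions()].
#' @param truth a `synthetic_truth`.
#' @param seed integer seed for the stochastic layers.
#' @param n_decoys number of decoy (assumed-negative) scored pairs.
#' @return a `synthetic_bundle`: `model`, `conditions`, `fluxes`,
#'   `fluxsums`, `eta_true`, `abundance` (gene x condition), `scores`,
#'   `fingerprints`, `labels`, `truth`.
#' @export
generate_omics <- function(model, conditions, truth, seed = 1, n_decoys = 400) {
  if (!inherits(truth, "synthetic_truth")) stop("truth must be a synthetic_truth")
  bad <- setdiff(truth$regulation$metabolite, model$metabolites$id)
  if (length(bad)) stop("truth references unknown metabolite(s): ",
                        paste(bad, collapse = ", "))
  set.seed(seed)
  fluxes <- pfba_all(model, conditions)
  if (any(fluxes$status != "optimal"))
    stop("pFBA failed for condition(s): ",
         paste(names(fluxes$status)[fluxes$status != "optimal"], collapse = ", "))
  fs <- flux_sum(model, fluxes, "c")
  mhat <- fs$normalized
  conds <- colnames(fluxes$values)

  enzymatic <- names(truth$kcat)
  eta_true <- matrix(NA_real_, length(enzymatic), length(conds),
                     dimnames = list(enzymatic, conds))
  reg_of <- setNames(seq_len(nrow(truth$regulation)), truth$regulation$reaction)
  for (i in enzymatic) {
    if (i %in% names(reg_of)) {
      r <- truth$regulation[reg_of[[i]], ]
      if (!r$metabolite %in% rownames(mhat))
        stop("regulator '", r$metabolite, "' has an all-zero flux sum")
      eta_true[i, ] <- hill_eta(mhat[r$metabolite, ], r$mode, r$alpha, r$K)
    } else {
      eta_true[i, ] <- pmin(exp(rnorm(length(conds), sd = 1.5)), 1)
    }
  }

  v <- abs(fluxes$values[enzymatic, , drop = FALSE])
  E_rxn <- v / (truth$kcat[enzymatic] * eta_true)
  # enzymes of momentarily idle reactions are still expressed at a baseline
  for (i in enzymatic) {
    idle <- v[i, ] == 0
    if (any(idle)) {
      base <- if (all(idle)) 1 else median(E_rxn[i, !idle])
      E_rxn[i, idle] <- base
    }
  }
  E_rxn <- E_rxn * exp(truth$sigma * matrix(rnorm(length(E_rxn)), nrow(E_rxn)))

  kos <- lapply(conditions, function(cd) cd$knockouts)
  names(kos) <- vapply(conditions, function(cd) cd$id, character(1))
  abundance <- matrix(0, length(model$genes), length(conds),
                      dimnames = list(model$genes, conds))
  for (i in enzymatic) {
    units <- model$gpr_units[[i]]
    for (j in conds) {
      active <- vapply(units, function(u) !any(u %in% kos[[j]]), logical(1))
      if (!any(active)) next
      share <- E_rxn[i, j] / sum(active)
      for (u in units[active]) abundance[u, j] <- share
    }
  }

  truth_pairs <- truth$pairs
  truth_ids <- pair_ids(truth_pairs)
  cyt <- model$metabolites$id[model$metabolites$compartment == "c"]
  proteins <- sort(unique(unlist(model$gpr_units)))
  decoys <- rbind(
    data.frame(metabolite = truth_pairs$metabolite,
               protein = sample(proteins, nrow(truth_pairs), replace = TRUE)),
    data.frame(metabolite = sample(cyt, nrow(truth_pairs), replace = TRUE),
               protein = truth_pairs$protein),
    data.frame(metabolite = sample(cyt, 3 * n_decoys, replace = TRUE),
               protein = sample(proteins, 3 * n_decoys, replace = TRUE)))
  decoys <- decoys[!pair_ids(decoys) %in% truth_ids, ]
  decoys <- decoys[!duplicated(pair_ids(decoys)), ]
  if (nrow(decoys) < n_decoys)
    stop("could not sample ", n_decoys, " distinct decoy pairs")
  decoys <- decoys[seq_len(n_decoys), ]
  rownames(decoys) <- NULL

  scores <- rbind(
    data.frame(metabolite = truth_pairs$metabolite, protein = truth_pairs$protein,
               score = as.integer(round(runif(nrow(truth_pairs), 501, 1000)))),
    data.frame(metabolite = decoys$metabolite, protein = decoys$protein,
               score = as.integer(round(runif(nrow(decoys), 100, 500)))))

  clust <- sample(1:2, length(cyt), replace = TRUE)
  fingerprints <- t(vapply(seq_along(cyt), function(i) {
    bits <- rep(FALSE, 64)
    half <- if (clust[i] == 1) 1:32 else 33:64
    bits[sample(half, 10)] <- TRUE
    bits
  }, logical(64)))
  rownames(fingerprints) <- cyt

  labels <- label_set(
    metabolite = c(truth_pairs$metabolite, decoys$metabolite),
    protein = c(truth_pairs$protein, decoys$protein),
    label = c(rep(1L, nrow(truth_pairs)), rep(0L, nrow(decoys))),
    strategy = "direct")

  structure(list(model = model, conditions = conditions, fluxes = fluxes,
                 fluxsums = fs, eta_true = eta_true, abundance = abundance,
                 scores = scores, fingerprints = fingerprints, labels = labels,
                 truth = truth),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(paste0("synthetic_bundle: %d conditions, %d genes, ",
                     "%d planted interactions, %d labelled pairs\n"),
              ncol(x$fluxes$values), nrow(x$abundance),
              nrow(x$truth$regulation), nrow(x$labels)))
  invisible(x)
}

#' Generate a complete synthetic dataset
#'
#' One-call composition of [make_toy_model()], [simulate_conditions()],
#' [synthetic_truth()] and [generate_omics()] with documented defaults
#' (J = 12 conditions, 4 branches, 40 planted interactions, sigma = 0.2,
#' 400 decoys).  All sub-seeds derive deterministically from `seed`.
#'
#' @param config named list overriding any of the defaults
#'   `n_branches`, `chain_length`, `J`, `n_interactions`, `sigma`,
#'   `n_decoys`, `knockout_fraction`, `aux_prob`.
#' @param seed master seed.
#' @return a `synthetic_bundle`.
#' @export
generate_dataset <- function(config = list(), seed = 1) {
  defaults <- list(n_branches = 4, chain_length = 15, J = 12,
                   n_interactions = 40, sigma = 0.2, n_decoys = 400,
                   knockout_fraction = 0.25, aux_prob = 0.7)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 4)
  model <- make_toy_model(cfg$n_branches, seed = seeds[1],
                          chain_length = cfg$chain_length)
  conditions <- simulate_conditions(model, J = cfg$J, seed = seeds[2],
                                    knockout_fraction = cfg$knockout_fraction,
                                    aux_prob = cfg$aux_prob)
  truth <- synthetic_truth(model, n_interactions = cfg$n_interactions,
                           seed = seeds[3], sigma = cfg$sigma)
  generate_omics(model, conditions, truth, seed = seeds[4],
                 n_decoys = cfg$n_decoys)
}

#' Write every layer of a bundle to standard-format files
#'
#' Emits exactly the formats the pipeline consumes (model JSON, conditions
#' JSON, abundance/flux/scores/fingerprints/labels TSV) plus `truth.json`,
#' which the pipeline never reads (test-only ground truth).
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_model(bundle$model, p("model.json"))
  write_conditions(bundle$conditions, p("conditions.json"))
  write_abundance(bundle$abundance, p("abundance.tsv"))
  write_fluxes(bundle$fluxes, p("fluxes.tsv"))
  write.table(bundle$scores, p("scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_fingerprints(bundle$fingerprints, p("fingerprints.tsv"))
  write_labels(bundle$labels, p("labels.tsv"))
  jsonlite::write_json(
    list(regulation = bundle$truth$regulation,
         kcat = as.list(bundle$truth$kcat), sigma = bundle$truth$sigma),
    p("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
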