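# Condition-specific parsimonious FBA.
#
# Numerical constants: steady-state/bound feasibility is checked at 1e-6;
# the LP itself is solved by a simplex method (exact up to floating point).

PFBA_TOL <- 1e-6

flux_table <- function(values, status, failures = list()) {
  structure(list(values = values, status = status, failures = failures),
            class = "flux_table")
}

#' @export
print.flux_table <- function(x, ...) {
  cat(sprintf("flux_table: %d reactions x %d conditions (%d failed)\n",
              nrow(x$values), ncol(x$values), length(x$failures)))
  invisible(x)
}

#' Apply a condition's constraints to a model
#'
#' Overwrites reaction bounds with the condition's uptake and measured flux
#' bounds, closes (0, 0) every reaction whose GPR is unsatisfiable under the
#' condition's knockouts (every isozyme unit contains a knocked-out gene),
#' and, if a growth rate is given, fixes the biomass reaction to it
#' (lb = ub = growth rate).
#'
#' @param model a `metabolic_model`.
#' @param cond an `mpi_condition`.
#' @return the constrained `metabolic_model`.
#' @export
apply_condition <- function(model, cond) {
  rxns <- model$reactions
  unknown_ko <- setdiff(cond$knockouts, model$genes)
  if (length(unknown_ko))
    stop("condition '", cond$id, "': unknown knockout gene(s): ",
         paste(unknown_ko, collapse = ", "))
  for (b in list(cond$uptake_bounds, cond$measured_flux_bounds)) {
    if (!nrow(b)) next
    unknown <- setdiff(b$reaction, rxns$id)
    if (length(unknown))
      stop("condition '", cond$id, "': unknown reaction(s) in bounds: ",
           paste(unknown, collapse = ", "))
    if (any(b$lb > b$ub)) stop("condition '", cond$id, "': bound pair with lb > ub")
    i <- match(b$reaction, rxns$id)
    rxns$lower_bound[i] <- b$lb
    rxns$upper_bound[i] <- b$ub
  }
  if (length(cond$knockouts)) {
    dead <- !vapply(model$gpr_units[rxns$id], gpr_satisfied, logical(1),
                    knockouts = cond$knockouts)
    rxns$lower_bound[dead] <- 0
    rxns$upper_bound[dead] <- 0
  }
  if (!is.na(cond$growth_rate)) {
    obj <- rxns$objective_weight != 0
    rxns$lower_bound[obj] <- cond$growth_rate
    rxns$upper_bound[obj] <- cond$growth_rate
  }
  model$reactions <- rxns
  model$condition_id <- cond$id
  model
}

#' Parsimonious flux balance analysis
#'
#' Two-stage LP.  Stage 1 maximizes the model objective (biomass) subject to
#' steady state `S v = 0` and the reaction bounds; if the biomass reaction is
#' already fixed (lb = ub, e.g. to a measured growth rate) the stage-1
#' optimum is that value.  Stage 2 fixes the biomass at the stage-1 optimum
#' and minimizes total absolute flux `sum(|v|)`, with `|v|` handled by the
#' standard split into non-negative forward/reverse parts.
#'
#' @param model a (condition-constrained) `metabolic_model`.
#' @return list with `fluxes` (named vector), `status`, `biomass`
#'   (stage-1 objective) and `total_flux` (stage-2 objective `sum(|v|)`).
#' @export
pfba <- function(model) {
  S <- stoich_matrix(model)
  rxns <- model$reactions
  n <- nrow(rxns)
  obj <- rxns$objective_weight

  s1 <- solve_lp(obj, S, rep(0, nrow(S)), rxns$lower_bound, rxns$upper_bound,
                 maximize = TRUE)
  if (s1$status != "optimal")
    stop("pFBA stage 1 (biomass) failed: ", s1$message,
         call. = FALSE)
  biomass <- s1$objective

  # stage 2: v = p - q, p,q >= 0; minimize sum(p + q) at fixed biomass
  lb <- rxns$lower_bound; ub <- rxns$upper_bound
  lp <- pmax(lb, 0); up <- pmax(ub, 0)
  lq <- pmax(-ub, 0); uq <- pmax(-lb, 0)
  Aeq <- rbind(cbind(S, -S), c(obj, -obj))
  beq <- c(rep(0, nrow(S)), biomass)
  s2 <- solve_lp(rep(1, 2 * n), Aeq, beq, c(lp, lq), c(up, uq), maximize = FALSE)
  if (s2$status != "optimal")
    stop("pFBA stage 2 (flux minimization) failed: ", s2$message, call. = FALSE)
  v <- s2$x[seq_len(n)] - s2$x[n + seq_len(n)]
  names(v) <- rxns$id
  resid <- max(abs(S %*% v))
  if (resid > PFBA_TOL)
    stop(sprintf("pFBA solution violates steady state (max |S v| = %.2e)", resid))
  list(fluxes = v, status = "optimal", biomass = biomass, total_flux = s2$objective)
}

#' pFBA across a set of conditions
#'
#' Applies each condition to the model and solves pFBA; conditions whose LP
#' fails are recorded in `failures` (with the error message) and excluded
#' from the flux matrix.
#'
#' @param model a `metabolic_model`.
#' @param conditions list of `mpi_condition`.
#' @return a `flux_table`: `values` (reaction x condition matrix), `status`
#'   per condition, `failures`.
#' @export
pfba_all <- function(model, conditions) {
  stopifnot(length(conditions) >= 1)
  ids <- vapply(conditions, function(cd) cd$id, character(1))
  cols <- list(); status <- character(); failures <- list()
  for (cd in conditions) {
    res <- tryCatch(pfba(apply_condition(model, cd)), error = function(e) e)
    if (inherits(res, "error")) {
      status[cd$id] <- "failed"
      failures[[cd$id]] <- conditionMessage(res)
    } else {
      status[cd$id] <- res$status
      cols[[cd$id]] <- res$fluxes
    }
  }
  if (!length(cols)) stop("pFBA failed for every condition")
  flux_table(do.call(cbind, cols), status, failures)
}
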