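#' Construct an experimental condition
#'
#' A condition describes one strain/environment: an optional measured growth
#' rate, uptake-reaction bounds, gene knockouts and optional measured flux
#' bounds (e.g. from metabolic flux analysis).
#'
#' @param id condition identifier.
#' @param growth_rate non-negative growth rate (1/h) or `NA` if unmeasured.
#' @param uptake_bounds data.frame with columns `reaction`, `lb`, `ub`.
#' @param knockouts character vector of knocked-out gene ids.
#' @param measured_flux_bounds data.frame with columns `reaction`, `lb`, `ub`.
#' @return object of class `mpi_condition`.
#' @export
condition <- function(id, growth_rate = NA_real_,
                      uptake_bounds = empty_bounds(),
                      knockouts = character(),
                      measured_flux_bounds = empty_bounds()) {
  uptake_bounds <- as_bounds(uptake_bounds)
  measured_flux_bounds <- as_bounds(measured_flux_bounds)
  if (!length(growth_rate)) growth_rate <- NA_real_
  for (b in list(uptake_bounds, measured_flux_bounds))
    if (any(b$lb > b$ub)) stop("condition '", id, "': bound pair with lb > ub")
  if (!is.na(growth_rate) && growth_rate < 0)
    stop("condition '", id, "': negative growth rate")
  structure(list(id = as.character(id), growth_rate = as.numeric(growth_rate),
                 uptake_bounds = uptake_bounds,
                 knockouts = as.character(knockouts),
                 measured_flux_bounds = measured_flux_bounds),
            class = "mpi_condition")
}

empty_bounds <- function() {
  data.frame(reaction = character(), lb = numeric(), ub = numeric(),
             stringsAsFactors = FALSE)
}

as_bounds <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!nrow(x)) return(empty_bounds())
  stopifnot(all(c("reaction", "lb", "ub") %in% names(x)))
  x[, c("reaction", "lb", "ub")]
}

#' Read conditions from JSON or TSV
#'
#' JSON holds a list of condition records mirroring [condition()].  The TSV
#' dialect is long-format with columns `condition`, `growth_rate`,
#' `knockouts` (semicolon-separated), `bound_type` (`uptake` or `measured`,
#' empty on header rows), `reaction`, `lb`, `ub`: one header row per
#' condition plus one row per bound.
#'
#' @param path input path; format chosen by extension (`.json` vs `.tsv`).
#' @return list of `mpi_condition` objects.
#' @export
read_conditions <- function(path) {
  if (!file.exists(path)) stop("conditions file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path)
    return(lapply(doc, function(cd) {
      condition(cd$id,
                growth_rate = if (is.null(cd$growth_rate)) NA_real_ else cd$growth_rate,
                uptake_bounds = bounds_from_json(cd$uptake_bounds),
                knockouts = unlist(cd$knockouts) %||% character(),
                measured_flux_bounds = bounds_from_json(cd$measured_flux_bounds))
    }))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition", "growth_rate", "knockouts", "bound_type", "reaction", "lb", "ub")
  if (!all(need %in% names(tab)))
    stop("conditions TSV must have columns: ", paste(need, collapse = ", "))
  lapply(unique(tab$condition), function(id) {
    rows <- tab[tab$condition == id, ]
    hdr <- rows[!nzchar(ifelse(is.na(rows$bound_type), "", rows$bound_type)), ]
    if (nrow(hdr) != 1) stop("conditions TSV: expected one header row for '", id, "'")
    kos <- hdr$knockouts
    kos <- if (is.na(kos) || !nzchar(kos)) character() else strsplit(kos, ";")[[1]]
    take <- function(type) {
      b <- rows[!is.na(rows$bound_type) & rows$bound_type == type, c("reaction", "lb", "ub")]
      rownames(b) <- NULL
      b
    }
    condition(id, growth_rate = hdr$growth_rate, uptake_bounds = take("uptake"),
              knockouts = kos, measured_flux_bounds = take("measured"))
  })
}

bounds_from_json <- function(x) {
  if (is.null(x) || !length(x)) return(empty_bounds())
  data.frame(reaction = vapply(x, function(b) b$reaction, character(1)),
             lb = vapply(x, function(b) as.numeric(b$lb), numeric(1)),
             ub = vapply(x, function(b) as.numeric(b$ub), numeric(1)),
             stringsAsFactors = FALSE)
}

#' Write conditions to JSON
#' @param conditions list of `mpi_condition`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_conditions <- function(conditions, path) {
  doc <- lapply(conditions, function(cd) {
    list(id = cd$id,
         growth_rate = if (is.na(cd$growth_rate)) NULL else cd$growth_rate,
         uptake_bounds = bounds_to_json(cd$uptake_bounds),
         knockouts = as.list(cd$knockouts),
         measured_flux_bounds = bounds_to_json(cd$measured_flux_bounds))
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

bounds_to_json <- function(b) {
  lapply(seq_len(nrow(b)), function(i)
    list(reaction = b$reaction[i], lb = b$lb[i], ub = b$ub[i]))
}

# Shared TSV matrix layout: first column = row id, remaining columns = one
# per condition.  Used for protein abundance and flux tables alike.
read_matrix_tsv <- function(path, what = "row") {
  if (!file.exists(path)) stop(what, " table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2) stop("matrix TSV needs an id column plus >=1 condition column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  m
}

write_matrix_tsv <- function(m, path, id_name) {
  tab <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(tab)[1] <- id_name
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-abundance table (TSV: protein x condition)
#' @param path input path.
#' @return numeric matrix, proteins x conditions.
#' @export
read_abundance <- function(path) {
  m <- read_matrix_tsv(path, "abundance")
  if (any(m < 0, na.rm = TRUE)) stop("abundance table contains negative entries")
  m
}

#' Write a protein-abundance table
#' @param abundance matrix, proteins x conditions.
#' @param path output path.
#' @export
write_abundance <- function(abundance, path) write_matrix_tsv(abundance, path, "protein")

#' Read a flux table (TSV: reaction x condition), bypassing pFBA
#' @param path input path.
#' @return a `flux_table` (all statuses `"loaded"`).
#' @export
read_fluxes <- function(path) {
  m <- read_matrix_tsv(path, "flux")
  flux_table(m, setNames(rep("loaded", ncol(m)), colnames(m)))
}

#' Write a flux table
#' @param fluxes a `flux_table` or reaction x condition matrix.
#' @param path output path.
#' @export
write_fluxes <- function(fluxes, path) {
  m <- if (inherits(fluxes, "flux_table")) fluxes$values else fluxes
  write_matrix_tsv(m, path, "reaction")
}
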