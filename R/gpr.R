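#' Parse a gene-protein-reaction (GPR) rule
#'
#' Parses a boolean GPR expression over gene identifiers into OR-of-ANDs
#' normal form: a list of alternative enzyme units (isozymes), each unit a
#' character vector of gene ids that must all be present (a complex).  An
#' empty rule denotes a spontaneous reaction and yields an empty list.
#'
#' @param rule character scalar, e.g. `"(g1 and g2) or g3"`.  `and`/`or` are
#'   case-insensitive; `&`/`|` are accepted as synonyms.
#' @return list of character vectors (sorted, deduplicated), possibly empty.
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(rule) {
  stopifnot(is.character(rule), length(rule) == 1)
  if (is.na(rule) || !nzchar(trimws(rule))) return(list())

  # tokenize, keeping source positions for error messages
  pat <- "\\(|\\)|&{1,2}|\\|{1,2}|[^()&|[:space:]]+"
  m <- gregexpr(pat, rule)[[1]]
  if (m[1] == -1) stop("GPR syntax error: no tokens in rule")
  toks <- regmatches(rule, gregexpr(pat, rule))[[1]]
  pos <- as.integer(m)
  kind <- ifelse(toks == "(", "lpar",
          ifelse(toks == ")", "rpar",
          ifelse(tolower(toks) %in% c("and", "&", "&&"), "and",
          ifelse(tolower(toks) %in% c("or", "|", "||"), "or", "gene"))))

  i <- 0L
  peek <- function() if (i < length(toks)) kind[i + 1L] else "eof"
  advance <- function() { i <<- i + 1L; i }
  err <- function(what) {
    at <- if (i < length(toks)) pos[i + 1L] else nchar(rule) + 1L
    stop(sprintf("GPR syntax error at position %d: %s", at, what))
  }

  parse_expr <- function() {
    units <- parse_term()
    while (peek() == "or") {
      advance()
      units <- c(units, parse_term())
    }
    units
  }
  parse_term <- function() {
    units <- parse_factor()
    while (peek() == "and") {
      advance()
      rhs <- parse_factor()
      # distribute: AND of two OR-of-ANDs
      units <- unlist(lapply(units, function(u) {
        lapply(rhs, function(v) union(u, v))
      }), recursive = FALSE)
    }
    units
  }
  parse_factor <- function() {
    k <- peek()
    if (k == "gene") {
      g <- toks[advance()]
      list(g)
    } else if (k == "lpar") {
      advance()
      inner <- parse_expr()
      if (peek() != "rpar") err("expected ')'")
      advance()
      inner
    } else {
      err(sprintf("unexpected token '%s'", if (i < length(toks)) toks[i + 1L] else "<end>"))
    }
  }

  out <- parse_expr()
  if (i != length(toks)) err(sprintf("stray token '%s'", toks[i + 1L]))
  out <- lapply(out, function(u) sort(unique(u)))
  unique(out)
}

#' Genes appearing in a GPR rule
#' @param rule GPR string.
#' @return character vector of gene ids (possibly empty).
#' @export
gpr_genes <- function(rule) {
  sort(unique(unlist(parse_gpr(rule))))
}

# TRUE if the rule is satisfiable after removing knocked-out genes:
# at least one enzyme unit has no knocked-out member.  Empty rules
# (spontaneous reactions) are always satisfiable.
gpr_satisfied <- function(units, knockouts) {
  if (!length(units)) return(TRUE)
  any(vapply(units, function(u) !any(u %in% knockouts), logical(1)))
}
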