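#' @name gpr
#' @title Gene--protein--reaction (GPR) rules
#'
#' @description GPR rules are boolean expressions over gene ids
#' (`"g1 and (g2 or g3)"`). The package evaluates them over tri-state
#' expression levels (`low < moderate < high`) with the iMAT convention:
#' `and` takes the minimum state (a complex needs all subunits), `or` the
#' maximum (isoenzymes substitute for each other). An empty rule maps to
#' `moderate` (no evidence either way).
NULL

TRISTATE_LEVELS <- c("low", "moderate", "high")

# internal: validate a tri-state vector, return integer ranks 1..3
tristate_rank <- function(x) {
  r <- match(x, TRISTATE_LEVELS)
  if (anyNA(r)) {
    stop("invalid tri-state value(s): ",
         paste(unique(x[is.na(r)]), collapse = ", "))
  }
  r
}

# internal: tokenize a GPR string
gpr_tokenize <- function(gpr) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, gpr)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(gpr, list(m))[[1]]
}

#' Parse a GPR rule into an expression tree
#'
#' Recursive-descent parser for `and`/`or`/parentheses (case-insensitive;
#' `&`/`|` also accepted). `and` binds tighter than `or`.
#'
#' @param gpr GPR string; `""` or `NA` yields `NULL` (empty rule).
#' @return Nested list tree with nodes `list(op = "and"|"or", args = ...)`
#'   and leaves `list(op = "gene", id = <gene>)`, or `NULL`.
#' @export
parse_gpr <- function(gpr) {
  if (is.null(gpr) || is.na(gpr) || !nzchar(trimws(gpr))) return(NULL)
  tokens <- gpr_tokenize(gpr)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { t <- tokens[pos]; pos <<- pos + 1L; t }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) %in% kw

  parse_or <- function() {
    left <- parse_and()
    args <- list(left)
    while (is_kw(peek(), c("or", "|", "||"))) {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) left else list(op = "or", args = args)
  }
  parse_and <- function() {
    left <- parse_atom()
    args <- list(left)
    while (is_kw(peek(), c("and", "&", "&&"))) {
      advance()
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) left else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed GPR (unexpected end): ", gpr)
    if (t == "(") {
      advance()
      inner <- parse_or()
      if (!identical(peek(), ")")) stop("malformed GPR (missing ')'): ", gpr)
      advance()
      return(inner)
    }
    if (t == ")" || is_kw(t, c("and", "or", "&", "|", "&&", "||"))) {
      stop("malformed GPR (unexpected '", t, "'): ", gpr)
    }
    advance()
    list(op = "gene", id = t)
  }

  tree <- parse_or()
  if (pos <= length(tokens)) {
    stop("malformed GPR (trailing tokens): ", gpr)
  }
  tree
}

# internal: gene ids mentioned in a GPR string ("" -> character(0))
gpr_gene_ids <- function(gpr) {
  tree <- tryCatch(parse_gpr(gpr), error = function(e) NULL)
  collect <- function(node) {
    if (is.null(node)) return(character(0))
    if (node$op == "gene") return(node$id)
    unlist(lapply(node$args, collect))
  }
  unique(collect(tree))
}

#' Evaluate a GPR rule over tri-state gene levels
#'
#' @param gpr GPR string (or a tree from [parse_gpr()]).
#' @param gene_states named character vector / list mapping gene id to one of
#'   `"low"`, `"moderate"`, `"high"`.
#' @return One of `"low"`, `"moderate"`, `"high"`. Empty rules evaluate to
#'   `"moderate"`.
#' @examples
#' evaluate_gpr("g1 and g2", c(g1 = "high", g2 = "low"))   # "low"
#' evaluate_gpr("g1 or g2",  c(g1 = "high", g2 = "low"))   # "high"
#' @export
evaluate_gpr <- function(gpr, gene_states) {
  tree <- if (is.character(gpr) || is.null(gpr) ||
              (length(gpr) == 1 && is.na(gpr))) {
    parse_gpr(if (length(gpr)) gpr else "")
  } else {
    gpr
  }
  if (is.null(tree)) return("moderate")
  states <- unlist(gene_states)
  eval_node <- function(node) {
    if (node$op == "gene") {
      s <- if (node$id %in% names(states)) states[[node$id]] else NA
      if (is.null(s) || is.na(s)) {
        stop("gene without an expression state: ", node$id)
      }
      return(tristate_rank(s))
    }
    vals <- vapply(node$args, eval_node, numeric(1))
    if (node$op == "and") min(vals) else max(vals)
  }
  TRISTATE_LEVELS[eval_node(tree)]
}

#' Map a tri-state gene profile onto reactions
#'
#' Applies [evaluate_gpr()] to every reaction of the model. Reactions with no
#' GPR are `moderate`; genes missing from the profile default to `moderate`
#' (a warning reports how many).
#'
#' @param model a `metabolic_model`.
#' @param tristate_profile named character vector mapping gene id to
#'   `"low"`/`"moderate"`/`"high"`.
#' @return Named character vector over reaction ids.
#' @export
reaction_expression_states <- function(model, tristate_profile) {
  states <- unlist(tristate_profile)
  tristate_rank(states)  # validate values
  missing_genes <- setdiff(model$genes, names(states))
  if (length(missing_genes) > 0) {
    warning(length(missing_genes),
            " model gene(s) missing from the profile; defaulting to moderate")
    states <- c(states,
                stats::setNames(rep("moderate", length(missing_genes)),
                                missing_genes))
  }
  out <- vapply(model$reactions$gpr, function(g) evaluate_gpr(g, states),
                character(1), USE.NAMES = FALSE)
  stats::setNames(out, model$reactions$id)
}
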