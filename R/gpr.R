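#' Gene-protein-reaction (GPR) rules
#'
#' A GPR rule is a Boolean expression over gene identifiers that gates a
#' reaction: AND encodes enzyme subunits (all genes required), OR encodes
#' isoenzymes (any gene suffices). Rules are represented as expression trees
#' built from three node kinds: `literal` (a single gene), `and` and `or`
#' (each with two or more children).
#'
#' @name gpr
NULL

gpr_literal <- function(gene) {
  structure(list(op = "literal", gene = gene), class = "gpr_rule")
}

gpr_node <- function(op, args) {
  stopifnot(op %in% c("and", "or"), length(args) >= 2L)
  structure(list(op = op, args = args), class = "gpr_rule")
}

#' Parse a GPR string into a rule tree
#'
#' Grammar: `expr := term (OR term)*`, `term := factor (AND factor)*`,
#' `factor := gene | "(" expr ")"`. AND binds tighter than OR; parentheses
#' override precedence. Operators are case-insensitive; `&`/`&&` and `|`/`||`
#' are accepted as synonyms. Gene identifiers are any whitespace/parenthesis
#' delimited tokens that are not operators.
#'
#' @param text GPR string, e.g. `"(g1 and g2) or g3"`. An empty or
#'   all-whitespace string yields `NULL` (no rule: reaction always active).
#' @return A `gpr_rule` tree, or `NULL` for an empty string.
#' @examples
#' parse_gpr("g1 AND g2")
#' parse_gpr("g1 or g2 and g3")  # or(g1, and(g2, g3))
#' @export
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- gpr_tokenize(text)
  if (nrow(toks) == 0L) return(NULL)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  rule <- gpr_parse_expr(st)
  if (st$pos <= nrow(st$toks)) {
    stop(sprintf("GPR parse error at position %d: unexpected '%s'",
                 st$toks$at[st$pos], st$toks$text[st$pos]), call. = FALSE)
  }
  rule
}

gpr_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  toks <- list(); texts <- character(); ats <- integer()
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      texts <- c(texts, ch); ats <- c(ats, i); i <- i + 1L; next
    }
    j <- i
    while (j <= n && !grepl("^[[:space:]]$", chars[j]) &&
           !(chars[j] %in% c("(", ")"))) j <- j + 1L
    texts <- c(texts, paste0(chars[i:(j - 1L)], collapse = ""))
    ats <- c(ats, i)
    i <- j
  }
  type <- rep("gene", length(texts))
  lowered <- tolower(texts)
  type[lowered %in% c("and", "&", "&&")] <- "and"
  type[lowered %in% c("or", "|", "||")] <- "or"
  type[texts == "("] <- "lpar"
  type[texts == ")"] <- "rpar"
  data.frame(text = texts, type = type, at = ats, stringsAsFactors = FALSE)
}

gpr_peek <- function(st) {
  if (st$pos > nrow(st$toks)) NULL else st$toks[st$pos, ]
}

gpr_parse_expr <- function(st) {
  args <- list(gpr_parse_term(st))
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "or") break
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_term(st)))
  }
  if (length(args) == 1L) args[[1]] else gpr_node("or", args)
}

gpr_parse_term <- function(st) {
  args <- list(gpr_parse_factor(st))
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "and") break
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_factor(st)))
  }
  if (length(args) == 1L) args[[1]] else gpr_node("and", args)
}

gpr_parse_factor <- function(st) {
  tk <- gpr_peek(st)
  if (is.null(tk)) {
    stop("GPR parse error: unexpected end of input (dangling operator?)",
         call. = FALSE)
  }
  if (tk$type == "lpar") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_expr(st)
    tk2 <- gpr_peek(st)
    if (is.null(tk2) || tk2$type != "rpar") {
      stop(sprintf("GPR parse error at position %d: unbalanced '('", tk$at),
           call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk$type == "gene") {
    st$pos <- st$pos + 1L
    return(gpr_literal(tk$text))
  }
  stop(sprintf("GPR parse error at position %d: unexpected '%s'",
               tk$at, tk$text), call. = FALSE)
}

#' Evaluate a GPR rule under a gene state assignment
#'
#' @param rule A `gpr_rule` (or `NULL`, which is always active).
#' @param states Named logical or 0/1 vector giving each gene's state
#'   (1/`TRUE` = present, 0/`FALSE` = knocked out). Every gene appearing in
#'   the rule must be named; a missing gene is an error naming it.
#' @return `TRUE` if the reaction is active, `FALSE` otherwise.
#' @examples
#' evaluate_gpr(parse_gpr("g1 and g2"), c(g1 = 1, g2 = 0))  # FALSE
#' evaluate_gpr(parse_gpr("g1 or g2"), c(g1 = 0, g2 = 1))   # TRUE
#' @export
evaluate_gpr <- function(rule, states) {
  if (is.null(rule)) return(TRUE)
  stopifnot(inherits(rule, "gpr_rule"))
  switch(rule$op,
    literal = {
      if (!(rule$gene %in% names(states))) {
        stop(sprintf("no state given for gene '%s'", rule$gene), call. = FALSE)
      }
      as.logical(states[[rule$gene]])
    },
    and = all(vapply(rule$args, evaluate_gpr, logical(1), states = states)),
    or  = any(vapply(rule$args, evaluate_gpr, logical(1), states = states))
  )
}

#' Genes referenced by a GPR rule
#' @param rule A `gpr_rule` or `NULL`.
#' @return Character vector of unique gene identifiers (empty for `NULL`).
#' @export
gpr_genes <- function(rule) {
  if (is.null(rule)) return(character())
  if (rule$op == "literal") return(rule$gene)
  unique(unlist(lapply(rule$args, gpr_genes)))
}

#' Render a GPR rule back to a string
#' @param rule A `gpr_rule` or `NULL`.
#' @return GPR string (`""` for `NULL`); parsing it back yields an
#'   equivalent tree.
#' @export
format_gpr <- function(rule) {
  if (is.null(rule)) return("")
  fmt <- function(r, parent_op) {
    if (r$op == "literal") return(r$gene)
    sep <- if (r$op == "and") " and " else " or "
    s <- paste(vapply(r$args, fmt, character(1), parent_op = r$op),
               collapse = sep)
    # parenthesize an OR nested under an AND (and any nested same-op groups
    # are flattened by precedence anyway)
    if (r$op == "or" && identical(parent_op, "and")) s <- paste0("(", s, ")")
    s
  }
  fmt(rule, NA_character_)
}

#' @export
print.gpr_rule <- function(x, ...) {
  cat("<gpr_rule> ", format_gpr(x), "\n", sep = "")
  invisible(x)
}
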