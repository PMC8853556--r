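#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers in which
#' \code{and} joins subunits of a complex (all required) and \code{or}
#' joins isoenzymes (any sufficient). \code{and} binds tighter than
#' \code{or}, as in standard boolean precedence; parentheses override.
#' Gene tokens are any run of characters other than whitespace and
#' parentheses, so both gene symbols and numeric ids are accepted.
#'
#' The returned tree is a nested list: a leaf is a length-one character
#' vector (the gene id); an internal node is
#' \code{list(op = "and"|"or", children = list(...))} with at least two
#' children.
#'
#' @param text the rule, e.g. \code{"A and (B or C)"}. Operator keywords
#'   are case-insensitive.
#' @return the parsed tree, or \code{NULL} for empty/whitespace input.
#' @examples
#' parseGPR("GAPDH")
#' parseGPR("A and B or C")   # or(and(A, B), C)
#' @export
parseGPR <- function(text) {
    if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
    toks <- .gprTokenize(text)
    st <- new.env(parent = emptyenv())
    st$toks <- toks
    st$pos <- 1L
    expr <- .gprParseOr(st, text)
    if (st$pos <= nrow(st$toks))
        stop(sprintf("GPR syntax error: unexpected '%s' at position %d in \"%s\"",
                     st$toks$value[st$pos], st$toks$at[st$pos], text),
             call. = FALSE)
    expr
}

.gprTokenize <- function(text) {
    chars <- strsplit(text, "", fixed = TRUE)[[1]]
    vals <- character(); types <- character(); ats <- integer()
    i <- 1L; n <- length(chars)
    while (i <= n) {
        ch <- chars[i]
        if (grepl("^\\s$", ch)) { i <- i + 1L; next }
        if (ch %in% c("(", ")")) {
            vals <- c(vals, ch); types <- c(types, ch); ats <- c(ats, i)
            i <- i + 1L; next
        }
        j <- i
        while (j <= n && !grepl("^\\s$", chars[j]) && !chars[j] %in% c("(", ")"))
            j <- j + 1L
        word <- paste(chars[i:(j - 1L)], collapse = "")
        lw <- tolower(word)
        types <- c(types, if (lw %in% c("and", "or")) lw else "gene")
        vals <- c(vals, word); ats <- c(ats, i)
        i <- j
    }
    data.frame(value = vals, type = types, at = ats, stringsAsFactors = FALSE)
}

.gprPeek <- function(st) if (st$pos <= nrow(st$toks)) st$toks$type[st$pos] else NA_character_

.gprParseOr <- function(st, text) {
    kids <- list(.gprParseAnd(st, text))
    while (identical(.gprPeek(st), "or")) {
        st$pos <- st$pos + 1L
        kids <- c(kids, list(.gprParseAnd(st, text)))
    }
    if (length(kids) == 1L) kids[[1]] else list(op = "or", children = kids)
}

.gprParseAnd <- function(st, text) {
    kids <- list(.gprParsePrimary(st, text))
    while (identical(.gprPeek(st), "and")) {
        st$pos <- st$pos + 1L
        kids <- c(kids, list(.gprParsePrimary(st, text)))
    }
    if (length(kids) == 1L) kids[[1]] else list(op = "and", children = kids)
}

.gprParsePrimary <- function(st, text) {
    tp <- .gprPeek(st)
    if (is.na(tp))
        stop(sprintf("GPR syntax error: unexpected end of rule \"%s\"", text),
             call. = FALSE)
    tok <- st$toks[st$pos, ]
    if (tp == "gene") { st$pos <- st$pos + 1L; return(tok$value) }
    if (tp == "(") {
        st$pos <- st$pos + 1L
        inner <- .gprParseOr(st, text)
        if (!identical(.gprPeek(st), ")"))
            stop(sprintf("GPR syntax error: unbalanced '(' opened at position %d in \"%s\"",
                         tok$at, text), call. = FALSE)
        st$pos <- st$pos + 1L
        return(inner)
    }
    stop(sprintf("GPR syntax error: dangling operator '%s' at position %d in \"%s\"",
                 tok$value, tok$at, text), call. = FALSE)
}

.gprIsLeaf <- function(expr) is.character(expr)

#' Serialize a GPR tree back to rule text
#'
#' Produces a fully parenthesized, lower-case-operator form;
#' \code{parseGPR(gprToString(x))} reproduces \code{x}.
#'
#' @param expr a tree from \code{\link{parseGPR}}.
#' @return a character string, or \code{NA} for \code{NULL}.
#' @export
gprToString <- function(expr) {
    if (is.null(expr)) return(NA_character_)
    if (.gprIsLeaf(expr)) return(expr)
    inner <- vapply(expr$children, function(ch) {
        s <- gprToString(ch)
        if (.gprIsLeaf(ch)) s else paste0("(", s, ")")
    }, character(1))
    paste(inner, collapse = paste0(" ", expr$op, " "))
}

#' Genes referenced by a GPR tree
#' @param expr a tree from \code{\link{parseGPR}} (or \code{NULL}).
#' @return character vector of unique gene ids.
#' @export
gprGenes <- function(expr) {
    if (is.null(expr)) return(character())
    if (.gprIsLeaf(expr)) return(expr)
    unique(unlist(lapply(expr$children, gprGenes)))
}

#' Evaluate a GPR rule on gene expression values
#'
#' Resolves a GPR tree to a reaction activity value: \code{and} nodes
#' (subunits, all required) take the minimum of their children and
#' \code{or} nodes (isoenzymes, additive) take the sum, recursively.
#'
#' Genes absent from \code{geneValues} are handled by \code{missingPolicy}:
#' \describe{
#'   \item{\code{"skip"}}{(default) a missing term under \code{or} is
#'     dropped; a missing operand under \code{and} makes the whole score
#'     undefined (\code{NA}), so the reaction can fall back to the
#'     rule-free path.}
#'   \item{\code{"zero"}}{missing genes count as expression 0.}
#'   \item{\code{"undefined"}}{any missing gene makes the score \code{NA}.}
#' }
#'
#' @param expr parsed tree, see \code{\link{parseGPR}}.
#' @param geneValues named non-negative numeric vector of expression values.
#' @param missingPolicy one of \code{"skip"}, \code{"zero"}, \code{"undefined"}.
#' @return a single non-negative value, or \code{NA} if undefined.
#' @examples
#' evaluateGPR(parseGPR("A and B"), c(A = 5, B = 3))          # 3
#' evaluateGPR(parseGPR("A or B"), c(A = 5, B = 3))           # 8
#' evaluateGPR(parseGPR("(A and B) or C"), c(A = 2, B = 4, C = 1))  # 3
#' @export
evaluateGPR <- function(expr, geneValues,
                        missingPolicy = c("skip", "zero", "undefined")) {
    missingPolicy <- match.arg(missingPolicy)
    if (is.null(expr)) return(NA_real_)
    if (any(geneValues < 0, na.rm = TRUE))
        stop("gene expression values must be non-negative")
    .gprEval(expr, geneValues, missingPolicy)
}

.gprEval <- function(expr, vals, policy) {
    if (.gprIsLeaf(expr)) {
        if (expr %in% names(vals)) return(unname(vals[[expr]]))
        return(if (policy == "zero") 0 else NA_real_)
    }
    kids <- vapply(expr$children, .gprEval, numeric(1),
                   vals = vals, policy = policy)
    if (expr$op == "and") {
        if (anyNA(kids)) return(NA_real_)  # a required subunit is unquantified
        return(min(kids))
    }
    # or: isoforms are additive
    if (policy == "skip") {
        kids <- kids[!is.na(kids)]
        if (!length(kids)) return(NA_real_)
        return(sum(kids))
    }
    if (anyNA(kids)) return(NA_real_)
    sum(kids)
}
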