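#' Construct a ScoreTable
#'
#' @param scores reaction-by-sample numeric matrix.
#' @param groups group (cell line) label per sample column.
#' @param scoreType \code{"RAS"} or \code{"RPS"}.
#' @param rowData optional per-reaction annotation.
#' @return a \linkS4class{ScoreTable}.
#' @export
ScoreTable <- function(scores, groups, scoreType = c("RAS", "RPS"),
                       rowData = NULL) {
    scoreType <- match.arg(scoreType)
    stopifnot(ncol(scores) == length(groups))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(score = scores),
        colData = S4Vectors::DataFrame(group = as.character(groups),
                                       row.names = colnames(scores)))
    if (!is.null(rowData)) SummarizedExperiment::rowData(se) <- rowData
    methods::new("ScoreTable", se, scoreType = scoreType)
}

#' @rdname ScoreTable-class
#' @param object a \code{ScoreTable}.
#' @export
setMethod("scoreType", "ScoreTable", function(object) object@scoreType)

#' @rdname ScoreTable-class
#' @export
setMethod("scoreGroups", "ScoreTable", function(object)
    as.character(SummarizedExperiment::colData(object)$group))

#' @rdname ScoreTable-class
#' @details \code{groupMeans} averages the per-sample scores within each
#'   group, giving the per-group reaction score; \code{NA} sample scores
#'   (undefined rules) propagate to an \code{NA} mean.
#' @export
setMethod("groupMeans", "ScoreTable", function(object) {
    sc <- SummarizedExperiment::assay(object, "score")
    grp <- scoreGroups(object)
    lv <- sort(unique(grp))
    out <- vapply(lv, function(g)
        rowMeans(sc[, grp == g, drop = FALSE]), numeric(nrow(sc)))
    out <- matrix(out, nrow = nrow(sc),
                  dimnames = list(rownames(sc), lv))
    out
})

setMethod("show", "ScoreTable", function(object) {
    cat(sprintf("%s ScoreTable: %d reactions x %d samples (%d groups)\n",
                object@scoreType, nrow(object), ncol(object),
                length(unique(scoreGroups(object)))))
    invisible(object)
})

#' Compute per-sample Reaction Activity Scores
#'
#' For every reaction carrying a GPR rule, the rule is evaluated on each
#' sample's expression profile: complexes (\code{and}) score the minimum
#' of their subunits, isoenzymes (\code{or}) the sum. The per-group score
#' is the mean over that group's samples. Reactions without a GPR — and
#' reactions whose rule is undefined on the data under the missing-gene
#' policy — carry the sentinel score 1 in every sample, so that their
#' relative bounds are never tightened downstream.
#'
#' @param model a \linkS4class{MetabolicModel} with parsed GPRs.
#' @param expression gene-by-sample matrix of non-negative expression
#'   values (FPKM or counts; any consistent non-negative unit).
#' @param groups group label per sample column.
#' @param missingPolicy passed to \code{\link{evaluateGPR}}.
#' @return a \linkS4class{ScoreTable} (type RAS) over all model reactions,
#'   with a logical \code{hasGPR} column in \code{rowData} marking rows
#'   whose score is expression-derived rather than the sentinel.
#' @export
computeRAS <- function(model, expression, groups,
                       missingPolicy = "skip") {
    stopifnot(methods::is(model, "MetabolicModel"))
    expression <- as.matrix(expression)
    if (any(expression < 0, na.rm = TRUE))
        stop("expression values must be non-negative")
    if (ncol(expression) != length(groups))
        stop("one group label per expression column is required")
    if (anyDuplicated(rownames(expression)))
        stop("gene ids must be unique")
    if (!all(table(groups) >= 1L)) stop("each group needs at least 1 sample")

    rxIds <- reactionIds(model)
    out <- matrix(NA_real_, nrow = length(rxIds), ncol = ncol(expression),
                  dimnames = list(rxIds, colnames(expression)))
    hasGPR <- logical(length(rxIds))
    for (i in seq_along(rxIds)) {
        tree <- model@gprs[[i]]
        if (is.null(tree)) { out[i, ] <- 1; next }
        vals <- vapply(seq_len(ncol(expression)), function(j)
            evaluateGPR(tree,
                        stats::setNames(expression[, j], rownames(expression)),
                        missingPolicy), numeric(1))
        if (anyNA(vals)) {
            # rule undefined on this dataset: fall back to the rule-free path
            out[i, ] <- 1
        } else {
            out[i, ] <- vals
            hasGPR[i] <- TRUE
        }
    }
    ScoreTable(out, groups, "RAS",
               rowData = S4Vectors::DataFrame(hasGPR = hasGPR,
                                              row.names = rxIds))
}

#' Cross-group normalized RAS
#'
#' Normalizes each reaction's per-group mean RAS by the maximum across
#' groups, giving values in [0, 1]; the best-expressed group scores 1 and
#' retains full flux capability under the transcriptomic bounds. If a
#' reaction's RAS is 0 in every group, the normalized scores stay 0.
#'
#' @param object a RAS \linkS4class{ScoreTable}.
#' @return reaction-by-group matrix of normalized scores.
#' @export
setMethod("normalizedScores", "ScoreTable", function(object) {
    if (object@scoreType != "RAS")
        stop("normalizedScores is defined for RAS tables")
    m <- groupMeans(object)
    mx <- apply(m, 1, max)
    norm <- m / ifelse(mx > 0, mx, 1)  # all-zero rows stay 0
    norm
})

#' @rdname normalizeRAS
#' @name normalizeRAS
#' @title Normalize group-mean RAS across groups
#' @description Alias interface: \code{normalizeRAS(tab)} is
#'   \code{normalizedScores(tab)}.
#' @param object a RAS \code{ScoreTable}.
#' @export
normalizeRAS <- function(object) normalizedScores(object)
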