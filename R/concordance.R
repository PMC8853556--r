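#' Call the sign of variation between two groups
#'
#' A \code{+1} is called when the first group's values are statistically
#' higher (test p-value below \code{alpha}) \emph{and} the central value is
#' at least 20\% higher (ratio \eqn{\ge} \code{foldUp}); \code{-1}
#' symmetrically for at least 20\% lower (ratio \eqn{\le}
#' \code{foldDown}); \code{0} otherwise. Sampled flux distributions
#' (\code{mode = "distribution"}) use the Mann-Whitney U test and compare
#' medians; per-sample omics scores (\code{mode = "samples"}) use Welch's
#' t-test and compare means. Flux distributions larger than
#' \code{maxN} per group are thinned deterministically (evenly spaced
#' subsample) before testing, since rank-test p-values at very large n
#' reject for meaningless differences.
#'
#' @param a,b numeric value vectors for the two groups (a vs b).
#' @param mode \code{"samples"} or \code{"distribution"}.
#' @param alpha significance level (default 0.05).
#' @param foldUp,foldDown fold-change thresholds (defaults 1.2 and 0.8).
#' @param maxN per-group subsample cap in distribution mode.
#' @param varEqual pooled-variance t-test (default). At the typical three
#'   samples per group, Welch's correction collapses the degrees of
#'   freedom whenever variance scales with the mean and loses most of its
#'   power; set \code{FALSE} for Welch.
#' @return integer in \{-1, 0, +1\}.
#' @export
variationSign <- function(a, b, mode = c("samples", "distribution"),
                          alpha = 0.05, foldUp = 1.2, foldDown = 0.8,
                          maxN = 10000L, varEqual = TRUE) {
    mode <- match.arg(mode)
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (mode == "samples") {
        if (length(a) < 2L || length(b) < 2L) {
            warning("fewer than 2 values in a group; sign test undefined, ",
                    "returning 0")
            return(0L)
        }
        central <- c(mean(a), mean(b))
        p <- .safeTTest(a, b, varEqual)
    } else {
        if (!length(a) || !length(b)) return(0L)
        a <- .evenSubsample(a, maxN); b <- .evenSubsample(b, maxN)
        central <- c(stats::median(a), stats::median(b))
        p <- .safeUTest(a, b)
    }
    ratio <- if (central[2] > 0) central[1] / central[2]
             else if (central[1] > 0) Inf else 1
    if (p < alpha && ratio >= foldUp) return(1L)
    if (p < alpha && ratio <= foldDown) return(-1L)
    0L
}

.evenSubsample <- function(x, maxN) {
    if (length(x) <= maxN) return(x)
    x[round(seq(1L, length(x), length.out = maxN))]
}

.safeTTest <- function(a, b, varEqual = TRUE) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
        return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    tryCatch(stats::t.test(a, b, var.equal = varEqual)$p.value,
             error = function(e) 1)
}

.safeUTest <- function(a, b) {
    if (length(unique(c(a, b))) == 1L) return(1)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
}

#' Ordered group pairs
#'
#' Lexicographic pair enumeration shared by all sign matrices, so that
#' sign vectors from different datasets align: for groups A < B < C the
#' pairs are A|B, A|C, B|C.
#'
#' @param groups character vector of group labels.
#' @return data.frame with columns \code{a}, \code{b}, \code{label}.
#' @export
orderedGroupPairs <- function(groups) {
    g <- sort(unique(as.character(groups)))
    if (length(g) < 2L) stop("at least 2 groups are required")
    cmb <- utils::combn(g, 2)
    data.frame(a = cmb[1, ], b = cmb[2, ],
               label = paste(cmb[1, ], cmb[2, ], sep = "|"),
               stringsAsFactors = FALSE)
}

#' Pairwise variation-sign matrix for a dataset
#'
#' Applies \code{\link{variationSign}} to every reaction and every ordered
#' group pair of a score table (RAS/RPS; per-sample mode) or a list of
#' per-group flux sample sets (FFD; distribution mode).
#'
#' @param dataset a \linkS4class{ScoreTable}, or a named list of
#'   \linkS4class{FluxSampleSet} (names are group labels).
#' @param reactions optional reaction subset (default: all rows shared by
#'   the dataset).
#' @param batch optional single batch index: for FFD data, restrict to
#'   that sampling batch (used for batch-stability checks).
#' @param ... passed to \code{\link{variationSign}}.
#' @return a \linkS4class{SignMatrix}.
#' @export
pairwiseSignMatrix <- function(dataset, reactions = NULL, batch = NULL, ...) {
    if (methods::is(dataset, "ScoreTable")) {
        sc <- SummarizedExperiment::assay(dataset, "score")
        grp <- scoreGroups(dataset)
        getVals <- function(r, g) sc[r, grp == g]
        rxAll <- rownames(sc)
        groups <- sort(unique(grp))
        tag <- scoreType(dataset)
        mode <- "samples"
    } else if (is.list(dataset) &&
               all(vapply(dataset, methods::is, logical(1), "FluxSampleSet"))) {
        groups <- sort(names(dataset))
        rxAll <- Reduce(intersect, lapply(dataset, function(x)
            rownames(fluxes(x))))
        getVals <- function(r, g) {
            fs <- dataset[[g]]
            v <- fluxes(fs)[r, ]
            if (!is.null(batch)) v <- v[sampleBatches(fs) == batch]
            v
        }
        tag <- "FFD"
        mode <- "distribution"
    } else stop("dataset must be a ScoreTable or a list of FluxSampleSet")
    if (is.null(reactions)) reactions <- rxAll
    miss <- setdiff(reactions, rxAll)
    if (length(miss))
        stop("reactions absent from dataset: ", paste(miss, collapse = ", "))
    pairs <- orderedGroupPairs(groups)
    sig <- matrix(0L, nrow = length(reactions), ncol = nrow(pairs),
                  dimnames = list(reactions, pairs$label))
    for (r in reactions)
        for (k in seq_len(nrow(pairs)))
            sig[r, k] <- variationSign(getVals(r, pairs$a[k]),
                                       getVals(r, pairs$b[k]),
                                       mode = mode, ...)
    methods::new("SignMatrix", dataset = tag, signs = sig, groups = groups)
}

#' @rdname SignMatrix-class
#' @param object a \code{SignMatrix}.
#' @export
setMethod("signValues", "SignMatrix", function(object) object@signs)

#' @rdname SignMatrix-class
#' @export
setMethod("groupPairs", "SignMatrix", function(object)
    colnames(object@signs))

setMethod("show", "SignMatrix", function(object) {
    cat(sprintf("SignMatrix [%s]: %d reactions x %d group pairs\n",
                object@dataset, nrow(object@signs), ncol(object@signs)))
    invisible(object)
})

#' Cohen's kappa between two sign vectors
#'
#' Chance-corrected agreement between two categorical raters over the
#' categories \{-1, 0, +1\}: \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' \eqn{p_o} the observed agreement fraction and \eqn{p_e} the chance
#' agreement implied by the two marginal category distributions. Fully
#' concordant non-constant vectors give 1; vectors making opposite
#' judgments in every case (two categories, balanced marginals) give -1.
#' Degenerate cases: both vectors constant and equal gives 1, constant and
#' different gives -1; any other chance-saturated margin gives 0.
#'
#' @param a,b equal-length vectors with entries in \{-1, 0, +1\}.
#' @return kappa in [-1, 1].
#' @examples
#' cohensKappa(c(1, 1, 0, -1), c(1, 0, 0, -1))  # 0.636...
#' @export
cohensKappa <- function(a, b) {
    if (!length(a) || length(a) != length(b))
        stop("sign vectors must be non-empty and of equal length")
    if (length(unique(a)) == 1L && length(unique(b)) == 1L)
        return(if (a[1] == b[1]) 1 else -1)
    po <- mean(a == b)
    cats <- c(-1, 0, 1)
    pa <- vapply(cats, function(k) mean(a == k), numeric(1))
    pb <- vapply(cats, function(k) mean(b == k), numeric(1))
    pe <- sum(pa * pb)
    if (pe >= 1 - 1e-12) return(0)  # chance-saturated margins, non-constant
    (po - pe) / (1 - pe)
}

#' Empirical null p-values for RPS-vs-FFD concordance
#'
#' Builds the empirical probability of agreement between two independent
#' datasets: the pooled distribution of RPS sign-test outcomes
#' (\code{-1}, \code{0}, \code{+1}) is resampled with replacement into
#' random pair-length sign vectors — resampling test outcomes rather than
#' raw scores avoids over-representing zeros — and each resample is scored
#' with Cohen's kappa against every reaction's observed FFD sign vector.
#' The p-value is the add-one-corrected fraction of null kappas at least
#' as large as the observed kappa.
#'
#' @param rpsSigns,ffdSigns \linkS4class{SignMatrix} objects sharing the
#'   pair ordering.
#' @param observed named numeric vector of observed RPS-vs-FFD kappas (one
#'   per reaction, names = reaction ids present in \code{ffdSigns}).
#' @param nResamples number of resampled sign vectors (default 1000).
#' @param seed RNG seed.
#' @param pooling \code{"pooled"} (default) draws from all reactions'
#'   pooled RPS sign calls; \code{"perReaction"} draws from each
#'   reaction's own calls.
#' @return named numeric vector of p-values.
#' @export
empiricalNullPvalues <- function(rpsSigns, ffdSigns, observed,
                                 nResamples = 1000L, seed = 1L,
                                 pooling = c("pooled", "perReaction")) {
    pooling <- match.arg(pooling)
    stopifnot(identical(groupPairs(rpsSigns), groupPairs(ffdSigns)))
    rpsPool <- as.vector(signValues(rpsSigns))
    if (!length(rpsPool)) stop("empty RPS sign matrix")
    nPairs <- ncol(signValues(ffdSigns))
    ffd <- signValues(ffdSigns)
    reactions <- names(observed)
    stopifnot(all(reactions %in% rownames(ffd)))
    set.seed(as.integer(seed))
    nullDraws <- matrix(
        if (pooling == "pooled")
            sample(rpsPool, nResamples * nPairs, replace = TRUE)
        else NA_integer_,
        nrow = nResamples, ncol = nPairs)
    p <- stats::setNames(numeric(length(reactions)), reactions)
    for (r in reactions) {
        if (pooling == "perReaction") {
            own <- signValues(rpsSigns)[r, ]
            nullDraws <- matrix(sample(own, nResamples * nPairs,
                                       replace = TRUE),
                                nrow = nResamples, ncol = nPairs)
        }
        nullK <- apply(nullDraws, 1, cohensKappa, b = ffd[r, ])
        p[r] <- (1 + sum(nullK >= observed[[r]])) / (1 + nResamples)
    }
    p
}

#' Kappa stability across sampling batches
#'
#' Recomputes the RPS-vs-FFD kappa per sampling batch (each batch is an
#' independent chain) and reports the per-reaction standard deviation — a
#' cheap convergence diagnostic: a kappa that swings between batches is
#' not supported by the sample size.
#'
#' @param rpsSigns \linkS4class{SignMatrix} of RPS calls.
#' @param ffdSets named list of \linkS4class{FluxSampleSet} per group.
#' @param reactions reaction ids to assess.
#' @param ... sign-calling parameters passed to
#'   \code{\link{pairwiseSignMatrix}}.
#' @return named numeric vector of standard deviations (NA where a batch
#'   pair carried no called variation).
#' @export
kappaBatchSd <- function(rpsSigns, ffdSets, reactions = NULL, ...) {
    nBatches <- min(vapply(ffdSets, function(x) x@nBatches, integer(1)))
    rps <- signValues(rpsSigns)
    if (is.null(reactions)) reactions <- rownames(rps)
    perBatch <- vapply(seq_len(nBatches), function(b) {
        ffdB <- signValues(pairwiseSignMatrix(ffdSets, batch = b, ...))
        vapply(reactions, function(r)
            cohensKappa(rps[r, ], ffdB[r, ]), numeric(1))
    }, numeric(length(reactions)))
    perBatch <- matrix(perBatch, nrow = length(reactions),
                       dimnames = list(reactions, NULL))
    apply(perBatch, 1, stats::sd)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1); thin
#' wrapper over \code{stats::p.adjust}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order and names.
#' @export
bhAdjust <- function(p) {
    stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
    stats::p.adjust(p, method = "BH")
}

#' Classify reactions by regulatory quadrant
#'
#' Maps the kappa scores to the quadrant semantics of the concordance
#' scatter: both RPS-vs-FFD and RPS-vs-RAS above the threshold means
#' \emph{concerted} transcriptional and metabolic regulation; RPS-vs-FFD
#' above with RPS-vs-RAS below (or missing, for rule-free reactions) means
#' \emph{metabolic control only}; RPS-vs-FFD below the threshold with a
#' high RAS-vs-FFD concordance means \emph{transcriptional control only};
#' RPS-vs-RAS above with RPS-vs-FFD below is \emph{other} (expression and
#' substrate agree but the flux follows neither); anything else is
#' \emph{inconclusive}.
#'
#' @param kRpsFfd,kRpsRas,kRasFfd kappa vectors (NA allowed for missing
#'   RPS-vs-RAS).
#' @param threshold concordance threshold (default 0.2).
#' @return character vector of class labels.
#' @export
classifyReactions <- function(kRpsFfd, kRpsRas, kRasFfd, threshold = 0.2) {
    n <- length(kRpsFfd)
    out <- character(n)
    for (i in seq_len(n)) {
        rf <- kRpsFfd[i]; rr <- kRpsRas[i]; af <- kRasFfd[i]
        out[i] <- if (!is.na(rf) && rf > threshold) {
            if (!is.na(rr) && rr > threshold) "concerted" else "metabolic_only"
        } else if (!is.na(rr) && rr > threshold) {
            "other"
        } else if (!is.na(af) && af > threshold) {
            "transcriptional_only"
        } else "inconclusive"
    }
    out
}

#' Full concordance analysis
#'
#' Computes, per reaction, Cohen's kappa between the RPS and FFD sign
#' vectors, the RPS and RAS sign vectors (only for reactions with a usable
#' GPR), and RAS vs FFD (reported for context; it never drives
#' significance, the two datasets not being independent). Empirical null
#' p-values for RPS-vs-FFD are attached with
#' \code{\link{empiricalNullPvalues}}, BH-adjusted, and the quadrant class
#' is assigned.
#'
#' @param rasSigns,rpsSigns,ffdSigns \linkS4class{SignMatrix} objects with
#'   identical pair ordering; analysis covers reactions present in both
#'   \code{rpsSigns} and \code{ffdSigns}.
#' @param rasEligible reaction ids whose RAS is expression-derived (others
#'   get NA RPS-vs-RAS/RAS-vs-FFD); default all RAS rows.
#' @param threshold classification threshold (default 0.2).
#' @param nResamples,seed,pooling see \code{\link{empiricalNullPvalues}}.
#' @return a \linkS4class{ConcordanceResult}.
#' @export
concordanceAnalysis <- function(rasSigns, rpsSigns, ffdSigns,
                                rasEligible = NULL, threshold = 0.2,
                                nResamples = 1000L, seed = 1L,
                                pooling = "pooled") {
    stopifnot(identical(groupPairs(rpsSigns), groupPairs(ffdSigns)),
              identical(groupPairs(rasSigns), groupPairs(ffdSigns)))
    rps <- signValues(rpsSigns); ffd <- signValues(ffdSigns)
    ras <- signValues(rasSigns)
    reactions <- intersect(rownames(rps), rownames(ffd))
    if (!length(reactions)) stop("no reactions shared between RPS and FFD")
    if (is.null(rasEligible)) rasEligible <- rownames(ras)

    kRF <- kRR <- kAF <- stats::setNames(rep(NA_real_, length(reactions)),
                                         reactions)
    # two all-zero sign vectors mean no variation was called on either
    # side: there is no concordance evidence, not perfect concordance
    kap <- function(x, y)
        if (all(x == 0L) && all(y == 0L)) NA_real_ else cohensKappa(x, y)
    for (r in reactions) {
        kRF[r] <- kap(rps[r, ], ffd[r, ])
        if (r %in% rownames(ras) && r %in% rasEligible) {
            kRR[r] <- kap(rps[r, ], ras[r, ])
            kAF[r] <- kap(ras[r, ], ffd[r, ])
        }
    }
    pEmp <- empiricalNullPvalues(rpsSigns, ffdSigns, kRF,
                                 nResamples = nResamples, seed = seed,
                                 pooling = pooling)
    pAdj <- bhAdjust(pEmp)
    cls <- classifyReactions(kRF, kRR, kAF, threshold)
    tb <- S4Vectors::DataFrame(
        reaction = reactions, kappaRpsVsFfd = unname(kRF),
        kappaRpsVsRas = unname(kRR), kappaRasVsFfd = unname(kAF),
        pEmpirical = unname(pEmp[reactions]),
        pAdjusted = unname(pAdj[reactions]), class = cls,
        row.names = reactions)
    methods::new("ConcordanceResult", table = tb, threshold = threshold,
                 nResamples = as.integer(nResamples),
                 seed = as.integer(seed))
}

#' @rdname ConcordanceResult-class
#' @param x,object a \code{ConcordanceResult}.
#' @param ... unused.
#' @export
setMethod("show", "ConcordanceResult", function(object) {
    tb <- object@table
    cat(sprintf(
        "ConcordanceResult: %d reactions (threshold %.2f, %d resamples)\n",
        nrow(tb), object@threshold, object@nResamples))
    print(table(tb$class))
    invisible(object)
})

#' @rdname ConcordanceResult-class
#' @export
setMethod("as.data.frame", "ConcordanceResult", function(x, ...)
    as.data.frame(x@table))

#' @rdname ConcordanceResult-class
#' @export
concordanceTable <- function(object) object@table
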