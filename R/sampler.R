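#' @useDynLib fluxcord, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Sample feasible flux distributions from the constrained polytope
#'
#' Draws near-uniform steady-state flux vectors from
#' \eqn{\{v : S v = 0,\ v_L \le v \le v_U,\ \mathrm{extra\ rows}\}} with an
#' artificial-centering hit-and-run chain. The steady-state equalities are
#' eliminated by working in null-space coordinates (directions with no
#' residual freedom, e.g. blocked reactions, are projected out), warmup
#' points are the FVA optima, and the chain records a state every
#' \code{thinning} accepted steps after a burn-in of
#' \code{thinning * 100} steps per batch. Samples are drawn in
#' \code{nBatches} batches with per-batch seeds derived from the master
#' seed, so results are reproducible and batch-wise comparable.
#'
#' @param model irreversible, feasible \linkS4class{MetabolicModel} with
#'   all constraint layers applied.
#' @param group group label stored in the result.
#' @param nTotal total number of samples (default 5000; a production run
#'   mirroring the full protocol would use 1e6 in 10 batches).
#' @param nBatches number of independent chains/batches.
#' @param thinning record every \code{thinning}-th accepted step.
#' @param seed master seed; batch \code{b} uses \code{seed + b}.
#' @param tolerance validation tolerance stored with the samples.
#' @return a \linkS4class{FluxSampleSet}.
#' @export
sampleFluxes <- function(model, group = "group", nTotal = 5000L,
                         nBatches = 10L, thinning = 10L, seed = 1L,
                         tolerance = 1e-6) {
    stopifnot(nTotal >= nBatches, nBatches >= 1L, thinning >= 1L)
    struct <- .lpStructure(model)
    fva <- runFVA(model)
    verts <- attr(fva, "vertices")
    n <- length(struct$ids)
    v0 <- rowMeans(verts)

    ## null space of the steady-state matrix
    Smat <- struct$S
    if (nrow(Smat)) {
        sv <- svd(Smat, nu = 0, nv = n)
        rank <- sum(sv$d > max(dim(Smat)) * max(sv$d, 0) * 1e-12)
        N <- if (rank < n) sv$v[, (rank + 1L):n, drop = FALSE]
             else matrix(numeric(), nrow = n, ncol = 0)
    } else N <- diag(n)

    pointPolytope <- FALSE
    if (ncol(N) == 0L) {
        pointPolytope <- TRUE
    } else {
        W <- crossprod(N, verts - v0)      # warmup points, null-space coords
        ## drop directions with no residual freedom (blocked reactions,
        ## equality-collapsed ratio rows)
        wsv <- svd(W, nv = 0)
        keep <- wsv$d > max(1e-9, max(wsv$d) * 1e-9)
        if (!any(keep)) {
            pointPolytope <- TRUE
        } else {
            P <- wsv$u[, keep, drop = FALSE]
            N <- N %*% P
            W <- crossprod(P, W)
        }
    }
    if (pointPolytope) {
        warning("the constrained flux polytope is a single point; ",
                "returning that vertex repeated")
        fluxes <- matrix(rep(v0, nTotal), nrow = n,
                         dimnames = list(struct$ids, NULL))
        batchSizes <- .batchSizes(nTotal, nBatches)
        return(methods::new("FluxSampleSet", group = group, fluxes = fluxes,
                            batch = rep(seq_len(nBatches), batchSizes),
                            nBatches = as.integer(nBatches),
                            thinning = as.integer(thinning),
                            seed = as.integer(seed), tolerance = tolerance,
                            reverseMap = reverseMap(model)))
    }

    ## inequality rows in t-space: A t <= b
    A <- rbind(N, -N)
    b <- c(struct$ub - v0, v0 - struct$lb)
    finite <- is.finite(b)
    if (!is.null(struct$G)) {
        GN <- struct$G %*% N
        Gv0 <- as.numeric(struct$G %*% v0)
        A <- rbind(A, GN, -GN)
        b <- c(b, struct$ghi - Gv0, Gv0 - struct$glo)
        finite <- c(finite, is.finite(struct$ghi), is.finite(struct$glo))
    }
    A <- A[finite, , drop = FALSE]
    b <- b[finite]

    batchSizes <- .batchSizes(nTotal, nBatches)
    t0 <- numeric(ncol(N))
    chunks <- vector("list", nBatches)
    for (bt in seq_len(nBatches)) {
        set.seed(as.integer(seed) + bt)
        Tchain <- .achrChain(A, b, W, t0, as.integer(batchSizes[bt]),
                             as.integer(thinning),
                             as.integer(thinning * 100L))
        chunks[[bt]] <- v0 + N %*% Tchain
    }
    fluxes <- do.call(cbind, chunks)
    rownames(fluxes) <- struct$ids
    methods::new("FluxSampleSet", group = group, fluxes = fluxes,
                 batch = rep(seq_len(nBatches), batchSizes),
                 nBatches = as.integer(nBatches),
                 thinning = as.integer(thinning),
                 seed = as.integer(seed), tolerance = tolerance,
                 reverseMap = reverseMap(model))
}

.batchSizes <- function(nTotal, nBatches) {
    base <- nTotal %/% nBatches
    sizes <- rep(base, nBatches)
    extra <- nTotal - base * nBatches
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    sizes
}

#' @rdname FluxSampleSet-class
#' @param object a \code{FluxSampleSet}.
#' @export
setMethod("fluxes", "FluxSampleSet", function(object) object@fluxes)

#' @rdname FluxSampleSet-class
#' @export
setMethod("sampleBatches", "FluxSampleSet", function(object) object@batch)

setMethod("show", "FluxSampleSet", function(object) {
    cat(sprintf(
        "FluxSampleSet '%s': %d reactions x %d samples (%d batches, thinning %d, seed %d)\n",
        object@group, nrow(object@fluxes), ncol(object@fluxes),
        object@nBatches, object@thinning, object@seed))
    invisible(object)
})

#' Validate sampled flux vectors against the model constraints
#'
#' Checks every sample for steady-state residual, bound violations and
#' extra-constraint-row violations.
#'
#' @param model the irreversible model the samples were drawn from.
#' @param samples a \linkS4class{FluxSampleSet} or flux matrix.
#' @param tol violation tolerance.
#' @return list with \code{maxEquality}, \code{maxBound} (worst violations),
#'   \code{fracOutside} (fraction of samples violating either beyond
#'   \code{tol}), \code{badSamples} (their column indices) and \code{pass}.
#' @export
verifySamples <- function(model, samples, tol = 1e-6) {
    V <- if (methods::is(samples, "FluxSampleSet")) fluxes(samples)
         else as.matrix(samples)
    if (ncol(V) == 0L) {
        warning("empty sample set: nothing to verify")
        return(list(maxEquality = 0, maxBound = 0, fracOutside = 0,
                    badSamples = integer(), pass = TRUE))
    }
    struct <- .lpStructure(model)
    V <- V[struct$ids, , drop = FALSE]
    eqRes <- if (nrow(struct$S)) abs(struct$S %*% V) else
        matrix(0, 1, ncol(V))
    eqMax <- apply(eqRes, 2, max)
    lbV <- pmax(struct$lb - V, 0)
    ubV <- pmax(V - struct$ub, 0); ubV[!is.finite(struct$ub), ] <- 0
    bMax <- pmax(apply(lbV, 2, max), apply(ubV, 2, max))
    if (!is.null(struct$G)) {
        GV <- struct$G %*% V
        loV <- pmax(struct$glo - GV, 0); loV[!is.finite(struct$glo), ] <- 0
        hiV <- pmax(GV - struct$ghi, 0); hiV[!is.finite(struct$ghi), ] <- 0
        bMax <- pmax(bMax, apply(loV, 2, max), apply(hiV, 2, max))
    }
    bad <- which(eqMax > tol | bMax > tol)
    list(maxEquality = max(eqMax), maxBound = max(bMax),
         fracOutside = length(bad) / ncol(V), badSamples = bad,
         pass = max(eqMax) <= tol && max(bMax) <= tol)
}

#' In-silico growth yield of sampled fluxes
#'
#' Computes, per sample, the protein-synthesis-over-glucose-uptake yield
#' with both fluxes in gram units:
#' \eqn{(0.131972\, v_{Biomass}) / (v_{ExGlc}\, mw_{Glc}\, 0.001)}, where
#' \eqn{v_{ExGlc}} is glucose consumption. The summary statistic is the
#' median; samples whose glucose consumption falls below \code{tol} are
#' excluded (and counted).
#'
#' @param samples a \linkS4class{FluxSampleSet}.
#' @param yield the \code{\link{growthYieldConstraint}} naming the biomass
#'   and glucose-exchange fluxes and carrying the unit constants.
#' @param tol consumption cutoff below which a sample is excluded.
#' @return list with \code{yields}, \code{median}, \code{nExcluded}.
#' @export
growthYield <- function(samples, yield, tol = 1e-9) {
    stopifnot(methods::is(samples, "FluxSampleSet"),
              inherits(yield, "growthYieldConstraint"))
    vBio <- netFlux(samples, yield$biomassId)
    cons <- -netFlux(samples, yield$glucoseExchangeId)  # uptake is negative net
    keep <- cons > tol
    if (!any(keep))
        stop("all samples have glucose consumption below tolerance; ",
             "growth yield undefined")
    y <- (yield$proteinFraction * vBio[keep]) /
        (cons[keep] * yield$mwGlc * 0.001)
    list(yields = y, median = stats::median(y), nExcluded = sum(!keep))
}
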