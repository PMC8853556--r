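#' Medium-composition (nutrient availability) constraints
#'
#' Scales each uptake bound proportionally to the metabolite's
#' concentration in the group's growth medium, relative to the maximum
#' concentration across groups: the group with the richest supply of a
#' metabolite may take it up at \code{baseUptake}, the others
#' proportionally less. Metabolites absent from a group's medium cannot be
#' internalized (uptake bound 0). Only uptake (negative lower) bounds of
#' exchange reactions are touched; secretion bounds are left as modelled.
#' Absolute flux units are arbitrary — only the between-group ratios
#' matter — so \code{baseUptake} is a plain scale factor.
#'
#' @param model a reversible-form \linkS4class{MetabolicModel}.
#' @param medium data.frame with columns \code{species}, \code{group},
#'   \code{conc} (mM).
#' @param baseUptake uptake bound granted to the maximum-concentration
#'   group (flux units; default 10).
#' @return named list of per-group models.
#' @export
applyMediumConstraints <- function(model, medium, baseUptake = 10) {
    stopifnot(all(c("species", "group", "conc") %in% colnames(medium)))
    if (any(medium$conc < 0)) stop("medium concentrations must be >= 0")
    exSp <- .exchangeSpecies(model)   # exchange reaction -> species
    spToEx <- stats::setNames(names(exSp), exSp)
    bad <- setdiff(unique(medium$species), names(spToEx))
    if (length(bad))
        stop("medium references species without an exchange reaction: ",
             paste(bad, collapse = ", "))
    groups <- sort(unique(medium$group))
    maxConc <- tapply(medium$conc, medium$species, max)
    lapply(stats::setNames(groups, groups), function(g) {
        m <- model
        sub <- medium[medium$group == g, , drop = FALSE]
        conc <- stats::setNames(sub$conc, sub$species)
        # every uptake-capable exchange: closed unless the medium supplies it
        uptakeRx <- names(exSp)[m@reactions[match(names(exSp), m@reactions$id),
                                            "lb"] < 0]
        for (r in uptakeRx) {
            sp <- exSp[[r]]
            cc <- if (sp %in% names(conc)) conc[[sp]] else 0
            scale <- if (cc > 0 && maxConc[[sp]] > 0) cc / maxConc[[sp]] else 0
            i <- match(r, m@reactions$id)
            m@reactions$lb[i] <- -baseUptake * scale
        }
        methods::validObject(m)
        m
    })
}

#' Exchange-flux ratio constraints from spent-medium measurements
#'
#' From spent-medium concentrations at seeding (t0) and after the growth
#' window (t48), computes the produced-over-consumed ratios
#' lactate/glucose, lactate/glutamine and glutamate/glutamine per sample.
#' Since only ratios are constrained, dividing the concentration
#' differences by the cell-number integral is unnecessary and omitted.
#' Technical replicates are averaged within each biological replicate;
#' the constraint mean and standard deviation (sample sd, n-1) are then
#' taken across biological replicates.
#'
#' @param spent data.frame with columns \code{group}, \code{bioRep},
#'   \code{techRep}, \code{metabolite} (one of \code{glucose},
#'   \code{glutamine}, \code{lactate}, \code{glutamate}), \code{t0},
#'   \code{t48}.
#' @param fluxIds named character vector mapping those four metabolite
#'   names to the model's exchange reaction ids.
#' @param sigmaFallback optional sd used when a group has fewer than two
#'   biological replicates (otherwise an error).
#' @return data.frame with one row per (group, ratio): columns
#'   \code{group}, \code{ratio}, \code{numerator}, \code{denominator},
#'   \code{xbar}, \code{sigma}.
#' @export
deriveRatioConstraints <- function(spent, fluxIds, sigmaFallback = NULL) {
    need <- c("group", "bioRep", "techRep", "metabolite", "t0", "t48")
    stopifnot(all(need %in% colnames(spent)))
    stopifnot(all(c("glucose", "glutamine", "lactate", "glutamate") %in%
                  names(fluxIds)))
    defs <- data.frame(
        ratio = c("lac/glc", "lac/gln", "glu/gln"),
        num = c("lactate", "lactate", "glutamate"),
        den = c("glucose", "glutamine", "glutamine"),
        stringsAsFactors = FALSE)
    out <- list()
    for (g in sort(unique(spent$group))) {
        sg <- spent[spent$group == g, , drop = FALSE]
        for (k in seq_len(nrow(defs))) {
            perBio <- vapply(sort(unique(sg$bioRep)), function(br) {
                sb <- sg[sg$bioRep == br, , drop = FALSE]
                perTech <- vapply(sort(unique(sb$techRep)), function(tr) {
                    st <- sb[sb$techRep == tr, , drop = FALSE]
                    get <- function(met) st[st$metabolite == met, , drop = FALSE]
                    num <- get(defs$num[k]); den <- get(defs$den[k])
                    if (nrow(num) != 1L || nrow(den) != 1L)
                        stop("spent-medium table needs exactly one row per ",
                             "group/replicate/metabolite")
                    produced <- num$t48 - num$t0     # byproduct accumulates
                    consumed <- den$t0 - den$t48     # nutrient is depleted
                    produced / consumed
                }, numeric(1))
                mean(perTech)
            }, numeric(1))
            if (length(perBio) < 2L && is.null(sigmaFallback))
                stop("group '", g, "' has fewer than 2 biological replicates; ",
                     "sigma is undefined (supply sigmaFallback)")
            out[[length(out) + 1L]] <- data.frame(
                group = g, ratio = defs$ratio[k],
                numerator = unname(fluxIds[defs$num[k]]),
                denominator = unname(fluxIds[defs$den[k]]),
                xbar = mean(perBio),
                sigma = if (length(perBio) >= 2L) stats::sd(perBio)
                        else sigmaFallback,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}

#' Growth-yield bracket definition
#'
#' Constrains the order of magnitude of the growth yield on glucose:
#' \deqn{minYield \cdot v_{ExGlc} \cdot mw_{Glc} \cdot 0.001 \le
#'       0.131972 \cdot v_{Biomass} \le
#'       maxYield \cdot v_{ExGlc} \cdot mw_{Glc} \cdot 0.001}
#' where \eqn{v_{ExGlc}} is glucose \emph{consumption} (grams via the
#' molecular weight) and 0.131972 is the protein fraction of biomass. The
#' default yield bounds are the experimentally observed extremes across
#' all samples of the study design this package follows.
#'
#' @param biomassId biomass synthesis reaction id.
#' @param glucoseExchangeId glucose exchange reaction id (uptake =
#'   negative flux in the reversible model).
#' @param minYield,maxYield dimensionless growth-yield bounds.
#' @param mwGlc glucose molecular weight, g/mol.
#' @param proteinFraction protein mass fraction of biomass.
#' @return an object describing the two one-sided rows; pass to
#'   \code{\link{attachConstraints}} and \code{\link{growthYield}}.
#' @export
growthYieldConstraint <- function(biomassId, glucoseExchangeId,
                                  minYield = 3.90762e-5,
                                  maxYield = 1.67998e-4,
                                  mwGlc = 180.16,
                                  proteinFraction = 0.131972) {
    stopifnot(minYield > 0, minYield <= maxYield)
    structure(list(biomassId = biomassId,
                   glucoseExchangeId = glucoseExchangeId,
                   minYield = minYield, maxYield = maxYield,
                   mwGlc = mwGlc, proteinFraction = proteinFraction),
              class = "growthYieldConstraint")
}

#' Attach ratio and growth-yield rows to a model
#'
#' Converts \code{\link{deriveRatioConstraints}} rows and a
#' \code{\link{growthYieldConstraint}} into general linear constraint rows
#' on the model. With secretion positive and uptake negative
#' (reversible-model sign convention), the ratio row
#' \eqn{-\sigma \le v_{num} - \bar{x}\,(-v_{den}) \le \sigma} becomes
#' coefficients \{numerator: 1, denominator: \eqn{\bar x}\} within
#' \eqn{[-\sigma, \sigma]}. Must be called \emph{before}
#' \code{\link{makeIrreversible}}, which rewrites the rows onto the split
#' variables.
#'
#' @param model a reversible-form \linkS4class{MetabolicModel}.
#' @param ratios data.frame rows for \emph{one} group (subset of
#'   \code{deriveRatioConstraints} output), or \code{NULL}.
#' @param yield a \code{growthYieldConstraint}, or \code{NULL}.
#' @return the model with extra constraint rows appended.
#' @export
attachConstraints <- function(model, ratios = NULL, yield = NULL) {
    rows <- model@extraConstraints
    rxIds <- reactionIds(model)
    if (!is.null(ratios) && nrow(ratios)) {
        for (k in seq_len(nrow(ratios))) {
            num <- ratios$numerator[k]; den <- ratios$denominator[k]
            miss <- setdiff(c(num, den), rxIds)
            if (length(miss))
                stop("ratio constraint references unknown flux id(s): ",
                     paste(miss, collapse = ", "))
            rows[[length(rows) + 1L]] <- list(
                id = paste0("ratio_", gsub("/", "_", ratios$ratio[k])),
                coefs = stats::setNames(c(1, ratios$xbar[k]), c(num, den)),
                lo = -ratios$sigma[k], hi = ratios$sigma[k])
        }
    }
    if (!is.null(yield)) {
        miss <- setdiff(c(yield$biomassId, yield$glucoseExchangeId), rxIds)
        if (length(miss))
            stop("yield constraint references unknown flux id(s): ",
                 paste(miss, collapse = ", "))
        gram <- yield$mwGlc * 0.001
        # consumption = -v_exchange, so the glucose coefficient flips sign
        rows[[length(rows) + 1L]] <- list(
            id = "yield_min",
            coefs = stats::setNames(
                c(yield$proteinFraction, yield$minYield * gram),
                c(yield$biomassId, yield$glucoseExchangeId)),
            lo = 0, hi = Inf)
        rows[[length(rows) + 1L]] <- list(
            id = "yield_max",
            coefs = stats::setNames(
                c(yield$proteinFraction, yield$maxYield * gram),
                c(yield$biomassId, yield$glucoseExchangeId)),
            lo = -Inf, hi = 0)
    }
    extraConstraints(model) <- rows
    model
}

#' Flux Variability Analysis
#'
#' Solves, for each reaction, the pair of linear programs
#' \eqn{\max / \min v_i} subject to \eqn{S v = 0}, the flux bounds, and
#' any extra constraint rows. No biomass objective is imposed: the
#' variability is taken over the whole constrained region, with realism
#' enforced only through the growth-yield bracket if attached.
#'
#' @param model an irreversible \linkS4class{MetabolicModel} (with type 1,
#'   type 2 and yield rows already in place, when used in the pipeline).
#' @param reactions reaction ids to analyse (default all).
#' @param zeroTol magnitudes below this are clipped to exactly 0.
#' @return data.frame with columns \code{id}, \code{min}, \code{max};
#'   attribute \code{"vertices"} holds the optimal flux vectors (one
#'   column per solved LP), which downstream sampling reuses as warmup
#'   points.
#' @export
runFVA <- function(model, reactions = NULL, zeroTol = 1e-9) {
    struct <- .lpStructure(model)
    .assertFeasible(struct)
    if (is.null(reactions)) reactions <- struct$ids
    verts <- matrix(NA_real_, nrow = length(struct$ids),
                    ncol = 2L * length(reactions),
                    dimnames = list(struct$ids, NULL))
    lo <- hi <- stats::setNames(numeric(length(reactions)), reactions)
    for (k in seq_along(reactions)) {
        r <- reactions[k]
        mx <- .solveLP(struct, r, maximize = TRUE)
        mn <- .solveLP(struct, r, maximize = FALSE)
        if (mx$status != 1 || mn$status != 1)
            stop("FVA did not converge for reaction ", r)
        hi[k] <- mx$value; lo[k] <- mn$value
        verts[, 2 * k - 1] <- mx$solution
        verts[, 2 * k] <- mn$solution
    }
    lo[abs(lo) < zeroTol] <- 0
    hi[abs(hi) < zeroTol] <- 0
    lo <- pmax(lo, 0)          # irreversible model: min >= 0
    hi <- pmax(hi, lo)
    out <- data.frame(id = reactions, min = unname(lo), max = unname(hi),
                      row.names = reactions, stringsAsFactors = FALSE)
    attr(out, "vertices") <- verts
    out
}

#' RAS-scaled transcriptomic flux bounds
#'
#' Applies the transcriptomic layer: reactions whose expression-derived
#' normalized score is below 1 get their group-specific flux capability
#' (FVA interval) shrunk proportionally,
#' \eqn{\overline{RAS}\, v_L \le v \le \overline{RAS}\, v_U}; reactions
#' without a usable rule, and any exempt reactions, keep the plain FVA
#' interval. Exemptions exist for rules whose null score would otherwise
#' make growth infeasible in some group.
#'
#' @param model irreversible \linkS4class{MetabolicModel}.
#' @param rasBar named numeric in [0, 1]: normalized RAS of this group,
#'   keyed by \emph{original} reaction id (split directions inherit it).
#' @param fva result of \code{\link{runFVA}} on this model.
#' @param exemptList reaction ids (original ids) never scaled.
#' @return the model with updated bounds.
#' @export
applyRasBounds <- function(model, rasBar, fva, exemptList = character()) {
    if (any(rasBar < -1e-12 | rasBar > 1 + 1e-12, na.rm = TRUE))
        stop("normalized RAS values must lie in [0, 1]")
    rmap <- as.data.frame(reverseMap(model))
    toOrig <- function(id) {
        i <- match(id, rmap$id)
        if (is.na(i)) id else rmap$original[i]
    }
    bounds <- reactionBounds(model)
    for (r in fva$id) {
        orig <- toOrig(r)
        s <- if (orig %in% names(rasBar) && !is.na(rasBar[[orig]]) &&
                 !orig %in% exemptList) rasBar[[orig]] else 1
        bounds[r, "lb"] <- s * fva[r, "min"]
        bounds[r, "ub"] <- s * fva[r, "max"]
    }
    reactionBounds(model) <- bounds
    model
}

#' Build per-group cell-relative models
#'
#' Orchestrates the constraint layers in their mandated order: medium
#' (type 1) and exchange-ratio (type 2) constraints on the reversible
#' model, the growth-yield bracket, conversion to the irreversible form,
#' FVA under those constraints, then RAS-proportional bound scaling
#' (type 3). Ratio rows must precede irreversibilization so that they are
#' rewritten onto the split variables and FVA is not inflated by futile
#' loops. Type 2 may be skipped while keeping type 3.
#'
#' @param model generic reversible \linkS4class{MetabolicModel}.
#' @param expression gene-by-sample matrix; \code{groups} labels its
#'   columns.
#' @param groups group label per expression column.
#' @param medium see \code{\link{applyMediumConstraints}}; required when
#'   \code{type1} is on.
#' @param spent spent-medium table (see
#'   \code{\link{deriveRatioConstraints}}); required when \code{type2} is
#'   on.
#' @param fluxIds metabolite-to-exchange-id map for the ratio layer.
#' @param yield a \code{\link{growthYieldConstraint}} or \code{NULL}.
#' @param type1,type2,type3 layer toggles.
#' @param baseUptake see \code{\link{applyMediumConstraints}}.
#' @param exemptList see \code{\link{applyRasBounds}}.
#' @param missingPolicy see \code{\link{computeRAS}}.
#' @return list with elements \code{models} (named list of irreversible
#'   per-group models), \code{fva} (named list of FVA tables),
#'   \code{ras} (the \linkS4class{ScoreTable}) and \code{rasBar}
#'   (normalized score matrix).
#' @export
buildCellRelativeModels <- function(model, expression, groups,
                                    medium = NULL, spent = NULL,
                                    fluxIds = NULL, yield = NULL,
                                    type1 = TRUE, type2 = TRUE, type3 = TRUE,
                                    baseUptake = 10,
                                    exemptList = character(),
                                    missingPolicy = "skip") {
    rasTab <- computeRAS(model, expression, groups, missingPolicy)
    rasBar <- normalizedScores(rasTab)
    hasGPR <- SummarizedExperiment::rowData(rasTab)$hasGPR
    groupsAll <- sort(unique(as.character(groups)))

    base <- if (type1) {
        if (is.null(medium)) stop("type 1 layer requires a medium table")
        applyMediumConstraints(model, medium, baseUptake)
    } else {
        stats::setNames(rep(list(model), length(groupsAll)), groupsAll)
    }
    if (!all(groupsAll %in% names(base)))
        stop("medium table lacks group(s): ",
             paste(setdiff(groupsAll, names(base)), collapse = ", "))

    ratios <- if (type2) {
        if (is.null(spent) || is.null(fluxIds))
            stop("type 2 layer requires the spent-medium table and fluxIds")
        deriveRatioConstraints(spent, fluxIds)
    } else NULL

    models <- list(); fvas <- list()
    for (g in groupsAll) {
        m <- base[[g]]
        m <- attachConstraints(
            m, ratios = if (!is.null(ratios))
                ratios[ratios$group == g, , drop = FALSE] else NULL,
            yield = yield)
        irr <- makeIrreversible(m, requireExtraConstraints = type2)
        fva <- runFVA(irr)
        rb <- rasBar[, g]
        rb[!hasGPR] <- NA_real_   # rule-free reactions keep the FVA interval
        if (!type3) rb[] <- NA_real_
        irr <- applyRasBounds(irr, rb, fva, exemptList)
        models[[g]] <- irr
        fvas[[g]] <- fva
    }
    list(models = models, fva = fvas, ras = rasTab, rasBar = rasBar)
}
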