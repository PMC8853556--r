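#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Matrix dgCMatrix
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
NULL

#' Constraint-based metabolic model
#'
#' An S4 container for a stoichiometric metabolic network: species,
#' reactions with flux bounds and gene-protein-reaction (GPR) rules, the
#' sparse stoichiometric matrix, and any additional linear constraints
#' (exchange-flux ratio rows, the growth-yield bracket) that SBML cannot
#' embed.
#'
#' @slot species a \linkS4class{DataFrame} with columns \code{id},
#'   \code{name}, \code{compartment} and \code{boundary} (logical; boundary
#'   species are excluded from the steady-state constraint).
#' @slot reactions a \linkS4class{DataFrame} with columns \code{id},
#'   \code{lb}, \code{ub}, \code{reversible}, \code{gpr} (rule string or
#'   \code{NA}), \code{isExchange} and \code{pathway}.
#' @slot stoichiometry sparse species-by-reaction matrix; negative entries
#'   are substrates.
#' @slot gprs named list of parsed GPR trees (see \code{\link{parseGPR}});
#'   \code{NULL} entries for reactions without a rule.
#' @slot extraConstraints list of general linear rows, each a list with
#'   elements \code{id}, \code{coefs} (named numeric over reaction ids),
#'   \code{lo} and \code{hi} (may be \code{-Inf}/\code{Inf}).
#' @slot reverseMap \linkS4class{DataFrame} mapping split reactions of an
#'   irreversible model back to their originals (columns \code{id},
#'   \code{original}, \code{direction}).
#' @slot irreversible logical flag: all reactions run forward only.
#'
#' @seealso \code{\link{readSBML}}, \code{\link{makeIrreversible}},
#'   \code{\link{generateToyModel}}
#' @aliases MetabolicModel
#' @export
setClass("MetabolicModel",
         slots = c(species = "DataFrame",
                   reactions = "DataFrame",
                   stoichiometry = "dgCMatrix",
                   gprs = "list",
                   extraConstraints = "list",
                   reverseMap = "DataFrame",
                   irreversible = "logical"))

setValidity("MetabolicModel", function(object) {
    msg <- character()
    sp <- object@species
    rx <- object@reactions
    S <- object@stoichiometry
    need <- function(df, cols, what)
        if (!all(cols %in% colnames(df)))
            sprintf("%s must have columns %s", what, paste(cols, collapse = ", "))
        else NULL
    msg <- c(msg,
             need(sp, c("id", "name", "compartment", "boundary"), "species"),
             need(rx, c("id", "lb", "ub", "reversible", "gpr", "isExchange"),
                  "reactions"))
    if (length(msg)) return(msg)
    if (anyDuplicated(sp$id)) msg <- c(msg, "species ids must be unique")
    if (anyDuplicated(rx$id)) msg <- c(msg, "reaction ids must be unique")
    if (any(!nzchar(sp$compartment)))
        msg <- c(msg, "species compartments must be non-empty")
    if (!identical(dim(S), c(nrow(sp), nrow(rx))))
        msg <- c(msg, "stoichiometry must be (#species x #reactions)")
    if (!identical(rownames(S), as.character(sp$id)) ||
        !identical(colnames(S), as.character(rx$id)))
        msg <- c(msg, "stoichiometry dimnames must match species/reaction ids")
    if (any(rx$lb > rx$ub + 1e-12))
        msg <- c(msg, "every reaction must satisfy lb <= ub")
    if (isTRUE(object@irreversible) && any(rx$lb < -1e-12))
        msg <- c(msg, "irreversible model has a reaction with lb < 0")
    if (length(object@gprs) && !identical(names(object@gprs), as.character(rx$id)))
        msg <- c(msg, "gprs must be named by reaction id, in reaction order")
    for (ec in object@extraConstraints) {
        if (!all(c("coefs", "lo", "hi") %in% names(ec)) ||
            !all(names(ec$coefs) %in% rx$id)) {
            msg <- c(msg, "malformed extra constraint (unknown reaction id?)")
            break
        }
    }
    if (length(msg)) msg else TRUE
})

#' Reaction-by-sample omics score table
#'
#' Holds per-sample Reaction Activity Scores (RAS, expression through GPR
#' rules) or Reaction Propensity Scores (RPS, mass-action substrate
#' products) as a \linkS4class{SummarizedExperiment} with a single
#' \code{"score"} assay. Column data carry the sample's group (cell line);
#' group means and cross-group normalized scores are derived by
#' \code{\link{groupMeans}} and \code{\link{normalizedScores}}.
#'
#' @slot scoreType either \code{"RAS"} or \code{"RPS"}.
#' @aliases ScoreTable
#' @export
setClass("ScoreTable",
         contains = "SummarizedExperiment",
         slots = c(scoreType = "character"))

setValidity("ScoreTable", function(object) {
    msg <- character()
    if (length(object@scoreType) != 1L ||
        !object@scoreType %in% c("RAS", "RPS"))
        msg <- c(msg, "scoreType must be 'RAS' or 'RPS'")
    if (!"score" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "a 'score' assay is required")
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    sc <- SummarizedExperiment::assay(object, "score")
    if (any(sc < 0, na.rm = TRUE))
        msg <- c(msg, "scores must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Feasible flux distributions for one group
#'
#' A reaction-by-sample matrix of steady-state flux vectors drawn
#' near-uniformly from one group's constrained flux polytope, together with
#' the sampling metadata needed to reproduce it (seed, batches, thinning).
#'
#' @slot group group (cell line) label.
#' @slot fluxes numeric matrix, reactions in rows, samples in columns.
#' @slot batch integer batch index per sample column.
#' @slot nBatches,thinning,seed sampling protocol parameters.
#' @slot tolerance solver/validation tolerance the samples were checked at.
#' @slot reverseMap copy of the model's forward/reverse split map, so that
#'   \code{\link{netFlux}} can reconstruct net fluxes of reversible
#'   reactions.
#' @aliases FluxSampleSet
#' @export
setClass("FluxSampleSet",
         slots = c(group = "character",
                   fluxes = "matrix",
                   batch = "integer",
                   nBatches = "integer",
                   thinning = "integer",
                   seed = "integer",
                   tolerance = "numeric",
                   reverseMap = "DataFrame"))

setValidity("FluxSampleSet", function(object) {
    msg <- character()
    if (is.null(rownames(object@fluxes)))
        msg <- c(msg, "flux matrix must have reaction ids as rownames")
    if (length(object@batch) != ncol(object@fluxes))
        msg <- c(msg, "one batch index per sample column is required")
    if (length(object@group) != 1L)
        msg <- c(msg, "group must be a single label")
    if (length(msg)) msg else TRUE
})

#' Pairwise variation-sign matrix
#'
#' For one dataset (RAS, RPS or FFD), the called sign of variation
#' (\code{-1}, \code{0}, \code{+1}) of every reaction for every ordered
#' pair of groups. Pair ordering is lexicographic on group labels and
#' shared across datasets so that sign vectors are directly comparable.
#'
#' @slot dataset one of \code{"RAS"}, \code{"RPS"}, \code{"FFD"}.
#' @slot signs integer matrix, reactions by group pairs, entries in
#'   \{-1, 0, +1\}.
#' @slot groups the group labels the pairs were formed from.
#' @aliases SignMatrix
#' @export
setClass("SignMatrix",
         slots = c(dataset = "character",
                   signs = "matrix",
                   groups = "character"))

setValidity("SignMatrix", function(object) {
    msg <- character()
    if (!object@dataset %in% c("RAS", "RPS", "FFD"))
        msg <- c(msg, "dataset must be RAS, RPS or FFD")
    v <- object@signs
    if (!all(v %in% c(-1L, 0L, 1L)))
        msg <- c(msg, "sign values must be in {-1, 0, +1}")
    np <- choose(length(object@groups), 2)
    if (ncol(v) != np)
        msg <- c(msg, sprintf("expected %d pair columns, found %d", np, ncol(v)))
    if (length(msg)) msg else TRUE
})

#' Concordance analysis result
#'
#' Per-reaction Cohen's kappa concordance scores between the RPS, RAS and
#' FFD sign matrices, the empirical p-value of the RPS-vs-FFD score against
#' a resampling null, its Benjamini-Hochberg adjustment, and the derived
#' regulatory class label.
#'
#' @slot table a \linkS4class{DataFrame} with columns \code{reaction},
#'   \code{kappaRpsVsFfd}, \code{kappaRpsVsRas}, \code{kappaRasVsFfd},
#'   \code{pEmpirical}, \code{pAdjusted}, \code{class}.
#' @slot threshold kappa threshold used for classification (default 0.2).
#' @slot nResamples size of the empirical null.
#' @slot seed RNG seed of the null construction.
#' @aliases ConcordanceResult
#' @export
setClass("ConcordanceResult",
         slots = c(table = "DataFrame",
                   threshold = "numeric",
                   nResamples = "integer",
                   seed = "integer"))

setValidity("ConcordanceResult", function(object) {
    msg <- character()
    tb <- object@table
    need <- c("reaction", "kappaRpsVsFfd", "kappaRpsVsRas", "kappaRasVsFfd",
              "pEmpirical", "pAdjusted", "class")
    if (!all(need %in% colnames(tb)))
        msg <- c(msg, paste("table must have columns", paste(need, collapse = ", ")))
    else {
        k <- unlist(tb[, c("kappaRpsVsFfd", "kappaRpsVsRas", "kappaRasVsFfd")])
        if (any(k < -1 - 1e-9 | k > 1 + 1e-9, na.rm = TRUE))
            msg <- c(msg, "kappa values must lie in [-1, 1]")
        bad <- !is.na(tb$pAdjusted) & !is.na(tb$pEmpirical) &
            tb$pAdjusted < tb$pEmpirical - 1e-12
        if (any(bad))
            msg <- c(msg, "adjusted p-values may not fall below raw p-values")
    }
    if (length(msg)) msg else TRUE
})
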