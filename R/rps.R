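#' Assign measured metabolite abundances to model species
#'
#' Measured metabolite names rarely resolve compartments: a single
#' measurement (e.g. total citrate) can correspond to both the cytosolic
#' and mitochondrial species of the model. Each measured abundance is
#' therefore assigned identically to every mapped compartmental species.
#' Mapping uses, in order: an explicit \code{nameMap}, an exact species-id
#' match, then a case-insensitive match of the measured name against
#' species names stripped of a trailing compartment tag
#' (\code{"_c"}, \code{"_m"}, \code{"_e"}).
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param abundances metabolite-by-sample matrix of non-negative values,
#'   rownames = measured metabolite names.
#' @param nameMap optional data.frame with columns \code{name},
#'   \code{species} (repeated rows for multi-compartment assignments).
#' @return species-by-sample matrix restricted to mapped species; measured
#'   names that map to no species are dropped with a warning.
#' @export
mapMetabolites <- function(model, abundances, nameMap = NULL) {
    abundances <- as.matrix(abundances)
    if (any(abundances < 0, na.rm = TRUE))
        stop("metabolite abundances must be non-negative")
    spIds <- speciesIds(model)
    stripTag <- function(x) sub("_(c|m|e)$", "", x)
    targets <- list()
    for (nm in rownames(abundances)) {
        hit <- character()
        if (!is.null(nameMap)) {
            hit <- as.character(nameMap$species[nameMap$name == nm])
            bad <- setdiff(hit, spIds)
            if (length(bad))
                stop("name map sends '", nm, "' to unknown species: ",
                     paste(bad, collapse = ", "))
        }
        if (!length(hit) && nm %in% spIds) hit <- nm
        if (!length(hit))
            hit <- spIds[tolower(stripTag(spIds)) == tolower(stripTag(nm))]
        if (!length(hit)) {
            warning("measured metabolite '", nm,
                    "' maps to no model species; ignored")
            next
        }
        for (s in hit) targets[[s]] <- abundances[nm, , drop = FALSE]
    }
    if (!length(targets))
        return(matrix(numeric(), nrow = 0, ncol = ncol(abundances),
                      dimnames = list(character(), colnames(abundances))))
    out <- do.call(rbind, targets)
    dimnames(out) <- list(names(targets), colnames(abundances))
    out
}

#' Reactions with fully measured substrate pools
#'
#' A reaction enters the propensity dataset only if \emph{every} substrate
#' (negative stoichiometric coefficient) has a measured abundance; one
#' missing substrate removes the reaction. Ubiquitous species (water,
#' protons, phosphate, ...) can be excused via \code{exclusionList}.
#'
#' @param model an \emph{irreversible} \linkS4class{MetabolicModel}
#'   (substrates are direction-specific).
#' @param assignment species-by-sample matrix from
#'   \code{\link{mapMetabolites}} (only rownames are used).
#' @param exclusionList species ids that never count as required
#'   substrates.
#' @param excludeReactions reaction ids excluded outright (the biomass
#'   pseudo-reaction by default has no meaningful substrate pool — pass it
#'   here).
#' @return character vector of eligible reaction ids.
#' @export
eligibleReactions <- function(model, assignment, exclusionList = character(),
                              excludeReactions = character()) {
    stopifnot(methods::is(model, "MetabolicModel"))
    if (!isIrreversible(model))
        stop("eligibility is defined on the irreversible model")
    S <- stoichiometricMatrix(model)
    measured <- rownames(assignment)
    ok <- vapply(reactionIds(model), function(r) {
        subs <- rownames(S)[S[, r] < 0]
        counted <- setdiff(subs, exclusionList)
        # a reaction with no substrates at all (e.g. a split uptake
        # direction) has no propensity; one whose substrates are all
        # excluded ubiquitous species is vacuously eligible
        length(subs) > 0 && all(counted %in% measured)
    }, logical(1))
    setdiff(reactionIds(model)[ok], excludeReactions)
}

#' Compute Reaction Propensity Scores
#'
#' Under mass action, a reaction's rate is proportional to the product of
#' its substrate concentrations, each raised to its stoichiometric
#' coefficient; the kinetic constant cancels in any between-group ratio.
#' The RPS of reaction \eqn{r} in a sample is
#' \eqn{\prod_q [X_q]^{|s_{r,q}|}} over its substrates, giving a
#' flux-variation proxy driven purely by substrate availability.
#'
#' @inheritParams eligibleReactions
#' @param assignment species-by-sample abundance matrix from
#'   \code{\link{mapMetabolites}}.
#' @param groups group label per sample column.
#' @param exclusionList species skipped both in eligibility and in the
#'   product (e.g. \code{rpsCofactorPreset()}).
#' @param excludeReactions see \code{\link{eligibleReactions}}.
#' @return a \linkS4class{ScoreTable} (type RPS) over eligible reactions.
#' @export
computeRPS <- function(model, assignment, groups,
                       exclusionList = character(),
                       excludeReactions = character()) {
    elig <- eligibleReactions(model, assignment, exclusionList,
                              excludeReactions)
    if (!length(elig))
        stop("no reaction has a fully measured substrate pool")
    S <- stoichiometricMatrix(model)
    out <- matrix(NA_real_, nrow = length(elig), ncol = ncol(assignment),
                  dimnames = list(elig, colnames(assignment)))
    for (r in elig) {
        subs <- rownames(S)[S[, r] < 0]
        subs <- setdiff(subs, exclusionList)
        expo <- abs(S[subs, r])
        out[r, ] <- apply(assignment[subs, , drop = FALSE], 2,
                          function(x) prod(x ^ expo))
    }
    ScoreTable(out, groups, "RPS")
}

#' Ubiquitous-species preset for RPS eligibility
#'
#' Water, protons and inorganic phosphate in any compartment: species so
#' abundant and buffered that treating them as limiting substrates would
#' only discard reactions. Shipped as an opt-in preset; the default
#' exclusion list is empty.
#'
#' @return character vector of species ids.
#' @export
rpsCofactorPreset <- function() {
    base <- c("h2o", "h", "pi")
    as.character(outer(base, c("_c", "_m", "_e"), paste0))
}
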