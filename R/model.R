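#' Construct a MetabolicModel
#'
#' Low-level constructor used by \code{\link{readSBML}} and
#' \code{\link{generateToyModel}}. GPR strings in \code{reactions$gpr} are
#' parsed on construction.
#'
#' @param species data.frame/DataFrame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{boundary}.
#' @param reactions data.frame/DataFrame with columns \code{id}, \code{lb},
#'   \code{ub}, \code{reversible}, \code{gpr}, \code{isExchange} and
#'   optionally \code{pathway}.
#' @param stoichiometry species-by-reaction matrix (dense or sparse);
#'   negative coefficients mark substrates.
#' @param extraConstraints list of additional linear rows (see
#'   \linkS4class{MetabolicModel}).
#' @param reverseMap forward/reverse split map (internal use).
#' @param irreversible logical.
#' @return a validated \linkS4class{MetabolicModel}.
#' @export
MetabolicModel <- function(species, reactions, stoichiometry,
                           extraConstraints = list(),
                           reverseMap = S4Vectors::DataFrame(
                               id = character(), original = character(),
                               direction = character()),
                           irreversible = FALSE) {
    species <- S4Vectors::DataFrame(as.data.frame(species))
    reactions <- S4Vectors::DataFrame(as.data.frame(reactions))
    if (is.null(species$boundary)) species$boundary <- FALSE
    if (is.null(reactions$pathway)) reactions$pathway <- NA_character_
    if (is.null(reactions$gpr)) reactions$gpr <- NA_character_
    S <- methods::as(methods::as(Matrix::Matrix(stoichiometry, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    dimnames(S) <- list(as.character(species$id), as.character(reactions$id))
    gprs <- lapply(as.character(reactions$gpr), parseGPR)
    names(gprs) <- as.character(reactions$id)
    methods::new("MetabolicModel", species = species, reactions = reactions,
                 stoichiometry = S, gprs = gprs,
                 extraConstraints = extraConstraints,
                 reverseMap = S4Vectors::DataFrame(as.data.frame(reverseMap)),
                 irreversible = irreversible)
}

#' @rdname MetabolicModel-class
#' @param object,model a \code{MetabolicModel}.
#' @export
setMethod("reactionIds", "MetabolicModel",
          function(object) as.character(object@reactions$id))

#' @rdname MetabolicModel-class
#' @export
setMethod("speciesIds", "MetabolicModel",
          function(object) as.character(object@species$id))

#' @rdname MetabolicModel-class
#' @export
setMethod("geneIds", "MetabolicModel", function(object)
    sort(unique(unlist(lapply(object@gprs, gprGenes)))))

#' @rdname MetabolicModel-class
#' @param boundary include boundary species rows? Boundary species sit
#'   outside the mass-balance and are dropped by default.
#' @export
setMethod("stoichiometricMatrix", "MetabolicModel",
          function(object, boundary = FALSE) {
    S <- object@stoichiometry
    if (!boundary) S <- S[!object@species$boundary, , drop = FALSE]
    S
})

#' @rdname MetabolicModel-class
#' @export
setMethod("reactionBounds", "MetabolicModel", function(object) {
    data.frame(id = as.character(object@reactions$id),
               lb = object@reactions$lb, ub = object@reactions$ub,
               row.names = as.character(object@reactions$id))
})

#' @rdname MetabolicModel-class
#' @param value for \code{reactionBounds<-}: data.frame with rownames (or an
#'   \code{id} column) and columns \code{lb}, \code{ub}.
#' @export
setMethod("reactionBounds<-", "MetabolicModel", function(object, value) {
    ids <- if (!is.null(value$id)) as.character(value$id) else rownames(value)
    stopifnot(!is.null(ids))
    miss <- setdiff(ids, reactionIds(object))
    if (length(miss))
        stop("unknown reaction id(s): ", paste(miss, collapse = ", "))
    i <- match(ids, object@reactions$id)
    object@reactions$lb[i] <- value$lb
    object@reactions$ub[i] <- value$ub
    methods::validObject(object)
    object
})

#' @rdname MetabolicModel-class
#' @export
setMethod("gprRules", "MetabolicModel", function(object) object@gprs)

#' @rdname MetabolicModel-class
#' @export
setMethod("extraConstraints", "MetabolicModel",
          function(object) object@extraConstraints)

#' @rdname MetabolicModel-class
#' @export
setMethod("extraConstraints<-", "MetabolicModel", function(object, value) {
    object@extraConstraints <- value
    methods::validObject(object)
    object
})

#' @rdname MetabolicModel-class
#' @export
setMethod("reverseMap", "MetabolicModel", function(object) object@reverseMap)

#' @rdname MetabolicModel-class
#' @export
setMethod("isIrreversible", "MetabolicModel", function(object) object@irreversible)

#' @rdname MetabolicModel-class
#' @param override optional explicit character vector of exchange reaction
#'   ids, bypassing structural detection.
#' @details Exchange reactions are detected structurally: a reaction whose
#'   non-boundary stoichiometry touches exactly one species, located in the
#'   extracellular compartment (compartment id/name containing
#'   \code{"extracellular"} or equal to \code{"e"}). An explicit override
#'   list takes precedence.
#' @export
setMethod("exchangeReactions", "MetabolicModel",
          function(object, override = NULL) {
    if (!is.null(override)) {
        miss <- setdiff(override, reactionIds(object))
        if (length(miss))
            stop("override names unknown reaction(s): ",
                 paste(miss, collapse = ", "))
        return(override)
    }
    reactionIds(object)[object@reactions$isExchange]
})

#' Metabolite exchanged by each exchange reaction
#'
#' @param model a \code{MetabolicModel}.
#' @return named character vector: exchange reaction id -> species id of the
#'   single (non-boundary) metabolite it moves across the boundary.
#' @keywords internal
.exchangeSpecies <- function(model) {
    ex <- exchangeReactions(model)
    S <- stoichiometricMatrix(model)
    out <- vapply(ex, function(r) {
        sp <- rownames(S)[S[, r] != 0]
        if (length(sp) != 1L)
            stop("exchange reaction ", r, " must touch exactly one species")
        sp
    }, character(1))
    out
}

setMethod("show", "MetabolicModel", function(object) {
    cat(sprintf("MetabolicModel: %d reactions, %d species, %d genes\n",
                nrow(object@reactions), nrow(object@species),
                length(geneIds(object))))
    cat(sprintf("  %s; %d exchange reaction(s); %d extra constraint row(s)\n",
                if (object@irreversible) "irreversible" else "reversible form",
                sum(object@reactions$isExchange),
                length(object@extraConstraints)))
    invisible(object)
})

#' Split reversible reactions into forward/reverse pairs
#'
#' Rewrites each reversible reaction \code{r} (lower bound below zero) as
#' two irreversible reactions: \code{r} keeps the forward stoichiometry
#' with bounds \code{[max(0, lb), ub]} and \code{r_reverse} carries the
#' negated stoichiometry with bounds \code{[0, -lb]}. GPR rules are copied
#' to both directions and any extra linear constraint rows are rewritten
#' onto the split variables (coefficient \code{c} becomes \code{c} on the
#' forward and \code{-c} on the reverse variable), so the feasible
#' net-flux polytope is preserved. A back-map from split ids to original
#' ids is retained for \code{\link{netFlux}}.
#'
#' Exchange-ratio and growth-yield rows must be attached \emph{before}
#' this conversion (see \code{\link{attachConstraints}}); otherwise their
#' coefficients could not be placed on both directions consistently.
#'
#' @param model a reversible-form \code{MetabolicModel}.
#' @param requireExtraConstraints if \code{TRUE}, fail when no extra
#'   constraint rows are attached yet — used by the pipeline to enforce
#'   the ratio-before-splitting ordering.
#' @return an irreversible \code{MetabolicModel}.
#' @export
makeIrreversible <- function(model, requireExtraConstraints = FALSE) {
    stopifnot(methods::is(model, "MetabolicModel"))
    if (requireExtraConstraints && !length(model@extraConstraints))
        stop("ordering error: extracellular-ratio constraints must be ",
             "attached before converting to the irreversible form")
    rx <- as.data.frame(model@reactions)
    S <- model@stoichiometry
    split <- which(rx$lb < 0)
    ids <- as.character(rx$id)

    newRx <- rx
    newRx$lb <- pmax(rx$lb, 0)
    newRx$reversible <- FALSE
    mapId <- ids; mapOrig <- ids; mapDir <- rep("fwd", length(ids))
    Scols <- list(S)
    if (length(split)) {
        rev <- rx[split, , drop = FALSE]
        rev$id <- paste0(rev$id, "_reverse")
        rev$lb <- 0
        rev$ub <- -rx$lb[split]
        rev$reversible <- FALSE
        newRx <- rbind(newRx, rev)
        Scols <- c(Scols, list(-S[, split, drop = FALSE]))
        mapId <- c(mapId, rev$id)
        mapOrig <- c(mapOrig, ids[split])
        mapDir <- c(mapDir, rep("rev", length(split)))
    }
    Snew <- do.call(cbind, Scols)
    colnames(Snew) <- newRx$id

    ec <- lapply(model@extraConstraints, function(row) {
        co <- row$coefs
        extra <- co[names(co) %in% ids[split]]
        if (length(extra)) {
            revNames <- paste0(names(extra), "_reverse")
            row$coefs <- c(co, stats::setNames(-extra, revNames))
        }
        row
    })

    out <- MetabolicModel(
        species = model@species,
        reactions = newRx,
        stoichiometry = Snew,
        extraConstraints = ec,
        reverseMap = S4Vectors::DataFrame(id = mapId, original = mapOrig,
                                          direction = mapDir),
        irreversible = TRUE)
    out
}

#' Net flux of a reaction across sampled flux vectors
#'
#' For a reaction that was split into forward and reverse directions,
#' returns forward minus reverse per sample; for an irreversible reaction
#' the flux itself.
#'
#' @param object a \linkS4class{FluxSampleSet} (or a plain flux matrix with
#'   reaction rownames, via the matrix method).
#' @param reaction the \emph{original} reaction id.
#' @return numeric vector, one net flux per sample.
#' @rdname netFlux
#' @export
setMethod("netFlux", "FluxSampleSet", function(object, reaction) {
    .netFluxFromMatrix(object@fluxes, reaction, object@reverseMap)
})

#' @rdname netFlux
#' @param reverseMap split back-map as stored in the model/sample set.
#' @export
setMethod("netFlux", "matrix", function(object, reaction, reverseMap) {
    .netFluxFromMatrix(object, reaction, reverseMap)
})

.netFluxFromMatrix <- function(fluxes, reaction, reverseMap) {
    rm <- as.data.frame(reverseMap)
    mine <- rm[rm$original == reaction, , drop = FALSE]
    if (!nrow(mine)) {
        if (!reaction %in% rownames(fluxes))
            stop("unknown reaction id: ", reaction)
        return(fluxes[reaction, ])
    }
    fwd <- mine$id[mine$direction == "fwd"]
    rev <- mine$id[mine$direction == "rev"]
    out <- if (length(fwd) && fwd %in% rownames(fluxes))
        fluxes[fwd, ] else rep(0, ncol(fluxes))
    if (length(rev) && rev %in% rownames(fluxes))
        out <- out - fluxes[rev, ]
    out
}
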