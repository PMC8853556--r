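# Internal linear-programming layer.
#
# All LPs are solved over the irreversible model, whose fluxes are
# non-negative by construction, so the natural-variable form x >= 0 of the
# two-phase simplex in boot::simplex applies directly. Rows are routed to
# the <=, >= or = blocks so that every right-hand side is non-negative.

.lpStructure <- function(model) {
    stopifnot(methods::is(model, "MetabolicModel"))
    if (!isIrreversible(model))
        stop("LPs are solved on the irreversible model; call makeIrreversible() first")
    S <- as.matrix(stoichiometricMatrix(model))
    rx <- as.data.frame(model@reactions)
    G <- NULL; lo <- numeric(); hi <- numeric(); gid <- character()
    if (length(model@extraConstraints)) {
        G <- matrix(0, nrow = length(model@extraConstraints), ncol = nrow(rx),
                    dimnames = list(NULL, rx$id))
        for (k in seq_along(model@extraConstraints)) {
            ec <- model@extraConstraints[[k]]
            G[k, names(ec$coefs)] <- ec$coefs
            lo[k] <- ec$lo; hi[k] <- ec$hi
            gid[k] <- if (is.null(ec$id)) paste0("row", k) else ec$id
        }
    }
    list(S = S, lb = rx$lb, ub = rx$ub, ids = as.character(rx$id),
         G = G, glo = lo, ghi = hi, gid = gid)
}

# objective: numeric vector over reactions (or a single reaction id).
# Variables are shifted by their lower bounds (x = v - lb) so the simplex
# sees plain x >= 0 variables; equality rows with negative right-hand
# sides are sign-flipped to keep the phase-1 tableau well-posed.
.solveLP <- function(struct, objective, maximize = TRUE, eps = 1e-9) {
    n <- length(struct$ids)
    if (is.character(objective)) {
        a <- numeric(n); a[match(objective, struct$ids)] <- 1
    } else a <- objective
    lb <- struct$lb
    A1 <- NULL; b1 <- numeric(); A2 <- NULL; b2 <- numeric()
    addLE <- function(row, rhs) {
        if (rhs >= 0) { A1 <<- rbind(A1, row); b1 <<- c(b1, rhs) }
        else { A2 <<- rbind(A2, -row); b2 <<- c(b2, -rhs) }
    }
    ub <- struct$ub
    for (j in which(is.finite(ub))) {
        row <- numeric(n); row[j] <- 1
        addLE(row, ub[j] - lb[j])
    }
    if (!is.null(struct$G)) {
        Glb <- as.numeric(struct$G %*% lb)
        for (k in seq_len(nrow(struct$G))) {
            if (is.finite(struct$ghi[k]))
                addLE(struct$G[k, ], struct$ghi[k] - Glb[k])
            if (is.finite(struct$glo[k]))
                addLE(-struct$G[k, ], -(struct$glo[k] - Glb[k]))
        }
    }
    A3 <- struct$S
    b3 <- as.numeric(-A3 %*% lb)
    flip <- b3 < 0
    if (any(flip)) { A3[flip, ] <- -A3[flip, ]; b3[flip] <- -b3[flip] }
    res <- boot::simplex(a = a, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                         A3 = A3, b3 = b3,
                         maxi = maximize,
                         n.iter = 50 * (n + nrow(A3) + length(b1) +
                                        length(b2)),
                         eps = eps)
    list(status = res$solved,
         value = unname(res$value) + sum(a * lb),
         solution = stats::setNames(as.numeric(res$soln) + lb, struct$ids))
}

.assertFeasible <- function(struct, context = "model") {
    res <- .solveLP(struct, numeric(length(struct$ids)), maximize = TRUE)
    if (res$status == -1) {
        hint <- if (length(struct$gid))
            paste0(" (extra constraint rows present: ",
                   paste(struct$gid, collapse = ", "), ")")
        else ""
        stop("infeasible ", context,
             ": no flux vector satisfies the constraint set", hint,
             call. = FALSE)
    }
    invisible(res)
}
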