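# Shared builders and independent oracles for the test suite.

# Linear chain: A_e --uptake--> A_c --> B_c --> B_e --secretion-->
# One degree of freedom: the chain flux, 0..10.
tinyChainModel <- function(uptake = 10) {
    sp <- data.frame(
        id = c("A_e", "A_c", "B_c", "B_e"),
        name = c("A", "A", "B", "B"),
        compartment = c("extracellular", "cytosol", "cytosol",
                        "extracellular"),
        boundary = FALSE)
    rx <- data.frame(
        id = c("EX_A", "TA", "CONV", "TB", "EX_B"),
        lb = c(-uptake, 0, 0, 0, 0),
        ub = c(0, 1000, 1000, 1000, 1000),
        reversible = c(TRUE, FALSE, FALSE, FALSE, FALSE),
        gpr = c(NA, NA, "gC1 and gC2", NA, NA),
        isExchange = c(TRUE, FALSE, FALSE, FALSE, TRUE),
        stringsAsFactors = FALSE)
    S <- matrix(0, 4, 5, dimnames = list(sp$id, rx$id))
    S["A_e", "EX_A"] <- -1
    S["A_e", "TA"] <- -1; S["A_c", "TA"] <- 1
    S["A_c", "CONV"] <- -1; S["B_c", "CONV"] <- 1
    S["B_c", "TB"] <- -1; S["B_e", "TB"] <- 1
    S["B_e", "EX_B"] <- -1
    MetabolicModel(sp, rx, S)
}

# Brute-force Cohen's kappa oracle: explicit 3x3 contingency table.
# Same degenerate-case convention as the package documents: two constant
# raters agree (1) or contradict (-1); otherwise a chance-saturated
# margin scores 0.
bruteKappa <- function(a, b) {
    if (length(unique(a)) == 1 && length(unique(b)) == 1)
        return(if (a[1] == b[1]) 1 else -1)
    cats <- c(-1, 0, 1)
    n <- length(a)
    tab <- matrix(0, 3, 3)
    for (i in seq_len(n)) {
        r <- match(a[i], cats); c <- match(b[i], cats)
        tab[r, c] <- tab[r, c] + 1
    }
    tab <- tab / n
    po <- sum(diag(tab))
    pe <- sum(rowSums(tab) * colSums(tab))
    if (abs(1 - pe) < 1e-12) return(0)
    (po - pe) / (1 - pe)
}

# Textbook step-up Benjamini-Hochberg oracle.
bhTextbook <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- numeric(n)
    sorted <- p[o] * n / seq_len(n)
    # enforce monotonicity from the largest rank down
    for (i in n:1)
        adj[i] <- if (i == n) sorted[i] else min(sorted[i], adj[i + 1])
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
}

# Independent FVA oracle on the *reversible* model: shift x = v - lb >= 0
# and call the two-phase simplex directly.
reversibleFluxRange <- function(model, rid) {
    S <- as.matrix(stoichiometricMatrix(model))
    b <- reactionBounds(model)
    shiftRhs <- as.numeric(-S %*% b$lb)
    neg <- shiftRhs < 0          # simplex wants non-negative equality rhs
    S[neg, ] <- -S[neg, ]; shiftRhs[neg] <- -shiftRhs[neg]
    n <- nrow(b)
    A1 <- diag(n); b1 <- b$ub - b$lb
    obj <- numeric(n); obj[match(rid, b$id)] <- 1
    solve1 <- function(maxi) {
        res <- boot::simplex(a = obj, A1 = A1, b1 = b1, A3 = S, b3 = shiftRhs,
                             maxi = maxi, n.iter = 100 * (n + nrow(S)))
        stopifnot(res$solved == 1)
        unname(res$value + b$lb[match(rid, b$id)])
    }
    c(min = solve1(FALSE), max = solve1(TRUE))
}
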