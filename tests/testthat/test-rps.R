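.rpsToyModel <- function() {
    # irreversible two-substrate reaction plus a compartment pair
    m <- makeIrreversible(generateToyModel(nBranches = 1))
    m
}

test_that("metabolite mapping handles compartments, exact ids and misses", {
    m <- .rpsToyModel()
    ab <- matrix(c(3, 5, 7), nrow = 3,
                 dimnames = list(c("cit", "glc__weird", "pyr_c"), "g1__s1"))
    nameMap <- data.frame(name = "cit", species = c("cit_c", "cit_m"))
    expect_warning(asg <- mapMetabolites(m, ab, nameMap), "glc__weird")
    # one measurement lands on both compartmental species
    expect_equal(asg["cit_c", ], asg["cit_m", ])
    expect_equal(unname(asg["cit_c", ]), 3)
    expect_equal(unname(asg["pyr_c", ]), 7)     # exact id match
    expect_false("glc__weird" %in% rownames(asg))
    expect_error(
        mapMetabolites(m, ab, data.frame(name = "cit", species = "nope")),
        "unknown species")
    expect_error(mapMetabolites(m, -ab), "non-negative")
})

test_that("one missing substrate removes a reaction from the dataset", {
    m <- .rpsToyModel()
    measured <- matrix(1, nrow = 2, ncol = 1,
                       dimnames = list(c("pyr_c", "lac_c"), "g1__s1"))
    elig <- eligibleReactions(m, measured)
    expect_true("LDH" %in% elig)        # substrate pyr_c measured
    expect_false("GLYC" %in% elig)      # substrate glc_c not measured
    expect_false("GDH" %in% elig)       # glu_c not measured
    # exclusion list excuses a substrate
    elig2 <- eligibleReactions(m, measured, exclusionList = "glc_c")
    expect_true("GLYC" %in% elig2)
    # explicit exclusion wins over eligibility
    expect_false("LDH" %in%
        eligibleReactions(m, measured, excludeReactions = "LDH"))
    expect_error(eligibleReactions(generateToyModel(), measured),
                 "irreversible")
})

test_that("eligibility shrinks monotonically as measurements are removed", {
    m <- .rpsToyModel()
    allSp <- matrix(1, nrow = length(speciesIds(m)), ncol = 1,
                    dimnames = list(speciesIds(m), "g__s1"))
    prev <- eligibleReactions(m, allSp)
    keep <- rownames(allSp)
    set.seed(9)
    for (i in 1:5) {
        keep <- setdiff(keep, sample(keep, 2))
        cur <- eligibleReactions(m, allSp[keep, , drop = FALSE])
        expect_true(all(cur %in% prev))
        prev <- cur
    }
})

test_that("RPS is the substrate mass-action product", {
    sp <- data.frame(id = c("S1_c", "S2_c", "P_c"), name = c("S1", "S2", "P"),
                     compartment = "cytosol", boundary = FALSE)
    rx <- data.frame(id = c("R2s", "R1s", "SINK"),
                     lb = 0, ub = 10, reversible = FALSE, gpr = NA,
                     isExchange = FALSE)
    S <- matrix(0, 3, 3, dimnames = list(sp$id, rx$id))
    S["S1_c", "R2s"] <- -1; S["S2_c", "R2s"] <- -2; S["P_c", "R2s"] <- 1
    S["S2_c", "R1s"] <- -1; S["P_c", "R1s"] <- 1
    S["P_c", "SINK"] <- -1
    m <- MetabolicModel(sp, rx, S, irreversible = TRUE)
    ab <- matrix(c(2, 3, 1, 4, 0, 1), nrow = 3,
                 dimnames = list(c("S1_c", "S2_c", "P_c"),
                                 c("g1__s1", "g2__s1")))
    tab <- computeRPS(m, ab, c("g1", "g2"))
    sc <- SummarizedExperiment::assay(tab, "score")
    expect_equal(unname(sc["R2s", "g1__s1"]), 2 * 3^2)   # 18
    expect_equal(unname(sc["R1s", "g1__s1"]), 3)         # single substrate
    expect_equal(unname(sc["R2s", "g2__s1"]), 0)         # zero absorbing
    expect_equal(scoreType(tab), "RPS")
})

test_that("RPS ratios factorize over substrate ratios (kinetic constant cancels)", {
    m <- .rpsToyModel()
    S <- stoichiometricMatrix(m)
    sub <- rownames(S)[S[, "GLYC"] < 0]
    set.seed(21)
    spAll <- speciesIds(m)
    for (rep in 1:10) {
        x1 <- matrix(stats::runif(length(spAll), 0.5, 10), ncol = 1,
                     dimnames = list(spAll, "a__s1"))
        x2 <- matrix(stats::runif(length(spAll), 0.5, 10), ncol = 1,
                     dimnames = list(spAll, "b__s1"))
        ab <- cbind(x1, x2)
        tab <- computeRPS(m, ab, c("a", "b"))
        sc <- SummarizedExperiment::assay(tab)
        lhs <- sc["GLYC", 1] / sc["GLYC", 2]
        rhs <- prod((x1[sub, 1] / x2[sub, 1]) ^ abs(S[sub, "GLYC"]))
        expect_equal(unname(lhs), unname(rhs))
    }
})

test_that("RPS is scale-covariant with exponent sum", {
    m <- .rpsToyModel()
    spAll <- speciesIds(m)
    ab <- matrix(2, nrow = length(spAll), ncol = 1,
                 dimnames = list(spAll, "g__s1"))
    t1 <- SummarizedExperiment::assay(computeRPS(m, ab, "g"))
    t2 <- SummarizedExperiment::assay(computeRPS(m, 3 * ab, "g"))
    S <- stoichiometricMatrix(m)
    for (r in rownames(t1)) {
        expoSum <- sum(abs(S[S[, r] < 0, r]))
        expect_equal(unname(t2[r, 1]), unname(t1[r, 1]) * 3 ^ expoSum)
    }
})
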