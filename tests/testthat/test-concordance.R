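test_that("variation signs require both significance and the 20% rule", {
    # identical distributions: never significant
    x <- c(1, 1.1, 0.9, 1.05, 0.95)
    expect_equal(variationSign(x, x, "samples"), 0L)
    # medians 12 vs 10 (ratio exactly 1.2, the boundary) with tiny spread
    set.seed(1)
    a <- 12 + stats::rnorm(60, 0, 0.01)
    b <- 10 + stats::rnorm(60, 0, 0.01)
    a <- a * 12 / stats::median(a); b <- b * 10 / stats::median(b)
    expect_equal(variationSign(a, b, "distribution"), 1L)
    # means 10 vs 13: ratio 0.769 <= 0.8 and significant
    expect_equal(variationSign(c(9.9, 10, 10.1), c(12.9, 13, 13.1),
                               "samples"), -1L)
    # significant but under 20%: no sign
    expect_equal(variationSign(rep(c(10, 10.01), 10), rep(c(11, 11.01), 10),
                               "samples"), 0L)
    # fewer than 2 samples: undefined, warns
    expect_warning(s <- variationSign(5, c(1, 2), "samples"), "undefined")
    expect_equal(s, 0L)
})

test_that("pair enumeration is lexicographic and C(n,2)-sized", {
    expect_equal(nrow(orderedGroupPairs(c("b", "a"))), 1L)
    expect_equal(orderedGroupPairs(c("b", "a"))$label, "a|b")
    expect_equal(nrow(orderedGroupPairs(letters[1:3])), 3L)
    p5 <- orderedGroupPairs(paste0("line", 1:5))
    expect_equal(nrow(p5), 10L)
    expect_error(orderedGroupPairs("only"), "at least 2")
})

test_that("sign matrices share pair ordering across datasets", {
    set.seed(8)
    groups <- rep(c("g1", "g2", "g3"), each = 4)
    mk <- function(shift) {
        m <- matrix(stats::rlnorm(24, 0, 0.05), nrow = 2,
                    dimnames = list(c("r1", "r2"),
                                    paste0(groups, "__s", 1:4)))
        m["r1", groups == "g3"] <- m["r1", groups == "g3"] * shift
        m
    }
    tabA <- ScoreTable(mk(3), groups, "RAS")
    tabB <- ScoreTable(mk(3), groups, "RPS")
    sA <- pairwiseSignMatrix(tabA)
    sB <- pairwiseSignMatrix(tabB)
    expect_identical(groupPairs(sA), groupPairs(sB))
    expect_equal(groupPairs(sA), c("g1|g2", "g1|g3", "g2|g3"))
    # g3 is 3x higher on r1: pairs (g1,g3) and (g2,g3) called -1
    expect_equal(unname(signValues(sA)["r1", ]), c(0L, -1L, -1L))
})

test_that("Cohen's kappa matches its analytic extremes and worked example", {
    v <- c(1, 1, 0, -1, 0, 1, -1, 0, 1, 1)
    expect_equal(cohensKappa(v, v), 1)
    a <- c(rep(1, 5), rep(-1, 5))
    expect_equal(cohensKappa(a, -a), -1)
    # hand-computed contingency example: po = 0.75, pe = 0.3125
    expect_equal(cohensKappa(c(1, 1, 0, -1), c(1, 0, 0, -1)),
                 (0.75 - 0.3125) / (1 - 0.3125))
    expect_equal(cohensKappa(c(1, 1, 0, -1), c(1, 0, 0, -1)), 7 / 11)
    expect_error(cohensKappa(numeric(), numeric()), "non-empty")
})

test_that("kappa equals the brute-force contingency oracle on random pairs", {
    set.seed(123)
    for (i in 1:1000) {
        a <- sample(c(-1, 0, 1), 10, replace = TRUE)
        b <- sample(c(-1, 0, 1), 10, replace = TRUE)
        expect_equal(cohensKappa(a, b), bruteKappa(a, b))
    }
})

test_that("kappa is symmetric, relabel-invariant, and degenerate-safe", {
    set.seed(77)
    for (i in 1:50) {
        a <- sample(c(-1, 0, 1), 8, replace = TRUE)
        b <- sample(c(-1, 0, 1), 8, replace = TRUE)
        expect_equal(cohensKappa(a, b), cohensKappa(b, a))
        # swap the +1/-1 labels on both raters: kappa unchanged
        expect_equal(cohensKappa(-a, -b), cohensKappa(a, b))
        if (length(unique(a)) > 1) expect_equal(cohensKappa(a, a), 1)
    }
    expect_equal(cohensKappa(rep(0, 5), rep(0, 5)), 1)
    expect_equal(cohensKappa(rep(1, 5), rep(-1, 5)), -1)
})

test_that("empirical null p-values follow the add-one formula", {
    zeros <- matrix(0L, nrow = 3, ncol = 3,
                    dimnames = list(c("r1", "r2", "r3"),
                                    c("a|b", "a|c", "b|c")))
    rps <- methods::new("SignMatrix", dataset = "RPS", signs = zeros,
                        groups = c("a", "b", "c"))
    ffdM <- zeros; ffdM["r1", ] <- c(1L, 0L, -1L)
    ffd <- methods::new("SignMatrix", dataset = "FFD", signs = ffdM,
                        groups = c("a", "b", "c"))
    # null draws are all-zero vectors; kappa(0-vector, non-constant) = 0,
    # so an observed kappa of 1 beats every null draw
    p <- empiricalNullPvalues(rps, ffd, c(r1 = 1), nResamples = 1000,
                              seed = 5)
    expect_equal(unname(p), 1 / 1001)
    # an observed kappa below every null value gives p = 1
    pLow <- empiricalNullPvalues(rps, ffd, c(r1 = -1), nResamples = 1000,
                                 seed = 5)
    expect_equal(unname(pLow), 1)
    # determinism
    p2 <- empiricalNullPvalues(rps, ffd, c(r1 = 1), nResamples = 1000,
                               seed = 5)
    expect_identical(p, p2)
    empty <- methods::new("SignMatrix", dataset = "RPS",
                          signs = zeros[0, , drop = FALSE],
                          groups = c("a", "b", "c"))
    expect_error(empiricalNullPvalues(empty, ffd, c(r1 = 1)), "empty")
})

test_that("BH adjustment matches the textbook step-up procedure", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.3), 0.3)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    set.seed(42)
    for (i in 1:50) {
        p <- stats::runif(sample(3:30, 1))
        expect_equal(bhAdjust(p), bhTextbook(p))
    }
    # monotone in the order statistics
    p <- stats::runif(20)
    adj <- bhAdjust(p)
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj >= p - 1e-12))
})

test_that("quadrant classification follows the concordance thresholds", {
    expect_equal(classifyReactions(0.5, 0.5, 0.9), "concerted")
    expect_equal(classifyReactions(0.5, -0.1, 0.1), "metabolic_only")
    expect_equal(classifyReactions(0.5, NA, NA), "metabolic_only")
    expect_equal(classifyReactions(-0.3, -0.3, 0.7), "transcriptional_only")
    expect_equal(classifyReactions(-0.4, 0.6, 0.0), "other")
    expect_equal(classifyReactions(0.1, 0.1, 0.05), "inconclusive")
    # threshold is a parameter
    expect_equal(classifyReactions(0.15, 0.15, 0, threshold = 0.1),
                 "concerted")
})
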