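test_that("a single free flux is sampled uniformly on its interval", {
    mi <- makeIrreversible(tinyChainModel())
    fs <- sampleFluxes(mi, "g", nTotal = 10000L, nBatches = 10L,
                       thinning = 10L, seed = 7)
    v <- fluxes(fs)["CONV", ]
    expect_length(v, 10000L)
    # uniform [0, 10]: mean 5 within Monte-Carlo tolerance
    expect_gt(mean(v), 4.5)
    expect_lt(mean(v), 5.5)
    ks <- suppressWarnings(stats::ks.test(v, "punif", 0, 10))
    expect_lt(unname(ks$statistic), 0.05)
})

test_that("sampling is deterministic given the seed", {
    mi <- makeIrreversible(tinyChainModel())
    f1 <- sampleFluxes(mi, "g", nTotal = 500L, seed = 3)
    f2 <- sampleFluxes(mi, "g", nTotal = 500L, seed = 3)
    expect_identical(fluxes(f1), fluxes(f2))
    f3 <- sampleFluxes(mi, "g", nTotal = 500L, seed = 4)
    expect_false(identical(fluxes(f1), fluxes(f3)))
})

test_that("a point polytope returns its vertex repeated, with a warning", {
    m <- tinyChainModel()
    b <- reactionBounds(m)
    b["CONV", c("lb", "ub")] <- c(5, 5)   # pin the chain flux
    reactionBounds(m) <- b
    mi <- makeIrreversible(m)
    expect_warning(fs <- sampleFluxes(mi, "g", nTotal = 50L), "single point")
    expect_equal(unname(fluxes(fs)["CONV", ]), rep(5, 50))
    expect_equal(unname(fluxes(fs)["TB", ]), rep(5, 50))
})

test_that("verifySamples detects corrupted flux vectors by index", {
    mi <- makeIrreversible(tinyChainModel())
    fs <- sampleFluxes(mi, "g", nTotal = 200L, seed = 2)
    rep0 <- verifySamples(mi, fs, tol = 1e-6)
    expect_true(rep0$pass)
    expect_lte(rep0$maxEquality, 1e-6)
    expect_lte(rep0$maxBound, 1e-6)
    V <- fluxes(fs)
    V["CONV", 17] <- V["CONV", 17] + 1   # break mass balance
    repBad <- verifySamples(mi, V)
    expect_false(repBad$pass)
    expect_true(17 %in% repBad$badSamples)
    expect_warning(out <- verifySamples(mi, V[, 0]), "empty")
    expect_true(out$pass)
})

test_that("growth yield is the protein-over-glucose gram ratio, median-summarized", {
    y <- growthYieldConstraint("BIOMASS", "EX_glc")
    gram <- y$mwGlc * 0.001
    mkSet <- function(ratios, cons = 10) {
        vBio <- ratios * cons * gram / y$proteinFraction
        V <- rbind(BIOMASS = vBio, EX_glc = rep(0, length(vBio)),
                   EX_glc_reverse = rep(cons, length(vBio)))
        methods::new("FluxSampleSet", group = "g", fluxes = V,
                     batch = rep(1L, ncol(V)), nBatches = 1L, thinning = 1L,
                     seed = 1L, tolerance = 1e-6,
                     reverseMap = S4Vectors::DataFrame(
                         id = c("EX_glc", "EX_glc_reverse"),
                         original = c("EX_glc", "EX_glc"),
                         direction = c("fwd", "rev")))
    }
    # every sample exactly at the minimum yield
    gy <- growthYield(mkSet(rep(3.90762e-5, 5)), y)
    expect_equal(gy$median, 3.90762e-5)
    expect_equal(growthYield(mkSet(rep(1e-4, 7)), y)$median, 1e-4)
    expect_equal(growthYield(mkSet(c(1e-4, 5e-5, 1.5e-4)), y)$median, 1e-4)
    # zero-consumption samples are excluded and counted
    mixed <- mkSet(c(1e-4, 1e-4))
    mixed@fluxes["EX_glc_reverse", 2] <- 0
    gy2 <- growthYield(mixed, y)
    expect_equal(gy2$nExcluded, 1L)
    zero <- mkSet(1e-4)
    zero@fluxes["EX_glc_reverse", 1] <- 0
    expect_error(growthYield(zero, y), "below tolerance")
})

test_that("all samples of a constrained model respect ratio rows and the yield bracket", {
    m <- generateToyModel(nBranches = 1)
    sc <- plantedScenario("concerted", seed = 2)
    om <- generatePlantedOmics(m, sc)
    y <- growthYieldConstraint("BIOMASS", "EX_glc")
    built <- buildCellRelativeModels(m, om$expression, om$groups,
                                     medium = om$medium, spent = om$spent,
                                     fluxIds = om$fluxIds, yield = y)
    fs <- sampleFluxes(built$models$g1, "g1", nTotal = 2000L, seed = 11)
    rep1 <- verifySamples(built$models$g1, fs, tol = 1e-6)
    expect_true(rep1$pass)   # includes ratio and yield rows
    # condition the ratio on non-vanishing consumption so the quotient is
    # numerically meaningful, then check the bracket
    gy <- growthYield(fs, y, tol = 1e-3)
    expect_true(all(gy$yields >= y$minYield * (1 - 1e-4)))
    expect_true(all(gy$yields <= y$maxYield * (1 + 1e-4)))
})
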