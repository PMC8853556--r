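test_that("medium constraints scale uptake bounds by relative concentration", {
    m <- tinyChainModel()
    medium <- data.frame(species = "A_e", group = c("A", "B"),
                         conc = c(25, 17.5))
    ms <- applyMediumConstraints(m, medium, baseUptake = 10)
    expect_equal(reactionBounds(ms$A)["EX_A", "lb"], -10)
    expect_equal(reactionBounds(ms$B)["EX_A", "lb"], -7)
    # secretion bound untouched
    expect_equal(reactionBounds(ms$A)["EX_B", "ub"], 1000)
    # equal concentrations give equal bounds
    medium2 <- data.frame(species = "A_e", group = c("A", "B"), conc = 5)
    ms2 <- applyMediumConstraints(m, medium2, 10)
    expect_equal(reactionBounds(ms2$A)["EX_A", "lb"],
                 reactionBounds(ms2$B)["EX_A", "lb"])
    expect_error(
        applyMediumConstraints(m, data.frame(species = "Z_e", group = "A",
                                             conc = 1)),
        "Z_e")
})

test_that("metabolites absent from a group's medium cannot be taken up", {
    m <- tinyChainModel()
    medium <- data.frame(species = c("A_e", "A_e"), group = c("A", "B"),
                         conc = c(10, 0))
    ms <- applyMediumConstraints(m, medium, 10)
    expect_equal(reactionBounds(ms$B)["EX_A", "lb"], 0)
})

test_that("ratio constraints: technical means, then mean/sd over biological reps", {
    fluxIds <- c(glucose = "EX_glc", glutamine = "EX_gln",
                 lactate = "EX_lac", glutamate = "EX_glu")
    mk <- function(br, tr, lac48) data.frame(
        group = "g1", bioRep = br, techRep = tr,
        metabolite = c("glucose", "glutamine", "lactate", "glutamate"),
        t0 = c(25, 4, 0, 0), t48 = c(15, 2, lac48, 0.4))
    # bio-rep ratios 0.9 and 1.1 (lactate produced 9 and 11 over 10 consumed)
    spent <- rbind(mk(1, 1, 9), mk(2, 1, 11))
    rc <- deriveRatioConstraints(spent, fluxIds)
    lg <- rc[rc$ratio == "lac/glc", ]
    expect_equal(lg$xbar, 1.0)
    expect_equal(lg$sigma, stats::sd(c(0.9, 1.1)))  # sample sd, 0.1414...
    # identical replicates collapse to an equality
    rc0 <- deriveRatioConstraints(rbind(mk(1, 1, 18), mk(2, 1, 18)), fluxIds)
    expect_equal(rc0[rc0$ratio == "lac/glc", "sigma"], 0)
    expect_equal(rc0[rc0$ratio == "lac/glc", "xbar"], 1.8)  # (18-0)/(25-15)
    # glutamine-based ratios
    expect_equal(rc0[rc0$ratio == "lac/gln", "xbar"], 9)
    expect_equal(rc0[rc0$ratio == "glu/gln", "xbar"], 0.2)
    # technical replicates are averaged inside each biological replicate
    rcT <- deriveRatioConstraints(rbind(mk(1, 1, 8), mk(1, 2, 10),
                                        mk(2, 1, 11)), fluxIds)
    expect_equal(rcT[rcT$ratio == "lac/glc", "xbar"], mean(c(0.9, 1.1)))
    # single biological replicate: sd undefined
    expect_error(deriveRatioConstraints(mk(1, 1, 9), fluxIds),
                 "fewer than 2 biological replicates")
    expect_equal(
        deriveRatioConstraints(mk(1, 1, 9), fluxIds, sigmaFallback = 0.05)$sigma,
        rep(0.05, 3))
})

test_that("attached rows encode the ratio band and the yield bracket", {
    m <- generateToyModel(nBranches = 1)
    ratios <- data.frame(group = "g1", ratio = "lac/glc",
                         numerator = "EX_lac", denominator = "EX_glc",
                         xbar = 1, sigma = 0.1)
    y <- growthYieldConstraint("BIOMASS", "EX_glc")
    m2 <- attachConstraints(m, ratios, y)
    ec <- extraConstraints(m2)
    expect_length(ec, 3L)
    ratioRow <- ec[[1]]
    # secretion positive, uptake negative: v_lac + xbar * v_glc in [-s, s]
    expect_equal(ratioRow$coefs, c(EX_lac = 1, EX_glc = 1))
    expect_equal(c(ratioRow$lo, ratioRow$hi), c(-0.1, 0.1))
    # a flux with lactate = xbar * consumption sits at the row's center
    expect_equal(unname(sum(ratioRow$coefs * c(EX_lac = 7, EX_glc = -7))), 0)
    yMin <- ec[[2]]; yMax <- ec[[3]]
    expect_equal(unname(yMin$coefs["BIOMASS"]), 0.131972)
    expect_equal(unname(yMin$coefs["EX_glc"]), 3.90762e-5 * 180.16 * 0.001)
    expect_equal(unname(yMax$coefs["EX_glc"]), 1.67998e-4 * 180.16 * 0.001)
    expect_equal(c(yMin$lo, yMin$hi), c(0, Inf))
    expect_equal(c(yMax$lo, yMax$hi), c(-Inf, 0))
    # boundary case: biomass at exactly the minimum yield satisfies yield_min
    cons <- 10
    vBio <- 3.90762e-5 * cons * 180.16 * 0.001 / 0.131972
    lhs <- sum(yMin$coefs * c(BIOMASS = vBio, EX_glc = -cons))
    expect_equal(lhs, 0, tolerance = 1e-15)
    expect_error(attachConstraints(m, ratios = data.frame(
        group = "g", ratio = "x", numerator = "nope", denominator = "EX_glc",
        xbar = 1, sigma = 1)), "unknown flux id")
})

test_that("FVA brackets a linear chain, blocked reactions and parallel paths", {
    mi <- makeIrreversible(tinyChainModel())
    fva <- runFVA(mi)
    # every chain reaction spans [0, 10] (flow conservation)
    for (r in c("EX_A_reverse", "TA", "CONV", "TB", "EX_B"))
        expect_equal(unname(unlist(fva[r, c("min", "max")])), c(0, 10))
    expect_equal(unname(unlist(fva["EX_A", c("min", "max")])), c(0, 0))

    # dead-end metabolite: blocked reaction pinned at [0, 0]
    sp <- data.frame(id = c("A_e", "A_c", "D_c"), name = c("A", "A", "D"),
                     compartment = c("extracellular", "cytosol", "cytosol"),
                     boundary = FALSE)
    rx <- data.frame(id = c("EX_A", "TA", "DEAD"),
                     lb = c(-10, 0, 0), ub = c(1000, 1000, 1000),
                     reversible = c(TRUE, FALSE, FALSE), gpr = NA,
                     isExchange = c(TRUE, FALSE, FALSE))
    S <- matrix(0, 3, 3, dimnames = list(sp$id, rx$id))
    S["A_e", "EX_A"] <- -1
    S["A_e", "TA"] <- -1; S["A_c", "TA"] <- 1
    S["A_c", "DEAD"] <- -1; S["D_c", "DEAD"] <- 1
    fvaD <- runFVA(makeIrreversible(MetabolicModel(sp, rx, S)))
    expect_equal(unname(unlist(fvaD["DEAD", c("min", "max")])), c(0, 0))

    # two parallel branches sharing one uptake: each branch spans [0, 10]
    sp2 <- data.frame(id = c("A_e", "A_c", "B_e"), name = c("A", "A", "B"),
                      compartment = c("extracellular", "cytosol",
                                      "extracellular"),
                      boundary = FALSE)
    rx2 <- data.frame(id = c("EX_A", "TA", "P1", "P2", "EX_B"),
                      lb = c(-10, 0, 0, 0, 0), ub = c(0, 1000, 1000, 1000, 1000),
                      reversible = c(TRUE, rep(FALSE, 4)), gpr = NA,
                      isExchange = c(TRUE, FALSE, FALSE, FALSE, TRUE))
    S2 <- matrix(0, 3, 5, dimnames = list(sp2$id, rx2$id))
    S2["A_e", "EX_A"] <- -1
    S2["A_e", "TA"] <- -1; S2["A_c", "TA"] <- 1
    S2["A_c", "P1"] <- -1; S2["B_e", "P1"] <- 1
    S2["A_c", "P2"] <- -1; S2["B_e", "P2"] <- 1
    S2["B_e", "EX_B"] <- -1
    fva2 <- runFVA(makeIrreversible(MetabolicModel(sp2, rx2, S2)))
    expect_equal(unname(unlist(fva2["P1", c("min", "max")])), c(0, 10))
    expect_equal(unname(unlist(fva2["P2", c("min", "max")])), c(0, 10))
})

test_that("infeasible constraint sets are reported, not silently sampled", {
    m <- tinyChainModel()
    extraConstraints(m) <- list(list(id = "impossible",
                                     coefs = c(CONV = 1), lo = 20, hi = 30))
    mi <- makeIrreversible(m)
    expect_error(runFVA(mi), "infeasible")
})

test_that("RAS bounds shrink proportionally and respect exemptions", {
    mi <- makeIrreversible(tinyChainModel())
    fva <- runFVA(mi)
    # CONV carries a GPR: scaled; others keep the FVA interval
    m2 <- applyRasBounds(mi, c(CONV = 0.5), fva)
    expect_equal(reactionBounds(m2)["CONV", "ub"], 5)        # 0.5 * 10
    expect_equal(reactionBounds(m2)["TA", "ub"], 10)         # rule-free
    # exemption: null score must not close the reaction
    m3 <- applyRasBounds(mi, c(CONV = 0), fva, exemptList = "CONV")
    expect_equal(reactionBounds(m3)["CONV", "ub"], 10)
    m4 <- applyRasBounds(mi, c(CONV = 0), fva)
    expect_equal(reactionBounds(m4)["CONV", "ub"], 0)
    expect_error(applyRasBounds(mi, c(CONV = 1.4), fva), "\\[0, 1\\]")
})

test_that("transcriptomic layer only ever tightens the feasible region", {
    m <- generateToyModel(nBranches = 2)
    sc <- plantedScenario(c("transcriptional_only", "concerted"), seed = 3)
    om <- generatePlantedOmics(m, sc)
    y <- growthYieldConstraint("BIOMASS", "EX_glc")
    built <- buildCellRelativeModels(m, om$expression, om$groups,
                                     medium = om$medium, spent = om$spent,
                                     fluxIds = om$fluxIds, yield = y)
    for (g in names(built$models)) {
        b <- reactionBounds(built$models[[g]])
        fva <- built$fva[[g]]
        expect_true(all(b[fva$id, "lb"] >= fva$min - 1e-9))
        expect_true(all(b[fva$id, "ub"] <= fva$max + 1e-9))
    }
})

test_that("an all-ones RAS layer is a no-op on the type-1+2 region", {
    m <- generateToyModel(nBranches = 1)
    sc <- plantedScenario("metabolic_only", noiseSd = 0, effectSize = 1)
    om <- generatePlantedOmics(m, sc)
    y <- growthYieldConstraint("BIOMASS", "EX_glc")
    with3 <- buildCellRelativeModels(m, om$expression, om$groups,
                                     medium = om$medium, spent = om$spent,
                                     fluxIds = om$fluxIds, yield = y,
                                     type3 = TRUE)
    # zero noise, no effect: every normalized RAS is exactly 1
    expect_true(all(with3$rasBar == 1))
    no3 <- buildCellRelativeModels(m, om$expression, om$groups,
                                   medium = om$medium, spent = om$spent,
                                   fluxIds = om$fluxIds, yield = y,
                                   type3 = FALSE)
    for (g in names(with3$models))
        expect_equal(reactionBounds(with3$models[[g]]),
                     reactionBounds(no3$models[[g]]))
})

test_that("type 2 can be omitted while keeping type 3", {
    m <- generateToyModel(nBranches = 1)
    sc <- plantedScenario("concerted", seed = 5)
    om <- generatePlantedOmics(m, sc)
    built <- buildCellRelativeModels(m, om$expression, om$groups,
                                     medium = om$medium, type2 = FALSE)
    expect_named(built$models, c("g1", "g2", "g3"))
    expect_length(extraConstraints(built$models$g1), 0L)
})
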