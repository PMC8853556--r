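test_that("model invariants are enforced by the validity method", {
    m <- tinyChainModel()
    expect_true(methods::validObject(m))
    expect_equal(reactionIds(m), c("EX_A", "TA", "CONV", "TB", "EX_B"))
    expect_equal(sort(geneIds(m)), c("gC1", "gC2"))
    # lb > ub is rejected
    b <- reactionBounds(m)
    b["CONV", c("lb", "ub")] <- c(5, 1)
    expect_error(reactionBounds(m) <- b, "lb <= ub")
    expect_error({
        bad <- m
        bad@species$compartment[1] <- ""
        methods::validObject(bad)
    }, "non-empty")
})

test_that("exchange reactions are detected structurally", {
    m <- tinyChainModel()
    expect_setequal(exchangeReactions(m), c("EX_A", "EX_B"))
    expect_equal(exchangeReactions(m, override = "TA"), "TA")
    expect_error(exchangeReactions(m, override = "nope"), "unknown")
})

test_that("irreversibilization splits negative-lb reactions with _reverse", {
    sp <- data.frame(id = "X_e", name = "X", compartment = "extracellular",
                     boundary = FALSE)
    rx <- data.frame(id = "R1", lb = -5, ub = 10, reversible = TRUE,
                     gpr = "gA or gB", isExchange = TRUE)
    S <- matrix(-1, 1, 1, dimnames = list("X_e", "R1"))
    m <- MetabolicModel(sp, rx, S)
    mi <- makeIrreversible(m)
    b <- reactionBounds(mi)
    expect_equal(b["R1", c("lb", "ub")], data.frame(lb = 0, ub = 10,
                 row.names = "R1"))
    expect_equal(b["R1_reverse", c("lb", "ub")],
                 data.frame(lb = 0, ub = 5, row.names = "R1_reverse"))
    # GPR copied to both directions; stoichiometry negated on the reverse
    expect_equal(gprToString(gprRules(mi)[["R1_reverse"]]), "gA or gB")
    expect_equal(as.numeric(stoichiometricMatrix(mi, boundary = TRUE)),
                 c(-1, 1))
    rm <- as.data.frame(reverseMap(mi))
    expect_equal(rm$original[rm$id == "R1_reverse"], "R1")
})

test_that("fully irreversible models pass through unchanged in count", {
    sp <- data.frame(id = c("X_e", "Y_c"), name = c("X", "Y"),
                     compartment = c("extracellular", "cytosol"),
                     boundary = FALSE)
    rx <- data.frame(id = c("T1", "T2"), lb = c(0, 0), ub = c(10, 10),
                     reversible = FALSE, gpr = NA, isExchange = FALSE)
    S <- matrix(c(-1, 1, 1, -1), 2, 2, dimnames = list(sp$id, rx$id))
    m <- MetabolicModel(sp, rx, S)
    expect_equal(length(reactionIds(makeIrreversible(m))), 2L)
})

test_that("splitting 2 of 5 reversible reactions yields 7", {
    m <- tinyChainModel()   # EX_A has lb < 0
    b <- reactionBounds(m)
    b["CONV", "lb"] <- -3   # make a second reaction reversible
    reactionBounds(m) <- b
    expect_equal(length(reactionIds(makeIrreversible(m))), 7L)
})

test_that("irreversibilization preserves the net-flux polytope", {
    m <- generateToyModel(nBranches = 1)
    mi <- makeIrreversible(m)
    struct <- fluxcord:::.lpStructure(mi)
    rmap <- as.data.frame(reverseMap(mi))
    for (rid in c("GDH", "EX_glc", "GLYC", "BIOMASS")) {
        oracle <- reversibleFluxRange(m, rid)
        obj <- numeric(length(struct$ids))
        obj[match(rid, struct$ids)] <- 1
        revId <- rmap$id[rmap$original == rid & rmap$direction == "rev"]
        if (length(revId)) obj[match(revId, struct$ids)] <- -1
        mx <- fluxcord:::.solveLP(struct, obj, maximize = TRUE)
        mn <- fluxcord:::.solveLP(struct, obj, maximize = FALSE)
        expect_equal(mx$value, unname(oracle["max"]), tolerance = 1e-6)
        expect_equal(mn$value, unname(oracle["min"]), tolerance = 1e-6)
    }
})

test_that("ordering guard fires when ratio rows are required but absent", {
    m <- tinyChainModel()
    expect_error(makeIrreversible(m, requireExtraConstraints = TRUE),
                 "ordering error")
})

test_that("netFlux combines split directions and handles plain fluxes", {
    rm <- S4Vectors::DataFrame(id = c("R1", "R1_reverse"),
                               original = c("R1", "R1"),
                               direction = c("fwd", "rev"))
    V <- matrix(c(4, 1.5, 0, 2, 3, 0), nrow = 3,
                dimnames = list(c("R1", "R1_reverse", "other"), NULL))
    expect_equal(netFlux(V, "R1", rm), c(2.5, -1))
    expect_equal(netFlux(V, "other", rm), c(0, 0))
    expect_error(netFlux(V, "nope", rm), "unknown reaction")
})
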