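#' Generate a toy metabolic model
#'
#' Builds a small (~20 reaction) network exercising every structural
#' feature the pipeline consumes: nutrient and secretion exchanges, a
#' glycolysis-like backbone with AND/OR GPR rules, a rule-free
#' transporter, one reversible internal reaction, a biomass sink, an
#' optional cytosol/mitochondrion duplicated species pair (citrate), and
#' \code{nBranches} independent uptake-conversion-secretion branches
#' (\code{EX_n<i> -> Nt<i> -> R<i> -> Wt}) on which regulation scenarios
#' can be planted without perturbing the backbone.
#'
#' @param nBranches number of plantable branches (>= 1).
#' @param withCompartments include the mitochondrial citrate pair.
#' @return a reversible-form \linkS4class{MetabolicModel}.
#' @export
generateToyModel <- function(nBranches = 2L, withCompartments = TRUE) {
    stopifnot(nBranches >= 1L)
    ext <- function(id, nm) data.frame(id = id, name = nm,
                                       compartment = "extracellular")
    cyt <- function(id, nm) data.frame(id = id, name = nm,
                                       compartment = "cytosol")
    sp <- rbind(
        ext("glc_e", "glucose"), ext("gln_e", "glutamine"),
        ext("lac_e", "lactate"), ext("glu_e", "glutamate"),
        ext("akg_e", "alpha-ketoglutarate"), ext("w_e", "waste"),
        cyt("glc_c", "glucose"), cyt("pyr_c", "pyruvate"),
        cyt("lac_c", "lactate"), cyt("gln_c", "glutamine"),
        cyt("glu_c", "glutamate"), cyt("akg_c", "alpha-ketoglutarate"),
        cyt("cit_c", "citrate"), cyt("icit_c", "isocitrate"),
        cyt("w_c", "waste"))
    for (i in seq_len(nBranches)) {
        sp <- rbind(sp, ext(sprintf("n%d_e", i), sprintf("nutrient%d", i)),
                    cyt(sprintf("n%d_c", i), sprintf("nutrient%d", i)))
    }
    if (withCompartments)
        sp <- rbind(sp, data.frame(id = "cit_m", name = "citrate",
                                   compartment = "mitochondrion"))
    sp$boundary <- FALSE

    rx <- list(); st <- list()
    addRx <- function(id, stoich, lb, ub, gpr = NA_character_) {
        rx[[length(rx) + 1L]] <<- data.frame(
            id = id, lb = lb, ub = ub, reversible = lb < 0, gpr = gpr,
            isExchange = FALSE, pathway = NA_character_,
            stringsAsFactors = FALSE)
        st[[length(st) + 1L]] <<- stoich
    }
    addRx("EX_glc", c(glc_e = -1), -10, 0)
    addRx("EX_gln", c(gln_e = -1), -10, 0)
    addRx("EX_lac", c(lac_e = -1), 0, 1000)
    addRx("EX_glu", c(glu_e = -1), 0, 1000)
    addRx("EX_akg", c(akg_e = -1), 0, 1000)
    addRx("EX_w", c(w_e = -1), 0, 1000)
    addRx("GLCt", c(glc_e = -1, glc_c = 1), 0, 1000, "gGLCT1 or gGLCT2")
    addRx("GLNt", c(gln_e = -1, gln_c = 1), 0, 1000)        # rule-free
    addRx("GLYC", c(glc_c = -1, pyr_c = 2), 0, 1000, "gGLY1 and gGLY2")
    addRx("LDH", c(pyr_c = -1, lac_c = 1), 0, 1000, "gLDHA or gLDHB")
    addRx("LACt", c(lac_c = -1, lac_e = 1), 0, 1000)
    addRx("GLS", c(gln_c = -1, glu_c = 1), 0, 1000, "gGLS")
    addRx("GDH", c(glu_c = -1, akg_c = 1), -1000, 1000,
          "gGDH1 or (gGDH2 and gGDH3)")                     # reversible
    addRx("GLUt", c(glu_c = -1, glu_e = 1), 0, 1000)
    addRx("AKGt", c(akg_c = -1, akg_e = 1), 0, 1000)
    addRx("CS", c(pyr_c = -1, cit_c = 1), 0, 1000, "gCS")
    addRx("ACONT", c(cit_c = -1, icit_c = 1), 0, 1000, "gACO1")
    addRx("ICDH", c(icit_c = -1, akg_c = 1), 0, 1000, "gICDH")
    if (withCompartments) {
        addRx("CITtm", c(cit_c = -1, cit_m = 1), 0, 1000)
        addRx("IDHm", c(cit_m = -1, akg_c = 1), 0, 1000, "gIDHm")
    }
    for (i in seq_len(nBranches)) {
        addRx(sprintf("EX_n%d", i),
              stats::setNames(-1, sprintf("n%d_e", i)), -10, 0)
        addRx(sprintf("Nt%d", i),
              stats::setNames(c(-1, 1), sprintf(c("n%d_e", "n%d_c"), i)),
              0, 1000)
        addRx(sprintf("R%d", i),
              stats::setNames(c(-1, 1), c(sprintf("n%d_c", i), "w_c")),
              0, 1000, sprintf("gR%d", i))
    }
    addRx("Wt", c(w_c = -1, w_e = 1), 0, 1000)
    addRx("BIOMASS", c(pyr_c = -0.3, akg_c = -0.1, glu_c = -0.05), 0, 1000)

    rxDf <- do.call(rbind, rx)
    S <- matrix(0, nrow = nrow(sp), ncol = nrow(rxDf),
                dimnames = list(sp$id, rxDf$id))
    for (k in seq_along(st)) S[names(st[[k]]), k] <- st[[k]]
    rxDf$isExchange <- .detectExchanges(sp, S)
    MetabolicModel(sp, rxDf, S)
}

#' Describe a planted regulation scenario
#'
#' Assigns a regulation class to each plantable branch reaction of the toy
#' model and fixes the study conditions: per-group effect multipliers
#' (group \eqn{j} of \eqn{G} gets \code{effectSize^(j-1)}), multiplicative
#' lognormal noise, and the number of samples per group.
#'
#' @param classes character vector of classes, one per branch, from
#'   \{\code{concerted}, \code{metabolic_only}, \code{transcriptional_only},
#'   \code{other}\}; branch \code{i} plants on reaction \code{R<i>}.
#' @param groups group labels (default 3 groups).
#' @param effectSize between-adjacent-group multiplier (default 2).
#' @param noiseSd sd of the lognormal noise on expression and abundance
#'   (default 0.1).
#' @param nSamples samples per group (>= 3).
#' @param seed RNG seed for data generation.
#' @return a \code{plantedScenario} object.
#' @export
plantedScenario <- function(classes,
                            groups = c("g1", "g2", "g3"),
                            effectSize = 2, noiseSd = 0.1,
                            nSamples = 3L, seed = 1L) {
    stopifnot(all(classes %in% c("concerted", "metabolic_only",
                                 "transcriptional_only", "other")),
              effectSize > 0, noiseSd >= 0, nSamples >= 3L,
              length(groups) >= 2L)
    mult <- effectSize ^ (seq_along(groups) - 1L)
    names(mult) <- groups
    structure(list(classes = stats::setNames(classes,
                                             paste0("R", seq_along(classes))),
                   groups = groups, multipliers = mult,
                   effectSize = effectSize, noiseSd = noiseSd,
                   nSamples = as.integer(nSamples), seed = as.integer(seed)),
              class = "plantedScenario")
}

#' Generate matched multi-omics data for a planted scenario
#'
#' Produces every input the pipeline consumes, with group-level means
#' following the planted multipliers: for \emph{metabolic_only} branches
#' the substrate abundance and the medium concentration of the branch
#' nutrient co-vary across groups while enzyme expression is flat; for
#' \emph{transcriptional_only} branches the enzyme expression varies while
#' substrate and medium are flat; \emph{concerted} varies all three;
#' \emph{other} varies expression and abundance concordantly while the
#' medium bound varies \emph{inversely}, so the attainable flux is
#' decoupled from both omics layers (the second-quadrant phenomenon:
#' expression and substrate agree, the flux follows neither). Per-sample
#' values are drawn lognormal
#' around the group means (mean-preserving), deterministically for a given
#' seed.
#'
#' @param model the matching \code{\link{generateToyModel}} output.
#' @param scenario a \code{\link{plantedScenario}}.
#' @return list with \code{expression} (gene x sample matrix),
#'   \code{groups} (label per sample), \code{metabolomics} (measured
#'   metabolite x sample matrix; citrate is measured compartment-free),
#'   \code{nameMap}, \code{medium}, \code{spent}, \code{fluxIds},
#'   \code{biomassId}.
#' @export
generatePlantedOmics <- function(model, scenario) {
    stopifnot(inherits(scenario, "plantedScenario"))
    bad <- setdiff(names(scenario$classes), reactionIds(model))
    if (length(bad))
        stop("scenario references unknown reactions: ",
             paste(bad, collapse = ", "))
    set.seed(scenario$seed)
    groups <- scenario$groups
    nS <- scenario$nSamples
    mult <- scenario$multipliers
    sampleGroups <- rep(groups, each = nS)
    sampleNames <- paste0(sampleGroups, "__s", rep(seq_len(nS), length(groups)))

    noisy <- function(mean, n) {
        sd <- scenario$noiseSd
        if (sd == 0) return(rep(mean, n))
        mean * exp(stats::rnorm(n, -sd^2 / 2, sd))  # mean-preserving
    }

    varyExpr <- names(scenario$classes)[scenario$classes %in%
        c("transcriptional_only", "concerted", "other")]
    varySubstrate <- names(scenario$classes)[scenario$classes %in%
        c("metabolic_only", "concerted", "other")]
    varyMedium <- names(scenario$classes)[scenario$classes %in%
        c("metabolic_only", "concerted")]

    genes <- geneIds(model)
    baseExpr <- 100
    expr <- matrix(NA_real_, nrow = length(genes), ncol = length(sampleNames),
                   dimnames = list(genes, sampleNames))
    for (j in seq_along(sampleNames)) {
        g <- sampleGroups[j]
        mu <- rep(baseExpr, length(genes))
        names(mu) <- genes
        for (r in varyExpr) {
            rgenes <- gprGenes(gprRules(model)[[r]])
            mu[rgenes] <- baseExpr * mult[[g]]
        }
        expr[, j] <- noisy(1, length(genes)) * mu
    }

    branchSubstrate <- function(r) sub("^R", "n", r)  # R3 -> n3
    measured <- c("glc_c", "pyr_c", "lac_c", "gln_c", "glu_c", "akg_c",
                  "cit", "icit_c", "w_c",
                  paste0(branchSubstrate(names(scenario$classes)), "_c"))
    baseAbund <- 50
    metab <- matrix(NA_real_, nrow = length(measured),
                    ncol = length(sampleNames),
                    dimnames = list(measured, sampleNames))
    for (j in seq_along(sampleNames)) {
        g <- sampleGroups[j]
        mu <- rep(baseAbund, length(measured))
        names(mu) <- measured
        for (r in varySubstrate)
            mu[paste0(branchSubstrate(r), "_c")] <- baseAbund * mult[[g]]
        metab[, j] <- noisy(1, length(measured)) * mu
    }
    nameMap <- data.frame(name = "cit",
                          species = intersect(c("cit_c", "cit_m"),
                                              speciesIds(model)),
                          stringsAsFactors = FALSE)

    medium <- do.call(rbind, lapply(groups, function(g) {
        conc <- c(glc_e = 25, gln_e = 4)
        for (r in names(scenario$classes)) {
            nm <- paste0(branchSubstrate(r), "_e")
            conc[nm] <- if (r %in% varyMedium) 5 * mult[[g]]
                        else if (scenario$classes[[r]] == "other")
                            5 / mult[[g]]  # capacity decoupled from the omics
                        else 5
        }
        data.frame(species = names(conc), group = g, conc = unname(conc),
                   stringsAsFactors = FALSE)
    }))

    # spent-medium concentrations shared across groups: lac/glc 1.8,
    # lac/gln 9, glu/gln 0.2, with a +/-5% spread between biological reps
    spent <- do.call(rbind, lapply(groups, function(g) {
        do.call(rbind, lapply(1:2, function(br) {
            f <- c(0.95, 1.05)[br]
            do.call(rbind, lapply(1:2, function(tr) {
                data.frame(
                    group = g, bioRep = br, techRep = tr,
                    metabolite = c("glucose", "glutamine", "lactate",
                                   "glutamate"),
                    t0 = c(25, 4, 0, 0),
                    t48 = c(25 - 10, 4 - 2, 18 * f, 0.4 * f),
                    stringsAsFactors = FALSE)
            }))
        }))
    }))

    list(expression = expr, groups = sampleGroups, metabolomics = metab,
         nameMap = nameMap, medium = medium, spent = spent,
         fluxIds = c(glucose = "EX_glc", glutamine = "EX_gln",
                     lactate = "EX_lac", glutamate = "EX_glu"),
         biomassId = "BIOMASS")
}

#' Score recovery of planted regulation classes
#'
#' Compares the classes assigned by a concordance analysis with the
#' planted truth, over the planted reactions only.
#'
#' @param scenario a \code{\link{plantedScenario}}.
#' @param result a \linkS4class{ConcordanceResult}.
#' @return list with \code{confusion} (planted x assigned table),
#'   \code{perClass} (precision/recall data.frame) and \code{accuracy}.
#' @export
scoreRecovery <- function(scenario, result) {
    stopifnot(inherits(scenario, "plantedScenario"),
              methods::is(result, "ConcordanceResult"))
    tb <- as.data.frame(concordanceTable(result))
    truth <- scenario$classes
    assigned <- stats::setNames(rep("missing", length(truth)), names(truth))
    hit <- intersect(names(truth), tb$reaction)
    assigned[hit] <- tb$class[match(hit, tb$reaction)]
    lv <- union(unique(truth), unique(assigned))
    confusion <- table(planted = factor(truth, lv),
                       assigned = factor(assigned, lv))
    perClass <- do.call(rbind, lapply(sort(unique(truth)), function(cl) {
        tp <- sum(truth == cl & assigned == cl)
        data.frame(class = cl,
                   recall = tp / sum(truth == cl),
                   precision = if (sum(assigned == cl) > 0)
                       tp / sum(assigned == cl) else NA_real_)
    }))
    list(confusion = confusion, perClass = perClass,
         accuracy = mean(truth == assigned))
}
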