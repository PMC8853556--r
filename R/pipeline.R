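#' Read pipeline input tables
#'
#' Readers for the plain-TSV dialects the pipeline consumes. Expression
#' and metabolomics tables have the id in the first column and one column
#' per sample named \code{<group>__<sample>}; the group is recovered from
#' the column name.
#'
#' @param path TSV file.
#' @return \code{readExpression}/\code{readMetabolomics}: list with
#'   \code{values} (matrix) and \code{groups}; \code{readMedium},
#'   \code{readSpentMedium}, \code{readNameMap}: a data.frame.
#' @name pipeline-io
NULL

.readOmicsTSV <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ids <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
    cols <- colnames(m)
    if (!all(grepl("__", cols)))
        stop("sample columns must be named <group>__<sample>; offending: ",
             paste(cols[!grepl("__", cols)], collapse = ", "))
    list(values = m, groups = sub("__.*$", "", cols))
}

#' @rdname pipeline-io
#' @export
readExpression <- function(path) .readOmicsTSV(path)

#' @rdname pipeline-io
#' @export
readMetabolomics <- function(path) .readOmicsTSV(path)

#' @rdname pipeline-io
#' @export
readMedium <- function(path)
    utils::read.delim(path, stringsAsFactors = FALSE)

#' @rdname pipeline-io
#' @export
readSpentMedium <- function(path)
    utils::read.delim(path, stringsAsFactors = FALSE)

#' @rdname pipeline-io
#' @export
readNameMap <- function(path)
    utils::read.delim(path, stringsAsFactors = FALSE)

#' Write a score table (with group means and, for RAS, normalized scores)
#'
#' @param tab a \linkS4class{ScoreTable}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeScoreTable <- function(tab, path) {
    sc <- SummarizedExperiment::assay(tab, "score")
    m <- groupMeans(tab)
    colnames(m) <- paste0("mean_", colnames(m))
    out <- data.frame(reaction = rownames(sc), sc, m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (scoreType(tab) == "RAS") {
        nm <- normalizedScores(tab)
        colnames(nm) <- paste0("norm_", colnames(nm))
        out <- cbind(out, nm)
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' Collects input paths (or in-memory objects), constraint-layer toggles
#' and all statistical parameters, with the defaults of the analysis
#' protocol: significance level 0.05, fold thresholds 1.2/0.8, kappa
#' threshold 0.2, 1000 null resamples, sampling in 10 batches with
#' thinning 10.
#'
#' @param model a \linkS4class{MetabolicModel} or SBML path.
#' @param expression expression matrix + groups (as from
#'   \code{\link{readExpression}}) or a TSV path.
#' @param metabolomics idem for metabolite abundances.
#' @param medium,spent data.frames or TSV paths.
#' @param nameMap optional data.frame or TSV path.
#' @param fluxIds named map metabolite -> exchange reaction id (glucose,
#'   glutamine, lactate, glutamate) for the ratio and yield layers.
#' @param biomassId biomass reaction id (excluded from RPS; anchors the
#'   yield bracket).
#' @param outDir output directory.
#' @param type1,type2,type3 layer toggles.
#' @param baseUptake,exemptList,exclusionList,missingPolicy see the
#'   respective stage functions.
#' @param nTotal,nBatches,thinning sampling protocol.
#' @param alpha,foldUp,foldDown,kappaThreshold,nResamples test parameters.
#' @param seed master seed recorded in every output.
#' @return a \code{runConfig} list.
#' @export
makeRunConfig <- function(model, expression, metabolomics, medium = NULL,
                          spent = NULL, nameMap = NULL, fluxIds = NULL,
                          biomassId = NULL, outDir = tempfile("fluxcord_run_"),
                          type1 = TRUE, type2 = TRUE, type3 = TRUE,
                          baseUptake = 10, exemptList = character(),
                          exclusionList = character(),
                          missingPolicy = "skip",
                          nTotal = 5000L, nBatches = 10L, thinning = 10L,
                          alpha = 0.05, foldUp = 1.2, foldDown = 0.8,
                          kappaThreshold = 0.2, nResamples = 1000L,
                          seed = 1L) {
    stopifnot(alpha > 0, alpha < 1, foldUp >= 1, foldDown <= 1,
              kappaThreshold >= 0, kappaThreshold <= 1, nResamples >= 1)
    structure(list(model = model, expression = expression,
                   metabolomics = metabolomics, medium = medium,
                   spent = spent, nameMap = nameMap, fluxIds = fluxIds,
                   biomassId = biomassId, outDir = outDir,
                   type1 = type1, type2 = type2, type3 = type3,
                   baseUptake = baseUptake, exemptList = exemptList,
                   exclusionList = exclusionList,
                   missingPolicy = missingPolicy,
                   nTotal = as.integer(nTotal),
                   nBatches = as.integer(nBatches),
                   thinning = as.integer(thinning),
                   alpha = alpha, foldUp = foldUp, foldDown = foldDown,
                   kappaThreshold = kappaThreshold,
                   nResamples = as.integer(nResamples),
                   seed = as.integer(seed)),
              class = "runConfig")
}

#' Load a YAML run configuration
#'
#' Reads a YAML file whose keys mirror \code{\link{makeRunConfig}}
#' arguments (file paths for the data inputs; \code{fluxIds} as a named
#' mapping) and resolves it into a \code{runConfig}.
#'
#' @param path YAML file.
#' @return a \code{runConfig}.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    args <- y
    if (!is.null(y$fluxIds)) args$fluxIds <- unlist(y$fluxIds)
    if (!is.null(y$exemptList)) args$exemptList <- unlist(y$exemptList)
    if (!is.null(y$exclusionList)) args$exclusionList <- unlist(y$exclusionList)
    do.call(makeRunConfig, args)
}

.resolveInputs <- function(config) {
    cf <- config
    if (is.character(cf$model)) cf$model <- readSBML(cf$model, quiet = TRUE)
    if (is.character(cf$expression)) cf$expression <- readExpression(cf$expression)
    if (is.character(cf$metabolomics))
        cf$metabolomics <- readMetabolomics(cf$metabolomics)
    if (is.character(cf$medium)) cf$medium <- readMedium(cf$medium)
    if (is.character(cf$spent)) cf$spent <- readSpentMedium(cf$spent)
    if (is.character(cf$nameMap)) cf$nameMap <- readNameMap(cf$nameMap)
    cf
}

#' Run the full concordance pipeline
#'
#' Executes the stages in order — RAS, cell-relative model construction,
#' flux sampling, RPS, sign calling, concordance — persisting every
#' intermediate table under \code{config$outDir} together with a manifest
#' (package version, seed, parameters). A stage failure aborts with the
#' stage name; completed stages remain on disk.
#'
#' @param config a \code{runConfig} from \code{\link{makeRunConfig}} or
#'   \code{\link{readRunConfig}}.
#' @param verbose log stage progress.
#' @return list with elements \code{result}
#'   (\linkS4class{ConcordanceResult}), \code{models}, \code{ffd},
#'   \code{ras}, \code{rps}, \code{signs} and \code{outDir}.
#' @export
runPipeline <- function(config, verbose = TRUE) {
    stopifnot(inherits(config, "runConfig"))
    cf <- .resolveInputs(config)
    dir.create(cf$outDir, showWarnings = FALSE, recursive = TRUE)
    note <- function(...) if (verbose) message("[fluxcord] ", sprintf(...))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    yield <- NULL
    if (!is.null(cf$biomassId) && !is.null(cf$fluxIds))
        yield <- growthYieldConstraint(cf$biomassId, cf$fluxIds[["glucose"]])

    note("building cell-relative models (layers: %s)",
         paste(c("type1", "type2", "type3")[c(cf$type1, cf$type2, cf$type3)],
               collapse = "+"))
    built <- stage("models", buildCellRelativeModels(
        cf$model, cf$expression$values, cf$expression$groups,
        medium = cf$medium, spent = cf$spent, fluxIds = cf$fluxIds,
        yield = yield, type1 = cf$type1, type2 = cf$type2, type3 = cf$type3,
        baseUptake = cf$baseUptake, exemptList = cf$exemptList,
        missingPolicy = cf$missingPolicy))
    writeScoreTable(built$ras, file.path(cf$outDir, "ras.tsv"))
    for (g in names(built$models)) {
        writeSBML(built$models[[g]],
                  file.path(cf$outDir, sprintf("model_%s.xml", g)))
        writeConstraintSidecar(built$models[[g]],
                               file.path(cf$outDir,
                                         sprintf("model_%s.constraints.json", g)))
    }

    note("sampling %d flux distributions per group", cf$nTotal)
    ffd <- stage("sampling", {
        out <- list()
        for (g in names(built$models)) {
            fs <- sampleFluxes(built$models[[g]], group = g,
                               nTotal = cf$nTotal, nBatches = cf$nBatches,
                               thinning = cf$thinning, seed = cf$seed)
            chk <- verifySamples(built$models[[g]], fs, tol = fs@tolerance)
            if (!chk$pass)
                stop("sampled fluxes violate constraints for group ", g)
            utils::write.table(
                data.frame(reaction = rownames(fluxes(fs)), fluxes(fs),
                           check.names = FALSE),
                file.path(cf$outDir, sprintf("ffd_%s.tsv", g)),
                sep = "\t", quote = FALSE, row.names = FALSE)
            jsonlite::write_json(
                list(group = g, seed = cf$seed, nBatches = cf$nBatches,
                     thinning = cf$thinning, tolerance = fs@tolerance),
                file.path(cf$outDir, sprintf("ffd_%s.meta.json", g)),
                auto_unbox = TRUE)
            out[[g]] <- fs
        }
        out
    })

    note("computing reaction propensity scores")
    rps <- stage("rps", {
        anyModel <- built$models[[1]]
        assignment <- mapMetabolites(anyModel, cf$metabolomics$values,
                                     cf$nameMap)
        computeRPS(anyModel, assignment, cf$metabolomics$groups,
                   exclusionList = cf$exclusionList,
                   excludeReactions = c(cf$biomassId,
                                        paste0(cf$biomassId, "_reverse")))
    })
    writeScoreTable(rps, file.path(cf$outDir, "rps.tsv"))

    note("calling pairwise variation signs")
    signs <- stage("signs", {
        ras <- built$ras
        hasGPR <- SummarizedExperiment::rowData(ras)$hasGPR
        ## RAS signs over the split reaction ids, so vectors align with
        ## the FFD/RPS rows of the irreversible model
        rmap <- as.data.frame(reverseMap(built$models[[1]]))
        sc <- SummarizedExperiment::assay(ras, "score")
        scSplit <- sc[rmap$original, , drop = FALSE]
        rownames(scSplit) <- rmap$id
        rasSplit <- ScoreTable(scSplit, scoreGroups(ras), "RAS")
        list(ras = pairwiseSignMatrix(rasSplit, alpha = cf$alpha,
                                      foldUp = cf$foldUp,
                                      foldDown = cf$foldDown),
             rps = pairwiseSignMatrix(rps, alpha = cf$alpha,
                                      foldUp = cf$foldUp,
                                      foldDown = cf$foldDown),
             ffd = pairwiseSignMatrix(ffd, alpha = cf$alpha,
                                      foldUp = cf$foldUp,
                                      foldDown = cf$foldDown),
             rasEligible = rmap$id[hasGPR[match(rmap$original,
                                                rownames(sc))]])
    })
    for (tag in c("ras", "rps", "ffd"))
        utils::write.table(
            data.frame(reaction = rownames(signValues(signs[[tag]])),
                       signValues(signs[[tag]]), check.names = FALSE),
            file.path(cf$outDir, sprintf("signs_%s.tsv", tag)),
            sep = "\t", quote = FALSE, row.names = FALSE)

    note("concordance analysis (%d resamples)", cf$nResamples)
    result <- stage("concordance", concordanceAnalysis(
        signs$ras, signs$rps, signs$ffd, rasEligible = signs$rasEligible,
        threshold = cf$kappaThreshold, nResamples = cf$nResamples,
        seed = cf$seed))
    result@table$batchSd <- unname(stage("concordance", kappaBatchSd(
        signs$rps, ffd, reactions = as.character(result@table$reaction),
        alpha = cf$alpha, foldUp = cf$foldUp,
        foldDown = cf$foldDown))[as.character(result@table$reaction)])
    utils::write.table(as.data.frame(result),
                       file.path(cf$outDir, "concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    manifest <- list(
        package = "fluxcord",
        version = as.character(utils::packageVersion("fluxcord")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        seed = cf$seed,
        parameters = cf[c("type1", "type2", "type3", "baseUptake", "nTotal",
                          "nBatches", "thinning", "alpha", "foldUp",
                          "foldDown", "kappaThreshold", "nResamples",
                          "missingPolicy")])
    jsonlite::write_json(manifest, file.path(cf$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    note("done; outputs in %s", cf$outDir)
    list(result = result, models = built$models, ffd = ffd,
         ras = built$ras, rps = rps, signs = signs, fva = built$fva,
         outDir = cf$outDir)
}
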