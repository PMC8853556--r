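.SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read a constraint-based model from SBML
#'
#' Reads SBML Level 3 with the \code{fbc} (flux balance constraints)
#' extension: species with compartments and boundary flags, reactions with
#' flux bounds referenced through \code{listOfParameters}, and gene-product
#' association trees which are converted to GPR rule strings (using the
#' gene product \code{label} when present, else its id). Exchange
#' reactions are detected structurally: a single non-boundary metabolite,
#' located in the extracellular compartment.
#'
#' @param path SBML file.
#' @param quiet suppress the load summary message.
#' @return a \linkS4class{MetabolicModel}.
#' @seealso \code{\link{writeSBML}}
#' @export
readSBML <- function(path, quiet = FALSE) {
    if (!file.exists(path)) stop("no such file: ", path)
    doc <- tryCatch(xml2::read_xml(path), error = function(e)
        stop("malformed SBML in '", path, "': ", conditionMessage(e),
             call. = FALSE))
    ns <- c(s = .SBML_CORE_NS, fbc = .SBML_FBC_NS)

    comp <- xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment", ns)
    compName <- stats::setNames(
        vapply(comp, function(x) {
            nm <- xml2::xml_attr(x, "name")
            if (is.na(nm)) xml2::xml_attr(x, "id") else nm
        }, character(1)),
        vapply(comp, xml2::xml_attr, character(1), attr = "id"))

    spNodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
    if (!length(spNodes)) stop("SBML file '", path, "' contains no species")
    spId <- vapply(spNodes, xml2::xml_attr, character(1), attr = "id")
    spComp <- vapply(spNodes, xml2::xml_attr, character(1), attr = "compartment")
    species <- data.frame(
        id = spId,
        name = ifelse(is.na(vapply(spNodes, xml2::xml_attr, character(1),
                                   attr = "name")),
                      spId,
                      vapply(spNodes, xml2::xml_attr, character(1), attr = "name")),
        compartment = unname(compName[spComp]),
        boundary = vapply(spNodes, function(x)
            identical(xml2::xml_attr(x, "boundaryCondition"), "true"),
            logical(1)),
        stringsAsFactors = FALSE)
    species$compartment[is.na(species$compartment)] <- spComp[is.na(species$compartment)]

    pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
    parVal <- stats::setNames(
        as.numeric(vapply(pars, xml2::xml_attr, character(1), attr = "value")),
        vapply(pars, xml2::xml_attr, character(1), attr = "id"))

    gps <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
    gpLabel <- stats::setNames(
        vapply(gps, function(x) {
            lb <- xml2::xml_attr(x, "label")
            if (is.na(lb)) xml2::xml_attr(x, "id") else lb
        }, character(1)),
        vapply(gps, xml2::xml_attr, character(1), attr = "id"))

    rxNodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
    if (!length(rxNodes)) stop("SBML file '", path, "' contains no reactions")

    n <- length(rxNodes)
    ids <- vapply(rxNodes, xml2::xml_attr, character(1), attr = "id")
    lb <- ub <- numeric(n)
    gpr <- character(n)
    trips <- vector("list", n)
    for (i in seq_len(n)) {
        node <- rxNodes[[i]]
        lbRef <- xml2::xml_attr(node, "lowerFluxBound")
        ubRef <- xml2::xml_attr(node, "upperFluxBound")
        if (is.na(lbRef) || is.na(ubRef) ||
            !lbRef %in% names(parVal) || !ubRef %in% names(parVal))
            stop("reaction '", ids[i], "' is missing fbc flux bounds")
        lb[i] <- parVal[[lbRef]]
        ub[i] <- parVal[[ubRef]]
        refs <- function(xp) {
            sr <- xml2::xml_find_all(node, xp, ns)
            data.frame(
                species = vapply(sr, xml2::xml_attr, character(1),
                                 attr = "species"),
                stoich = as.numeric(vapply(sr, function(x) {
                    st <- xml2::xml_attr(x, "stoichiometry")
                    if (is.na(st)) "1" else st
                }, character(1))),
                stringsAsFactors = FALSE)
        }
        rea <- refs("./s:listOfReactants/s:speciesReference")
        pro <- refs("./s:listOfProducts/s:speciesReference")
        if (nrow(rea)) rea$stoich <- -rea$stoich
        trips[[i]] <- rbind(rea, pro)
        if (!nrow(trips[[i]]))
            stop("reaction '", ids[i], "' has empty stoichiometry")
        assoc <- xml2::xml_find_first(node, "./fbc:geneProductAssociation/*", ns)
        gpr[i] <- if (inherits(assoc, "xml_missing")) NA_character_
                  else gprToString(.sbmlAssocToTree(assoc, ns, gpLabel))
    }

    allTrip <- do.call(rbind, Map(cbind, rx = seq_len(n), trips))
    bad <- setdiff(unique(allTrip$species), species$id)
    if (length(bad))
        stop("reaction references unknown species: ", paste(bad, collapse = ", "))
    S <- Matrix::sparseMatrix(i = match(allTrip$species, species$id),
                              j = allTrip$rx, x = allTrip$stoich,
                              dims = c(nrow(species), n))

    reactions <- data.frame(
        id = ids, lb = lb, ub = ub,
        reversible = vapply(rxNodes, function(x)
            identical(xml2::xml_attr(x, "reversible"), "true"), logical(1)),
        gpr = gpr, isExchange = FALSE, pathway = NA_character_,
        stringsAsFactors = FALSE)
    reactions$isExchange <- .detectExchanges(species, S)

    # recognize a model already in irreversible form: no negative lower
    # bounds, no reversible flags; rebuild the forward/reverse back-map
    # from the stable `_reverse` naming convention
    irrev <- all(lb >= -1e-12) && !any(reactions$reversible)
    revMap <- S4Vectors::DataFrame(id = character(), original = character(),
                                   direction = character())
    if (irrev) {
        revIds <- grep("_reverse$", ids, value = TRUE)
        base <- sub("_reverse$", "", revIds)
        hit <- base %in% ids
        if (any(hit))
            revMap <- S4Vectors::DataFrame(
                id = c(base[hit], revIds[hit]),
                original = c(base[hit], base[hit]),
                direction = rep(c("fwd", "rev"), each = sum(hit)))
    }
    model <- MetabolicModel(species, reactions, S, reverseMap = revMap,
                            irreversible = irrev)
    if (!quiet)
        message(sprintf(
            "Loaded '%s': %d reactions, %d species, %d genes, %d exchanges",
            basename(path), length(ids), nrow(species),
            length(geneIds(model)), sum(reactions$isExchange)))
    model
}

.sbmlAssocToTree <- function(node, ns, gpLabel) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
        id <- xml2::xml_attr(node, "geneProduct")
        lab <- gpLabel[id]
        return(if (is.na(lab)) id else unname(lab))
    }
    if (nm %in% c("and", "or")) {
        kids <- lapply(xml2::xml_children(node), .sbmlAssocToTree,
                       ns = ns, gpLabel = gpLabel)
        if (length(kids) == 1L) return(kids[[1]])
        return(list(op = nm, children = kids))
    }
    stop("unsupported geneProductAssociation node: ", nm)
}

.detectExchanges <- function(species, S) {
    internal <- !species$boundary
    extracellular <- grepl("extracellular", species$compartment,
                           ignore.case = TRUE) | species$compartment == "e"
    vapply(seq_len(ncol(S)), function(j) {
        touched <- which(S[, j] != 0 & internal)
        length(touched) == 1L && extracellular[touched]
    }, logical(1))
}

#' Write a model to SBML Level 3 + fbc
#'
#' Inverse of \code{\link{readSBML}} for the subset of SBML this package
#' uses. Extra linear constraint rows (exchange ratios, the growth-yield
#' bracket) cannot be represented in SBML and are \emph{not} written; use
#' \code{\link{writeConstraintSidecar}} to persist them alongside.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSBML <- function(model, path) {
    stopifnot(methods::is(model, "MetabolicModel"))
    doc <- xml2::xml_new_root(
        "sbml", xmlns = .SBML_CORE_NS, "xmlns:fbc" = .SBML_FBC_NS,
        level = "3", version = "1", "fbc:required" = "false")
    mdl <- xml2::xml_add_child(doc, "model", id = "model",
                               "fbc:strict" = "true")

    sp <- as.data.frame(model@species)
    comps <- unique(sp$compartment)
    compId <- stats::setNames(paste0("comp", seq_along(comps)), comps)
    loc <- xml2::xml_add_child(mdl, "listOfCompartments")
    for (cc in comps)
        xml2::xml_add_child(loc, "compartment", id = compId[[cc]], name = cc,
                            constant = "true")

    los <- xml2::xml_add_child(mdl, "listOfSpecies")
    for (i in seq_len(nrow(sp)))
        xml2::xml_add_child(los, "species", id = sp$id[i], name = sp$name[i],
                            compartment = compId[[sp$compartment[i]]],
                            boundaryCondition = tolower(sp$boundary[i]),
                            hasOnlySubstanceUnits = "false", constant = "false")

    rx <- as.data.frame(model@reactions)
    lop <- xml2::xml_add_child(mdl, "listOfParameters")
    fmtNum <- function(x) formatC(x, format = "g", digits = 17)
    for (i in seq_len(nrow(rx))) {
        xml2::xml_add_child(lop, "parameter", id = paste0(rx$id[i], "_lb"),
                            value = fmtNum(rx$lb[i]), constant = "true")
        xml2::xml_add_child(lop, "parameter", id = paste0(rx$id[i], "_ub"),
                            value = fmtNum(rx$ub[i]), constant = "true")
    }

    genes <- geneIds(model)
    gpId <- stats::setNames(paste0("G_", gsub("[^A-Za-z0-9_]", "_", genes)), genes)
    if (length(genes)) {
        logp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
        for (g in genes)
            xml2::xml_add_child(logp, "fbc:geneProduct", "fbc:id" = gpId[[g]],
                                "fbc:label" = g)
    }

    S <- model@stoichiometry
    lor <- xml2::xml_add_child(mdl, "listOfReactions")
    for (i in seq_len(nrow(rx))) {
        rnode <- xml2::xml_add_child(
            lor, "reaction", id = rx$id[i],
            reversible = tolower(rx$reversible[i]), fast = "false",
            "fbc:lowerFluxBound" = paste0(rx$id[i], "_lb"),
            "fbc:upperFluxBound" = paste0(rx$id[i], "_ub"))
        coefs <- S[, i]
        subs <- which(coefs < 0); prods <- which(coefs > 0)
        if (length(subs)) {
            lrea <- xml2::xml_add_child(rnode, "listOfReactants")
            for (k in subs)
                xml2::xml_add_child(lrea, "speciesReference",
                                    species = rownames(S)[k],
                                    stoichiometry = fmtNum(-coefs[k]),
                                    constant = "true")
        }
        if (length(prods)) {
            lpro <- xml2::xml_add_child(rnode, "listOfProducts")
            for (k in prods)
                xml2::xml_add_child(lpro, "speciesReference",
                                    species = rownames(S)[k],
                                    stoichiometry = fmtNum(coefs[k]),
                                    constant = "true")
        }
        tree <- model@gprs[[i]]
        if (!is.null(tree)) {
            anode <- xml2::xml_add_child(rnode, "fbc:geneProductAssociation")
            .sbmlTreeToAssoc(anode, tree, gpId)
        }
    }
    xml2::write_xml(doc, path)
    invisible(path)
}

.sbmlTreeToAssoc <- function(parent, tree, gpId) {
    if (.gprIsLeaf(tree)) {
        xml2::xml_add_child(parent, "fbc:geneProductRef",
                            "fbc:geneProduct" = gpId[[tree]])
        return(invisible(NULL))
    }
    node <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
    for (ch in tree$children) .sbmlTreeToAssoc(node, ch, gpId)
    invisible(NULL)
}

#' Persist extra linear constraints as a JSON sidecar
#'
#' SBML cannot embed general linear rows such as exchange-flux ratio
#' constraints or the growth-yield bracket; they are stored next to the
#' model as JSON and re-attached with \code{\link{readConstraintSidecar}}.
#'
#' @param model a \code{MetabolicModel}.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
writeConstraintSidecar <- function(model, path) {
    rows <- lapply(model@extraConstraints, function(ec)
        list(id = ec$id, reactions = names(ec$coefs),
             coefs = unname(ec$coefs),
             lo = if (is.finite(ec$lo)) ec$lo else NULL,   # JSON has no Inf
             hi = if (is.finite(ec$hi)) ec$hi else NULL))
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
}

#' @rdname writeConstraintSidecar
#' @export
readConstraintSidecar <- function(model, path) {
    rows <- jsonlite::read_json(path, simplifyVector = FALSE)
    ec <- lapply(rows, function(r) list(
        id = r$id,
        coefs = stats::setNames(vapply(r$coefs, as.numeric, numeric(1)),
                                vapply(r$reactions, as.character, character(1))),
        lo = if (is.null(r$lo)) -Inf else as.numeric(r$lo),
        hi = if (is.null(r$hi)) Inf else as.numeric(r$hi)))
    extraConstraints(model) <- ec
    model
}
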