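#' Default pipeline configuration
#'
#' Returns the full run configuration with every stage's defaults:
#' abundance-class thresholds 1\% / 0.1\% / 0.01\% / 0.001\%, network
#' top 100 taxa at |rho| >= 0.6 and adjusted p <= 0.05 with 50\%
#' removal over 500 iterations, IndVal 999 permutations with the
#' IndVal > 0.7 & p < 0.05 strong-indicator rule, null models at 999
#' draws with abundance weighting, rarefaction to the minimum sample
#' depth. Override any entry via \code{modifyList}-style arguments or a
#' YAML file (\code{\link{readRunConfig}}).
#'
#' @param ... named overrides merged over the defaults (nested lists
#'   are merged recursively).
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(...) {
    base <- list(
        input = NULL,            # list(otu=, metadata=, tree=, env=)
        simulate = NULL,         # args for simulationConfig()
        normalization = "min",   # or an integer depth, or "none"
        thresholds = list(at_local = 0.01, at_mean = 0.001,
                          rt_local = 1e-4, rt_mean = 1e-5),
        permanova = list(n_perm = 999),
        env_top_n = 50,
        network = list(top_n = 100, rho_min = 0.6, p_max = 0.05,
                       removal_fraction = 0.5, n_iter = 500),
        indval = list(n_perm = 999, indval_min = 0.7, p_max = 0.05),
        assembly = list(n_null = 999, weighted = TRUE, by_class = FALSE,
                        enabled = TRUE),
        function_table = NULL,   # data.frame or TSV path
        seed = 1L)
    ov <- list(...)
    merge2 <- function(a, b) {
        for (nm in names(b))
            a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
                merge2(a[[nm]], b[[nm]]) else b[[nm]]
        a
    }
    structure(merge2(base, ov), class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with (a subset of) the \code{\link{runConfig}}
#'   sections.
#' @return a \code{RunConfig} list.
#' @export
readRunConfig <- function(path) {
    do.call(runConfig, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input/simulation and normalisation, region
#' pooling (Venn accounting), abundance classification, diversity
#' statistics (Shannon + ANOVA letters, Bray-Curtis, PCoA, PERMANOVA,
#' per-taxon Kruskal-Wallis), co-occurrence network with modularity and
#' robustness, indicator-value analysis, null-model assembly
#' partitioning, environmental correlations, and (when a function map
#' is supplied) per-function group tests. Every random stage consumes a
#' deterministic child seed derived from the master seed by stage-name
#' hashing, so adding a stage never perturbs earlier stages. When
#' \code{outdir} is given, per-stage TSVs, a JSON report and a MANIFEST
#' marking stage completion are written; on a stage error the pipeline
#' aborts naming the stage, with completed outputs retained.
#'
#' @param config a \code{\link{runConfig}} list.
#' @param outdir optional output directory.
#' @return the run report (JSON-serialisable list), invisibly carrying
#'   the heavier intermediate objects in \code{attr(, "objects")}.
#' @export
runPipeline <- function(config = runConfig(), outdir = NULL) {
    stopifnot(inherits(config, "RunConfig"))
    if (!is.null(outdir))
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    manifest <- character()
    report <- list(seed = config$seed)
    objects <- list()
    note <- function(stage) {
        manifest <<- c(manifest, stage)
        if (!is.null(outdir))
            writeLines(manifest, file.path(outdir, "MANIFEST"))
    }
    tsv <- function(d, name) {
        if (!is.null(outdir))
            utils::write.table(d, file.path(outdir, name), sep = "\t",
                               quote = FALSE, row.names = FALSE)
    }
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }

    ## -- input ---------------------------------------------------------
    otu <- stage("input", {
        if (!is.null(config$simulate)) {
            sim <- do.call(simulationConfig,
                c(config$simulate,
                  if (is.null(config$simulate$seed))
                      list(seed = stageSeed(config$seed, "simulate"))))
            simres <- simulateCommunities(sim)
            objects$truth <- simres$truth
            simres$otu
        } else if (!is.null(config$input)) {
            x <- readOtuTable(config$input$otu)
            md <- readSampleMetadata(config$input$metadata)
            tr <- if (!is.null(config$input$tree))
                readPhyloTree(config$input$tree, rownames(x)) else NULL
            OtuExperiment(otuCounts(x), md[colnames(x), , drop = FALSE],
                          tree = tr)
        } else stop("config needs either 'input' paths or a 'simulate' block")
    })
    if (!identical(config$normalization, "none")) {
        depth <- if (identical(config$normalization, "min")) NULL
                 else as.integer(config$normalization)
        otu <- stage("normalize",
            rarefyCounts(otu, depth, seed = stageSeed(config$seed, "rarefy")))
    }
    relab <- relAbundance(otu)
    region <- sampleRegion(otu)
    report$otu_totals <- list(n_taxa = nrow(otu), n_samples = ncol(otu),
        depth = unname(colSums(otuCounts(otu))[1L]))
    objects$otu <- otu
    note("input")

    ## -- venn ----------------------------------------------------------
    pool <- stage("venn", poolByRegion(otu))
    report$venn <- list(cells = as.list(pool$cells),
        richness = as.list(pool$richness),
        shared_fraction_union = pool$shared_fraction_union,
        shared_fraction_sum = pool$shared_fraction_sum,
        shared_abundance_overall = pool$shared_abundance_overall)
    objects$pool <- pool
    note("venn")

    ## -- abundance classes ---------------------------------------------
    assignment <- stage("classify",
        classifyTaxa(relab, thresholds = config$thresholds))
    csum <- classSummary(assignment, otu)
    tsv(assignment, "abundance_classes.tsv")
    tsv(csum, "class_summary.tsv")
    report$classes <- list(
        n_per_class = as.list(table(assignment$label)),
        per_region = csum)
    objects$assignment <- assignment
    note("classify")

    ## -- diversity -----------------------------------------------------
    div <- stage("diversity", {
        H <- shannonDiversity(otu)
        shannon_test <- anovaTukey(H, region)
        bc <- brayCurtis(otu)
        ord <- pcoaOrdination(bc)
        perm <- permanovaTest(bc, region,
            n_perm = config$permanova$n_perm,
            seed = stageSeed(config$seed, "permanova"))
        kw <- kruskalPerTaxon(relab, region)
        list(H = H, shannon_test = shannon_test, bc = bc, ord = ord,
             perm = perm, kw = kw)
    })
    tsv(data.frame(sample_id = names(div$H), shannon = div$H),
        "shannon.tsv")
    tsv(div$kw$table, "kruskal_per_taxon.tsv")
    report$diversity <- list(
        shannon_by_region = div$shannon_test$summary,
        permanova = list(pseudo_F = div$perm$statistic, p = div$perm$p),
        pcoa_axis_pct = round(100 * div$ord$relative_eig[1:2], 1),
        differential_taxa = div$kw$fraction_significant)
    objects$diversity <- div
    note("diversity")

    ## -- network -------------------------------------------------------
    nw <- config$network
    net <- stage("network", buildCoNetwork(relab, top_n = nw$top_n,
        rho_min = nw$rho_min, p_max = nw$p_max))
    report$network <- stage("network", {
        if (igraph::ecount(net@graph) > 0) {
            mod <- networkModularity(net)
            rob <- networkRobustness(net, nw$removal_fraction, nw$n_iter,
                seed = stageSeed(config$seed, "robustness"))
            e <- net@edges
            list(n_nodes = igraph::vcount(net@graph),
                 n_edges = nrow(e),
                 positive_edges = fractionTriple(sum(e$sign > 0), nrow(e)),
                 modularity_Q = mod$Q,
                 robustness = list(R = rob$R, se = rob$se,
                                   removal_fraction = nw$removal_fraction,
                                   n_iter = nw$n_iter))
        } else list(n_nodes = 0, n_edges = 0)
    })
    if (!is.null(outdir) && nrow(net@edges))
        writeNetworkEdges(net, file.path(outdir, "network_edges.tsv"))
    objects$network <- net
    note("network")

    ## -- indicator values ----------------------------------------------
    iv <- config$indval
    ind <- stage("indval", suppressWarnings(
        indicatorValue(relab, region, n_perm = iv$n_perm,
            seed = stageSeed(config$seed, "indval"),
            indval_min = iv$indval_min, alpha = iv$p_max)))
    isum <- summarizeIndicators(ind, assignment,
        indval_min = iv$indval_min, alpha = iv$p_max)
    tsv(ind, "indicator_values.tsv")
    report$indicators <- list(n_indicator = isum$n_indicator,
        n_strong = isum$n_strong,
        class_share = as.list(isum$class_share),
        counts = isum$counts)
    objects$indval <- ind
    note("indval")

    ## -- assembly ------------------------------------------------------
    if (isTRUE(config$assembly$enabled)) {
        asm <- stage("assembly", assemblyAnalysis(otu,
            n_null = config$assembly$n_null,
            seed = stageSeed(config$seed, "assembly"),
            weighted = config$assembly$weighted,
            assignment = if (isTRUE(config$assembly$by_class))
                assignment else NULL))
        tsv(asm$partition$pairs, "assembly_pairs.tsv")
        tsv(asm$partition$fractions, "assembly_fractions.tsv")
        report$assembly <- list(
            tree_available = !is.null(phyloTree(otu)),
            fractions = asm$partition$fractions)
        if (!is.null(asm$by_class))
            report$assembly$by_class <- lapply(asm$by_class,
                function(r) r$partition$fractions)
        objects$assembly <- asm
        note("assembly")
    } else report$assembly <- list(skipped = TRUE)

    ## -- environment ---------------------------------------------------
    env <- NULL
    if (!is.null(config$input$env)) env <- readEnvTable(config$input$env)
    else if (!is.null(config$simulate))
        env <- simulateEnvTable(as.data.frame(colData(otu)),
            seed = stageSeed(config$seed, "env"))
    if (!is.null(env)) {
        ec <- stage("env_correlation", envCorrelation(relab, env,
            top_n = min(config$env_top_n, nrow(relab))))
        tsv(ec$table, "env_correlation.tsv")
        report$env_correlation <- list(by_variable = ec$by_variable)
        objects$env <- list(table = env, correlation = ec)
        note("env_correlation")
    }

    ## -- function table ------------------------------------------------
    if (!is.null(config$function_table)) {
        fmap <- config$function_table
        if (is.character(fmap))
            fmap <- utils::read.delim(fmap, sep = "\t",
                                      stringsAsFactors = FALSE)
        ft <- stage("function_table",
                    functionTableTests(fmap, relab, region))
        tsv(ft$table, "function_tests.tsv")
        report$functions <- list(
            significant = ft$fraction_significant,
            by_category = ft$by_category)
        note("function_table")
    }

    if (!is.null(outdir))
        jsonlite::write_json(report, file.path(outdir, "report.json"),
            auto_unbox = TRUE, digits = NA, dataframe = "rows")
    attr(report, "objects") <- objects
    invisible(report)
}

#' Per-function-group abundance tests
#'
#' Sums member-taxon relative abundances per sample for every function
#' group, runs a Kruskal-Wallis test across regions per function, and
#' tallies significant functions overall and per user-supplied category
#' (e.g. nitrogen / carbon / sulfur / pathogen), each share reported
#' with numerator and denominator.
#'
#' @param function_map data.frame with columns \code{taxon_id},
#'   \code{fun} and optionally \code{category}.
#' @param relabund taxa-x-samples relative-abundance matrix.
#' @param groups factor of regions per sample.
#' @param alpha significance level (default 0.05).
#' @return list with \code{table} (fun, category, H, p, q,
#'   significant), \code{fraction_significant}, and
#'   \code{by_category} (category shares among significant functions).
#' @export
functionTableTests <- function(function_map, relabund, groups,
                               alpha = 0.05) {
    if (is.null(function_map) || !nrow(function_map))
        stop("empty function map")
    stopifnot(all(c("taxon_id", "fun") %in% colnames(function_map)))
    known <- function_map$taxon_id %in% rownames(relabund)
    if (!any(known)) stop("function map references no known taxa")
    fmap <- function_map[known, , drop = FALSE]
    funs <- unique(fmap$fun)
    agg <- t(vapply(funs, function(fn)
        colSums(relabund[fmap$taxon_id[fmap$fun == fn], , drop = FALSE]),
        numeric(ncol(relabund))))
    rownames(agg) <- funs
    kw <- kruskalPerTaxon(agg, groups, alpha = alpha)
    tab <- kw$table
    names(tab)[1L] <- "fun"
    tab$category <- if ("category" %in% colnames(fmap))
        fmap$category[match(tab$fun, fmap$fun)] else NA_character_
    tab$significant <- tab$p < alpha
    nsig <- sum(tab$significant)
    by_cat <- NULL
    if (any(!is.na(tab$category)) && nsig > 0) {
        cats <- unique(tab$category[!is.na(tab$category)])
        by_cat <- lapply(cats, function(cc) fractionTriple(
            sum(tab$significant & tab$category == cc, na.rm = TRUE),
            nsig, cc))
        names(by_cat) <- cats
    }
    list(table = tab,
         fraction_significant = fractionTriple(nsig, nrow(tab)),
         by_category = by_cat)
}
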