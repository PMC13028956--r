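#' Accessors for OtuExperiment and CoNetwork objects
#'
#' \code{otuCounts} returns the integer count matrix (taxa x samples);
#' \code{relAbundance} the column-normalised proportions;
#' \code{phyloTree} the phylogeny (or \code{NULL});
#' \code{sampleRegion} the per-sample region factor.
#'
#' @param x an \linkS4class{OtuExperiment} (or \linkS4class{CoNetwork}
#'   for the network accessors).
#' @return see the individual descriptions.
#' @name accessors
#' @aliases otuCounts relAbundance phyloTree sampleRegion networkGraph
#'   networkEdges networkNodes
NULL

#' @rdname accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname accessors
#' @export
setGeneric("relAbundance", function(x) standardGeneric("relAbundance"))

#' @rdname accessors
#' @export
setGeneric("phyloTree", function(x) standardGeneric("phyloTree"))

#' @rdname accessors
#' @export
setGeneric("sampleRegion", function(x) standardGeneric("sampleRegion"))

#' @rdname accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname accessors
setMethod("otuCounts", "OtuExperiment", function(x) assay(x, "counts"))

#' @rdname accessors
setMethod("relAbundance", "OtuExperiment", function(x) {
    m <- assay(x, "counts")
    sweep(m, 2L, colSums(m), "/")
})

#' @rdname accessors
setMethod("phyloTree", "OtuExperiment", function(x) x@tree)

#' @rdname accessors
setMethod("sampleRegion", "OtuExperiment", function(x) {
    cd <- colData(x)
    if (!"region" %in% colnames(cd))
        stop("sample metadata has no 'region' column")
    factor(cd$region)
})

#' @rdname accessors
setMethod("networkGraph", "CoNetwork", function(x) x@graph)

#' @rdname accessors
setMethod("networkEdges", "CoNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("networkNodes", "CoNetwork", function(x) x@nodes)

setMethod("show", "OtuExperiment", function(object) {
    cat("OtuExperiment:", nrow(object), "taxa x", ncol(object), "samples\n")
    if ("region" %in% colnames(colData(object))) {
        tab <- table(colData(object)$region)
        cat("  regions:", paste(sprintf("%s (%d)", names(tab), tab),
            collapse = ", "), "\n")
    }
    cat("  tree:", if (is.null(object@tree)) "none" else
        sprintf("%d tips", length(object@tree$tip.label)), "\n")
    invisible(NULL)
})

setMethod("show", "CoNetwork", function(object) {
    g <- object@graph
    e <- object@edges
    cat("CoNetwork:", igraph::vcount(g), "nodes,", igraph::ecount(g),
        "edges\n")
    if (nrow(e))
        cat(sprintf("  positive edges: %d (%.1f%%), negative: %d\n",
            sum(e$sign > 0), 100 * mean(e$sign > 0), sum(e$sign < 0)))
    cat("  thresholds: |rho| >=", object@params$rho_min,
        ", q <=", object@params$p_max, "\n")
    invisible(NULL)
})
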