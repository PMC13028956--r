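#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

setOldClass("phylo")
setOldClass("igraph")
setClassUnion("phyloOrNULL", c("phylo", "NULL"))

#' OtuExperiment: OTU counts, sample metadata and an optional phylogeny
#'
#' The central data container of the package. It extends
#' \linkS4class{SummarizedExperiment}: the single assay \code{"counts"}
#' holds non-negative integer OTU counts (taxa as rows, samples as
#' columns), \code{colData} holds the per-sample metadata (at minimum a
#' \code{region} factor), and an optional rooted phylogeny with branch
#' lengths covers the taxa used by phylogenetic turnover statistics.
#'
#' @slot tree a rooted \code{ape::phylo} object whose tip labels include
#'   every row name of the count matrix, or \code{NULL} when no
#'   phylogeny is available (e.g. ITS-based fungal tables).
#'
#' @seealso \code{\link{OtuExperiment}} (constructor),
#'   \code{\link{otuCounts}}, \code{\link{relAbundance}},
#'   \code{\link{phyloTree}}
#' @export
setClass("OtuExperiment",
    contains = "SummarizedExperiment",
    slots = c(tree = "phyloOrNULL"))

setValidity("OtuExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        x <- assay(object, "counts")
        if (is.null(rownames(x)) || is.null(colnames(x)))
            msg <- c(msg, "counts must have taxon row names and sample column names")
        else {
            if (anyDuplicated(rownames(x)))
                msg <- c(msg, "duplicate taxon ids")
            if (anyDuplicated(colnames(x)))
                msg <- c(msg, "duplicate sample ids")
        }
        if (any(x < 0) || any(x != floor(x)))
            msg <- c(msg, "counts must be non-negative integers")
        if (ncol(x) > 0 && any(colSums(x) <= 0))
            msg <- c(msg, sprintf("sample(s) with zero total count: %s",
                paste(colnames(x)[colSums(x) <= 0], collapse = ", ")))
    }
    if (!is.null(object@tree)) {
        tr <- object@tree
        if (is.null(tr$edge.length))
            msg <- c(msg, "tree must have branch lengths")
        missing <- setdiff(rownames(object), tr$tip.label)
        if (length(missing))
            msg <- c(msg, sprintf("%d taxa absent from tree (e.g. %s)",
                length(missing), missing[1L]))
    }
    if (length(msg)) msg else TRUE
})

#' Bacterial-fungal co-occurrence network
#'
#' An undirected signed network over the most abundant taxa, with edges
#' retained where the between-taxon Spearman correlation passes the
#' magnitude and (BH-adjusted) significance thresholds.
#'
#' @slot graph the underlying \code{igraph} object (undirected, no
#'   self-loops); vertex attribute \code{name} carries taxon ids.
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{rho}, \code{p}, \code{q}, \code{sign}.
#' @slot nodes data.frame with columns \code{taxon_id}, \code{kingdom}
#'   (if supplied), \code{mean_relabund}.
#' @slot params list of the thresholds used (\code{top_n},
#'   \code{rho_min}, \code{p_max}).
#' @export
setClass("CoNetwork",
    slots = c(graph = "igraph", edges = "data.frame",
              nodes = "data.frame", params = "list"))

setValidity("CoNetwork", function(object) {
    msg <- character()
    g <- object@graph
    if (igraph::any_loop(g))
        msg <- c(msg, "network must not contain self-loops")
    if (igraph::is_directed(g))
        msg <- c(msg, "network must be undirected")
    n <- igraph::vcount(g)
    if (igraph::ecount(g) > n * (n - 1) / 2)
        msg <- c(msg, "edge count exceeds simple-graph maximum")
    if (length(msg)) msg else TRUE
})
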