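#' Build a co-occurrence network over the most abundant taxa
#'
#' Ranks taxa by mean relative abundance (combined across kingdoms, or
#' with a per-kingdom quota), computes all pairwise Spearman
#' correlations across samples, BH-adjusts the two-sided p-values over
#' all pairs, and keeps edges with \code{|rho| >= rho_min} and adjusted
#' \code{p <= p_max}. Isolated nodes are dropped from the graph but kept
#' in the node table.
#'
#' @param relabund taxa-x-samples relative-abundance matrix (bacterial
#'   and fungal tables may be row-bound; tag rows via \code{kingdom}).
#' @param top_n number of taxa to retain (default 100).
#' @param rho_min minimum absolute Spearman correlation (default 0.6).
#' @param p_max maximum BH-adjusted p (default 0.05).
#' @param kingdom optional character vector tagging each row (e.g.
#'   \code{"bacteria"}/\code{"fungi"}).
#' @param per_kingdom_quota if TRUE take \code{top_n} per kingdom
#'   instead of overall.
#' @return a \linkS4class{CoNetwork}.
#' @export
buildCoNetwork <- function(relabund, top_n = 100, rho_min = 0.6,
                           p_max = 0.05, kingdom = NULL,
                           per_kingdom_quota = FALSE) {
    relabund <- as.matrix(relabund)
    if (ncol(relabund) < 3)
        stop("need >= 3 samples for correlation-based networks")
    if (top_n < 3) stop("top_n must be >= 3")
    if (!is.null(kingdom)) stopifnot(length(kingdom) == nrow(relabund))
    mr <- rowMeans(relabund)
    if (per_kingdom_quota && !is.null(kingdom)) {
        top <- unlist(lapply(split(seq_len(nrow(relabund)), kingdom),
            function(idx) idx[order(mr[idx],
                decreasing = TRUE)][seq_len(min(top_n, length(idx)))]))
    } else {
        top <- order(mr, decreasing = TRUE)[seq_len(min(top_n,
                                                        nrow(relabund)))]
    }
    sub <- relabund[sort(top), , drop = FALSE]
    kng <- if (is.null(kingdom)) rep(NA_character_, nrow(sub))
           else kingdom[sort(top)]
    n <- ncol(sub)
    rk <- t(apply(sub, 1L, rank))
    sds <- apply(rk, 1L, stats::sd)
    rho <- suppressWarnings(stats::cor(t(rk)))
    ut <- which(upper.tri(rho), arr.ind = TRUE)
    r <- rho[ut]
    ok <- sds[ut[, 1L]] > 0 & sds[ut[, 2L]] > 0 & is.finite(r)
    tval <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    p[abs(r) >= 1 - 1e-12] <- 0
    p[!ok] <- NA
    q <- stats::p.adjust(p, "BH")
    keep <- ok & abs(r) >= rho_min & q <= p_max
    edges <- data.frame(
        source = rownames(sub)[ut[keep, 1L]],
        target = rownames(sub)[ut[keep, 2L]],
        rho = r[keep], p = p[keep], q = q[keep],
        sign = ifelse(r[keep] > 0, 1L, -1L))
    g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
        directed = FALSE,
        vertices = data.frame(name = rownames(sub)))
    igraph::E(g)$rho <- edges$rho
    igraph::E(g)$sign <- edges$sign
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
    nodes <- data.frame(taxon_id = rownames(sub), kingdom = kng,
        mean_relabund = rowMeans(sub),
        in_graph = rownames(sub) %in% igraph::V(g)$name,
        row.names = NULL)
    new("CoNetwork", graph = g, edges = edges, nodes = nodes,
        params = list(top_n = top_n, rho_min = rho_min, p_max = p_max))
}

#' Greedy modularity of a co-occurrence network
#'
#' Agglomerative greedy modularity maximisation (deterministic) on the
#' unweighted simple graph; Q = sum_c (e_c/m - (d_c/2m)^2) over the
#' final modules.
#'
#' @param net a \linkS4class{CoNetwork} or \code{igraph}.
#' @return list with \code{Q} and \code{membership} (named integer).
#' @export
networkModularity <- function(net) {
    g <- if (is(net, "CoNetwork")) net@graph else net
    if (igraph::ecount(g) == 0) stop("modularity needs >= 1 edge")
    g <- igraph::simplify(igraph::as_undirected(g))
    cm <- igraph::cluster_fast_greedy(g, weights = NULL)
    memb <- igraph::membership(cm)
    Q <- igraph::modularity(g, memb)
    # the trivial single-module partition has Q = 0; never report a
    # partition worse than it (greedy can on unsplittable graphs)
    if (Q < 0) {
        memb[] <- 1L
        Q <- 0
    }
    list(Q = Q, membership = memb)
}

#' Network robustness under random node removal
#'
#' Per iteration, removes \code{floor(f * n)} uniformly chosen nodes,
#' then deletes any node left without neighbours (secondary
#' extinction); robustness is the surviving share of the original
#' \code{n} nodes, averaged over iterations.
#'
#' @param net a \linkS4class{CoNetwork} or \code{igraph}.
#' @param removal_fraction fraction of nodes removed (0 < f < 1;
#'   default 0.5).
#' @param n_iter number of random removals (default 500).
#' @param seed integer seed.
#' @return list with \code{removal_fraction}, \code{n_iter},
#'   \code{values} (per-iteration proportions), \code{R} (mean),
#'   \code{se}.
#' @export
networkRobustness <- function(net, removal_fraction = 0.5, n_iter = 500,
                              seed = 1L) {
    g <- if (is(net, "CoNetwork")) net@graph else net
    n <- igraph::vcount(g)
    if (n < 4) stop("network needs >= 4 nodes")
    if (removal_fraction <= 0 || removal_fraction >= 1)
        stop("removal_fraction must be in (0, 1)")
    if (n_iter < 1) stop("n_iter must be >= 1")
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
    nrem <- floor(removal_fraction * n)
    values <- withSeed(seed, vapply(seq_len(n_iter), function(i) {
        keep <- sample.int(n, n - nrem)
        deg <- rowSums(A[keep, keep, drop = FALSE])
        sum(deg > 0) / n
    }, numeric(1)))
    list(removal_fraction = removal_fraction, n_iter = n_iter,
         values = values, R = mean(values),
         se = stats::sd(values) / sqrt(n_iter))
}

#' Induced subnetwork on a taxon subset
#'
#' Keeps the listed taxa and the edges among them, e.g. the AT/IT/RT
#' subcommunity networks used for class-wise robustness comparisons.
#'
#' @param net a \linkS4class{CoNetwork}.
#' @param taxa character vector of taxon ids.
#' @return a \linkS4class{CoNetwork} over the intersection.
#' @export
inducedSubnetwork <- function(net, taxa) {
    g <- net@graph
    keep <- intersect(igraph::V(g)$name, taxa)
    sg <- igraph::induced_subgraph(g, keep)
    e <- net@edges
    e <- e[e$source %in% keep & e$target %in% keep, , drop = FALSE]
    nd <- net@nodes[net@nodes$taxon_id %in% keep, , drop = FALSE]
    nd$in_graph <- nd$taxon_id %in% igraph::V(sg)$name
    new("CoNetwork", graph = sg, edges = e, nodes = nd,
        params = net@params)
}

#' Compare robustness across networks with ANOVA + Tukey letters
#'
#' Runs the removal simulation on each network (same removal fraction,
#' iteration count and seed stream), then a one-way ANOVA with
#' Tukey-Kramer letters across the per-iteration robustness values.
#' Networks with fewer than 4 nodes are skipped with a warning.
#'
#' @param networks named list of \linkS4class{CoNetwork} or
#'   \code{igraph} objects.
#' @param removal_fraction,n_iter,seed as in
#'   \code{\link{networkRobustness}}.
#' @return list with \code{robustness} (named list of per-network
#'   results) and \code{test} (an \code{\link{anovaTukey}} result, or
#'   NULL with < 2 usable networks).
#' @export
compareRobustness <- function(networks, removal_fraction = 0.5,
                              n_iter = 500, seed = 1L) {
    stopifnot(length(networks) >= 2, !is.null(names(networks)))
    rob <- list()
    for (nm in names(networks)) {
        g <- networks[[nm]]
        gg <- if (is(g, "CoNetwork")) g@graph else g
        if (igraph::vcount(gg) < 4) {
            warning("network '", nm, "' has < 4 nodes; skipped")
            next
        }
        rob[[nm]] <- networkRobustness(g, removal_fraction, n_iter,
                                       seed = stageSeed(seed, nm))
    }
    if (length(rob) < 2)
        return(list(robustness = rob, test = NULL))
    vals <- unlist(lapply(rob, `[[`, "values"), use.names = FALSE)
    grp <- factor(rep(names(rob), each = n_iter), levels = names(rob))
    list(robustness = rob, test = anovaTukey(vals, grp))
}

#' Export a network as edge-list TSV
#'
#' @param net a \linkS4class{CoNetwork}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNetworkEdges <- function(net, path) {
    utils::write.table(net@edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeNetworkEdges
#' @export
writeNetworkGraphML <- function(net, path) {
    igraph::write_graph(net@graph, path, format = "graphml")
    invisible(path)
}
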