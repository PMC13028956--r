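# Independent oracles used across the suite. Deliberately brute-force:
# they share no code with the implementation paths they check.

# all set partitions of 1..n (Bell(8) = 4140, fine for n <= 8)
allPartitions <- function(n) {
    if (n == 1L) return(list(list(1L)))
    out <- list()
    for (p in allPartitions(n - 1L)) {
        for (k in seq_along(p)) {
            q <- p
            q[[k]] <- c(q[[k]], n)
            out[[length(out) + 1L]] <- q
        }
        out[[length(out) + 1L]] <- c(p, list(n))
    }
    out
}

# exhaustive-search modularity maximum over all partitions
exhaustiveModularity <- function(g) {
    n <- igraph::vcount(g)
    best <- -Inf
    for (p in allPartitions(n)) {
        memb <- integer(n)
        for (k in seq_along(p)) memb[p[[k]]] <- k
        q <- igraph::modularity(g, memb)
        if (q > best) best <- q
    }
    best
}

# betaMNTD by explicit double loop over all taxon pairs
bmntdOracle <- function(x1, x2, D, weighted = TRUE) {
    i1 <- which(x1 > 0); i2 <- which(x2 > 0)
    f1 <- if (weighted) x1[i1] / sum(x1[i1]) else rep(1 / length(i1), length(i1))
    f2 <- if (weighted) x2[i2] / sum(x2[i2]) else rep(1 / length(i2), length(i2))
    s1 <- 0
    for (a in seq_along(i1)) {
        dmin <- Inf
        for (b in i2) dmin <- min(dmin, D[i1[a], b])
        s1 <- s1 + f1[a] * dmin
    }
    s2 <- 0
    for (b in seq_along(i2)) {
        dmin <- Inf
        for (a in i1) dmin <- min(dmin, D[i2[b], a])
        s2 <- s2 + f2[b] * dmin
    }
    0.5 * (s1 + s2)
}

# small OtuExperiment with a region factor
makeRegionOtu <- function(counts, regions, tree = NULL) {
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("OTU%03d", seq_len(nrow(counts)))
    OtuExperiment(counts,
        data.frame(region = regions, row.names = colnames(counts)),
        tree = tree)
}

# four-tip ultrametric tree with hand-set branch lengths:
# ((A:1,B:1):2,(C:1.5,D:1.5):1.5);  patristic: A-B 2, C-D 3, cross 6
fourTipTree <- function() {
    ape::read.tree(text = "((A:1,B:1):2,(C:1.5,D:1.5):1.5);")
}
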