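#' Patristic (cophenetic) distances for a set of taxa
#'
#' @param tree rooted \code{ape::phylo} with branch lengths.
#' @param taxa taxon ids to keep (default all tips).
#' @return symmetric zero-diagonal matrix of tip-to-tip path lengths.
#' @export
patristicDistances <- function(tree, taxa = NULL) {
    D <- ape::cophenetic.phylo(tree)
    if (!is.null(taxa)) {
        miss <- setdiff(taxa, rownames(D))
        if (length(miss))
            stop("taxa missing from tree: ", paste(utils::head(miss, 3),
                 collapse = ", "))
        D <- D[taxa, taxa]
    }
    D
}

# betaMNTD for all sample pairs given an (optionally label-shuffled)
# patristic matrix. m: taxa x samples abundances; pres/f precomputed
# presence indices and within-sample weights.
betaMNTDcore_ <- function(D, pres, f, ns) {
    # minTo[i, l] = distance from taxon i to its nearest taxon in sample l
    minTo <- vapply(seq_len(ns), function(l)
        rowMins_(D[, pres[[l]], drop = FALSE]), numeric(nrow(D)))
    minTo <- matrix(minTo, nrow = nrow(D))   # 1-taxon tables
    bm <- matrix(0, ns, ns)
    for (k in seq_len(ns - 1L)) for (l in (k + 1L):ns) {
        v <- 0.5 * (sum(f[[k]] * minTo[pres[[k]], l]) +
                    sum(f[[l]] * minTo[pres[[l]], k]))
        bm[k, l] <- bm[l, k] <- v
    }
    bm
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For samples k and l: betaMNTD = 1/2 [ sum_i f_ik min_j d(i,j) +
#' sum_j f_jl min_i d(j,i) ], the minimum running over taxa present in
#' the \emph{other} sample and f being relative abundances among the
#' sample's present taxa (abundance-weighted, the default) or uniform.
#' Shared taxa contribute zero (their nearest taxon in the other
#' community is themselves).
#'
#' @param x an \linkS4class{OtuExperiment} (tree taken from the object
#'   unless \code{tree} given) or a taxa-x-samples abundance matrix.
#' @param tree rooted phylogeny covering all present taxa.
#' @param weighted abundance-weight the taxon contributions (default
#'   TRUE).
#' @param D optional precomputed patristic matrix (rows/cols =
#'   \code{rownames(x)}), e.g. from \code{\link{patristicDistances}};
#'   computing it once and reusing it is the intended pattern for
#'   repeated calls.
#' @return symmetric matrix of betaMNTD values with sample dimnames.
#' @export
betaMNTD <- function(x, tree = NULL, weighted = TRUE, D = NULL) {
    m <- if (is(x, "OtuExperiment")) {
        if (is.null(tree)) tree <- phyloTree(x)
        otuCounts(x)
    } else as.matrix(x)
    if (is.null(D)) {
        if (is.null(tree)) stop("a tree (or precomputed D) is required")
        D <- patristicDistances(tree, rownames(m))
    } else D <- D[rownames(m), rownames(m), drop = FALSE]
    ns <- ncol(m)
    pres <- lapply(seq_len(ns), function(j) which(m[, j] > 0))
    f <- lapply(seq_len(ns), function(j) {
        v <- m[pres[[j]], j]
        if (weighted) v / sum(v) else rep(1 / length(v), length(v))
    })
    bm <- betaMNTDcore_(D, pres, f, ns)
    dimnames(bm) <- list(colnames(m), colnames(m))
    bm
}

#' beta nearest taxon index (betaNTI) against a tip-shuffling null
#'
#' Standardised effect size of betaMNTD: tip labels are shuffled across
#' the whole phylogeny (taxa randomised over the tree; abundances
#' untouched) \code{n_null} times, betaMNTD recomputed per shuffle, and
#' betaNTI = (obs - mean_null) / sd_null per sample pair. |betaNTI| > 2
#' is the conventional signature of deterministic (selection-driven)
#' turnover. The shuffle permutes the rows/columns of the precomputed
#' patristic matrix, which is mathematically identical to relabelling
#' tips and far cheaper.
#'
#' @inheritParams betaMNTD
#' @param n_null number of null shuffles (>= 99; default 999).
#' @param seed integer seed.
#' @return list with \code{bmntd} (observed matrix), \code{bnti}
#'   (matrix, NA where degenerate), \code{degenerate} (logical matrix:
#'   pairs whose null sd is zero, e.g. on a star phylogeny), and
#'   \code{n_null}.
#' @export
betaNTI <- function(x, tree = NULL, n_null = 999, seed = 1L,
                    weighted = TRUE, D = NULL) {
    if (n_null < 99) stop("n_null must be >= 99")
    m <- if (is(x, "OtuExperiment")) {
        if (is.null(tree)) tree <- phyloTree(x)
        otuCounts(x)
    } else as.matrix(x)
    if (is.null(D)) {
        if (is.null(tree)) stop("a tree (or precomputed D) is required")
        D <- patristicDistances(tree, rownames(m))
    } else D <- D[rownames(m), rownames(m), drop = FALSE]
    nt <- nrow(m); ns <- ncol(m)
    pres <- lapply(seq_len(ns), function(j) which(m[, j] > 0))
    f <- lapply(seq_len(ns), function(j) {
        v <- m[pres[[j]], j]
        if (weighted) v / sum(v) else rep(1 / length(v), length(v))
    })
    obs <- betaMNTDcore_(D, pres, f, ns)
    Du <- unname(D)
    acc <- matrix(0, ns, ns); acc2 <- matrix(0, ns, ns)
    withSeed(seed, {
        for (b in seq_len(n_null)) {
            perm <- sample.int(nt)
            bmn <- betaMNTDcore_(Du[perm, perm, drop = FALSE], pres, f, ns)
            acc <- acc + bmn
            acc2 <- acc2 + bmn^2
        }
    })
    mu <- acc / n_null
    sdv <- sqrt(pmax(acc2 / n_null - mu^2, 0) * n_null / (n_null - 1))
    degen <- sdv < 1e-12
    bnti <- (obs - mu) / sdv
    bnti[degen] <- NA_real_
    diag(bnti) <- 0; diag(degen) <- FALSE
    dimnames(obs) <- dimnames(bnti) <- dimnames(degen) <-
        list(colnames(m), colnames(m))
    list(bmntd = obs, bnti = bnti, degenerate = degen, n_null = n_null)
}

#' Raup-Crick metric on Bray-Curtis dissimilarity (RCbray)
#'
#' For each sample pair, \code{n_null} pairs of null communities are
#' assembled from the species pool of the whole table: each null
#' community draws the sample's observed richness (species picked
#' without replacement with probability proportional to pool occupancy)
#' and is then filled to the sample's observed total abundance with
#' probability proportional to pooled relative abundance. RCbray =
#' 2 [ (#\{null BC < obs BC\} + 1/2 #\{null BC = obs BC\}) / n_null ]
#' - 1, in [-1, 1]; values beyond +/-0.95 flag turnover more extreme
#' than the null (dispersal limitation / homogenising dispersal).
#'
#' @param x an \linkS4class{OtuExperiment} or taxa-x-samples count
#'   matrix (integer counts; totals define the null community sizes).
#' @param n_null number of null pairs per sample pair (>= 99; default
#'   999).
#' @param seed integer seed.
#' @param pool optional subset of samples (column names) defining the
#'   species pool; default all samples (whole-lake pool).
#' @return symmetric matrix of RCbray values with sample dimnames.
#' @export
rcBray <- function(x, n_null = 999, seed = 1L, pool = NULL) {
    if (n_null < 99) stop("n_null must be >= 99")
    m <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
    pm <- if (is.null(pool)) m else m[, pool, drop = FALSE]
    occ <- rowSums(pm > 0)
    ab <- rowSums(pm)
    poolSize <- sum(occ > 0)
    ns <- ncol(m)
    rich <- colSums(m > 0)
    if (any(rich > poolSize))
        stop("observed richness exceeds the species pool")
    tot <- round(colSums(m))
    bc <- function(a, b) sum(abs(a - b)) / sum(a + b)
    drawNull <- function(k) {
        sp <- sample.int(nrow(m), rich[k], prob = occ)
        v <- rep(1, rich[k])
        extra <- tot[k] - rich[k]
        if (extra > 0)
            v <- v + stats::rmultinom(1L, extra, prob = ab[sp])[, 1L]
        list(sp = sp, v = v)
    }
    rc <- matrix(0, ns, ns)
    withSeed(seed, {
        for (k in seq_len(ns - 1L)) for (l in (k + 1L):ns) {
            obsBC <- bc(m[, k] / sum(m[, k]), m[, l] / sum(m[, l]))
            less <- 0; equal <- 0
            for (b in seq_len(n_null)) {
                n1 <- drawNull(k); n2 <- drawNull(l)
                x1 <- numeric(nrow(m)); x1[n1$sp] <- n1$v
                x2 <- numeric(nrow(m)); x2[n2$sp] <- n2$v
                nullBC <- bc(x1 / sum(x1), x2 / sum(x2))
                if (nullBC < obsBC - 1e-12) less <- less + 1
                else if (abs(nullBC - obsBC) <= 1e-12) equal <- equal + 1
            }
            rc[k, l] <- rc[l, k] <- 2 * ((less + 0.5 * equal) / n_null) - 1
        }
    })
    dimnames(rc) <- list(colnames(m), colnames(m))
    rc
}

processLevels <- c("heterogeneous_selection", "homogeneous_selection",
                   "dispersal_limitation", "homogenizing_dispersal",
                   "drift")

#' Partition sample pairs into five assembly processes
#'
#' Pure threshold rules per pair: betaNTI > 2 -> heterogeneous
#' selection; betaNTI < -2 -> homogeneous selection; otherwise RCbray >
#' 0.95 -> dispersal limitation; RCbray < -0.95 -> homogenising
#' dispersal; else drift. When betaNTI is entirely unavailable (no
#' usable phylogeny, e.g. ITS data) the partition runs on RCbray alone
#' and selection is never inferred. The deterministic fraction is the
#' share of selection pairs; stochastic the remaining three.
#'
#' @param bnti matrix of betaNTI values (may be all-NA), aligned with
#'   \code{rc}.
#' @param rc matrix of RCbray values (same samples, same order).
#' @param groups optional factor (one level per sample, e.g. region);
#'   fractions are then reported per within-group set and for
#'   between-group pairs.
#' @return list with \code{pairs} (data.frame: sample1, sample2, scope,
#'   betaNTI, rcbray, process) and \code{fractions} (data.frame per
#'   scope: process shares summing to 1, plus deterministic /
#'   stochastic totals and the pair count).
#' @export
partitionProcesses <- function(bnti, rc, groups = NULL) {
    bnti <- as.matrix(bnti); rc <- as.matrix(rc)
    if (!identical(dim(bnti), dim(rc)))
        stop("betaNTI and RCbray matrices must align")
    if (!is.null(rownames(bnti)) && !is.null(rownames(rc)) &&
        !identical(rownames(bnti), rownames(rc)))
        stop("betaNTI and RCbray matrices must cover identical samples")
    ns <- nrow(rc)
    ids <- rownames(rc); if (is.null(ids)) ids <- as.character(seq_len(ns))
    if (!is.null(groups)) {
        groups <- as.factor(groups)
        stopifnot(length(groups) == ns)
    }
    rows <- list()
    for (k in seq_len(ns - 1L)) for (l in (k + 1L):ns) {
        b <- bnti[k, l]; r <- rc[k, l]
        proc <- if (!is.na(b) && b > 2) "heterogeneous_selection"
            else if (!is.na(b) && b < -2) "homogeneous_selection"
            else if (r > 0.95) "dispersal_limitation"
            else if (r < -0.95) "homogenizing_dispersal"
            else "drift"
        scope <- if (is.null(groups)) "all"
            else if (groups[k] == groups[l])
                paste0("within_", groups[k])
            else "between_regions"
        rows[[length(rows) + 1L]] <- data.frame(sample1 = ids[k],
            sample2 = ids[l], scope = scope, betaNTI = b, rcbray = r,
            process = proc, row.names = NULL)
    }
    pairs <- do.call(rbind, rows)
    pairs$process <- factor(pairs$process, levels = processLevels)
    scopes <- unique(c("all", pairs$scope))
    fractions <- do.call(rbind, lapply(scopes, function(sc) {
        sub <- if (sc == "all") pairs else pairs[pairs$scope == sc, ]
        if (!nrow(sub)) return(NULL)
        tab <- table(sub$process) / nrow(sub)
        out <- as.data.frame(as.list(tab))
        names(out) <- processLevels
        out$deterministic <- out$heterogeneous_selection +
            out$homogeneous_selection
        out$stochastic <- 1 - out$deterministic
        out$n_pairs <- nrow(sub)
        cbind(scope = sc, out)
    }))
    list(pairs = pairs, fractions = fractions)
}

#' Full assembly analysis: betaNTI + RCbray + process partition
#'
#' Convenience wrapper running \code{\link{betaNTI}} (when a phylogeny
#' is available), \code{\link{rcBray}}, and
#' \code{\link{partitionProcesses}}, optionally per abundance class
#' (each class's sub-table re-analysed on its own).
#'
#' @param x an \linkS4class{OtuExperiment} with a \code{region} column.
#' @param n_null null draws for both models (default 999).
#' @param seed integer seed (independent child seeds per stage).
#' @param weighted abundance-weighted betaMNTD (default TRUE).
#' @param assignment optional \code{\link{classifyTaxa}} result; when
#'   given, per-class partitions are added under \code{by_class}.
#' @param min_class_taxa minimum taxa for a class sub-analysis
#'   (default 5).
#' @return list with \code{bnti}, \code{rc}, \code{partition}, and
#'   optionally \code{by_class}.
#' @export
assemblyAnalysis <- function(x, n_null = 999, seed = 1L, weighted = TRUE,
                             assignment = NULL, min_class_taxa = 5L) {
    m <- otuCounts(x)
    region <- sampleRegion(x)
    tr <- phyloTree(x)
    runOne <- function(mm, tag, reg) {
        if (!is.null(tr)) {
            D <- patristicDistances(tr, rownames(mm))
            nb <- betaNTI(mm, n_null = n_null,
                          seed = stageSeed(seed, paste0("bnti_", tag)),
                          weighted = weighted, D = D)
            bn <- nb$bnti
        } else {
            message("no phylogeny available: betaNTI skipped, ",
                    "partition uses RCbray alone")
            bn <- matrix(NA_real_, ncol(mm), ncol(mm),
                         dimnames = list(colnames(mm), colnames(mm)))
            nb <- NULL
        }
        rc <- rcBray(mm, n_null = n_null,
                     seed = stageSeed(seed, paste0("rc_", tag)))
        list(bnti_raw = nb, bnti = bn, rc = rc,
             partition = partitionProcesses(bn, rc, reg))
    }
    out <- runOne(m, "all", region)
    if (!is.null(assignment)) {
        out$by_class <- list()
        for (k in levels(assignment$label)) {
            taxa <- assignment$taxon_id[assignment$label == k]
            mm <- m[rownames(m) %in% taxa, , drop = FALSE]
            mm <- mm[, colSums(mm) > 0, drop = FALSE]
            if (nrow(mm) < min_class_taxa || ncol(mm) < 3) {
                warning("class ", k, " too small for assembly analysis;",
                        " skipped")
                next
            }
            # regions restricted to the surviving samples
            reg_k <- region[match(colnames(mm), colnames(m))]
            out$by_class[[k]] <- runOne(mm, k, reg_k)
        }
    }
    out
}
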