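#' Per-sample Shannon diversity
#'
#' H' = -sum p_i ln p_i over taxa with p_i > 0 (natural log), computed
#' on each sample's relative abundances.
#'
#' @param x an \linkS4class{OtuExperiment} or a taxa-x-samples numeric
#'   matrix.
#' @return named numeric vector, one H' per sample.
#' @export
shannonDiversity <- function(x) {
    m <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
    if (any(colSums(m) <= 0)) stop("sample with no nonzero taxa")
    vegan::diversity(t(m), index = "shannon")
}

#' Bray-Curtis dissimilarity between samples
#'
#' BC(j,k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik), computed on
#' relative abundances so sequencing depth does not enter.
#'
#' @param x an \linkS4class{OtuExperiment} or a taxa-x-samples matrix of
#'   relative abundances.
#' @return a \code{dist} object with sample labels.
#' @export
brayCurtis <- function(x) {
    m <- if (is(x, "OtuExperiment")) relAbundance(x) else as.matrix(x)
    if (ncol(m) < 2) stop("need >= 2 samples")
    vegan::vegdist(t(m), method = "bray")
}

#' Principal coordinate analysis
#'
#' Gower double-centering of -d^2/2 followed by eigendecomposition.
#' Axes are ordered by eigenvalue; negative eigenvalues are reported but
#' excluded from the percent-variance denominator (sum of positive
#' eigenvalues only).
#'
#' @param d a \code{dist} or symmetric zero-diagonal matrix.
#' @param k number of axes to return (default all positive).
#' @return list with \code{points} (samples x axes), \code{eig} (all
#'   eigenvalues), \code{relative_eig} (share of each positive
#'   eigenvalue in the positive total).
#' @export
pcoaOrdination <- function(d, k = NULL) {
    if (!inherits(d, "dist")) {
        d <- as.matrix(d)
        if (!isSymmetric(unname(d), tol = 1e-8))
            stop("distance matrix must be symmetric")
        d <- stats::as.dist(d)
    }
    n <- attr(d, "Size")
    fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
    eig <- fit$eig
    pos <- eig[eig > sqrt(.Machine$double.eps)]
    if (is.null(k)) k <- length(pos)
    pts <- fit$points[, seq_len(min(k, ncol(fit$points))), drop = FALSE]
    colnames(pts) <- paste0("PCoA", seq_len(ncol(pts)))
    list(points = pts, eig = eig, relative_eig = pos / sum(pos))
}

# one-way pseudo-F on a squared-distance decomposition; labels is a factor
pseudoF_ <- function(d2, labels) {
    n <- nrow(d2)
    labels <- as.factor(labels)
    a <- nlevels(labels)
    sst <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (g in levels(labels)) {
        idx <- which(labels == g)
        if (length(idx) > 1) {
            sub <- d2[idx, idx]
            ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
        }
    }
    if (sst <= .Machine$double.eps) return(NA_real_)
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-way pseudo-F from the within/between decomposition of squared
#' dissimilarities, with significance from permutation of the group
#' labels: p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm). With
#' \code{exhaustive = TRUE} all distinct label arrangements are
#' enumerated instead (p = share of arrangements with F >= observed,
#' the identity included). \code{method = "anosim"} runs the rank-based
#' ANOSIM alternative instead.
#'
#' @param d \code{dist} or symmetric matrix of dissimilarities.
#' @param groups factor of group labels, one per sample.
#' @param n_perm number of Monte-Carlo permutations (ignored when
#'   exhaustive).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive enumerate all distinct label permutations.
#' @param method \code{"permanova"} (default) or \code{"anosim"}.
#' @return list with \code{statistic} (pseudo-F or ANOSIM R), \code{p},
#'   \code{n_perm}, \code{degenerate} (TRUE when total dissimilarity
#'   variance is zero; then p = 1).
#' @export
permanovaTest <- function(d, groups, n_perm = 999, seed = 1L,
                          exhaustive = FALSE,
                          method = c("permanova", "anosim")) {
    method <- match.arg(method)
    groups <- as.factor(groups)
    dm <- as.matrix(d)
    if (nlevels(groups) < 2) stop("need >= 2 groups")
    if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
    if (method == "anosim") {
        fit <- withSeed(seed,
            vegan::anosim(stats::as.dist(dm), groups,
                          permutations = n_perm))
        return(list(statistic = unname(fit$statistic),
                    p = fit$signif, n_perm = n_perm, degenerate = FALSE))
    }
    if (n_perm < 1 && !exhaustive) stop("n_perm must be >= 1")
    d2 <- dm^2
    obs <- pseudoF_(d2, groups)
    if (is.na(obs))
        return(list(statistic = NA_real_, p = 1, n_perm = n_perm,
                    degenerate = TRUE))
    if (exhaustive) {
        perms <- allLabelPermutations(as.character(groups))
        f <- vapply(perms, function(lab) pseudoF_(d2, factor(lab)),
                    numeric(1))
        p <- mean(f >= obs - 1e-12)
        return(list(statistic = obs, p = p, n_perm = length(perms),
                    degenerate = FALSE))
    }
    hits <- withSeed(seed, {
        sum(vapply(seq_len(n_perm), function(i) {
            pseudoF_(d2, sample(groups)) >= obs - 1e-12
        }, logical(1)))
    })
    list(statistic = obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm,
         degenerate = FALSE)
}

#' Per-taxon Kruskal-Wallis screen with BH correction
#'
#' Rank-based H test (with tie correction) of every taxon's relative
#' abundance across groups, Benjamini-Hochberg adjusted across taxa.
#'
#' @param relabund taxa-x-samples matrix (relative abundances, or any
#'   per-sample quantity to compare).
#' @param groups factor, one level per sample.
#' @param alpha significance level for the reported count.
#' @return list with \code{table} (data.frame: taxon_id, H, p, q) and
#'   \code{n_significant}/\code{fraction_significant} at raw p <
#'   \code{alpha} (the convention under which such screens are usually
#'   reported; q is available for stricter use).
#' @export
kruskalPerTaxon <- function(relabund, groups, alpha = 0.05) {
    relabund <- as.matrix(relabund)
    groups <- as.factor(groups)
    if (any(table(groups) == 0)) stop("empty group")
    if (ncol(relabund) != length(groups))
        stop("groups must match samples")
    res <- t(apply(relabund, 1L, function(v) {
        if (max(v) == min(v)) return(c(0, 1))
        kt <- stats::kruskal.test(v, groups)
        c(unname(kt$statistic), kt$p.value)
    }))
    tab <- data.frame(taxon_id = rownames(relabund), H = res[, 1],
                      p = res[, 2], q = stats::p.adjust(res[, 2], "BH"),
                      row.names = NULL)
    list(table = tab,
         n_significant = sum(tab$p < alpha),
         fraction_significant = fractionTriple(sum(tab$p < alpha),
                                               nrow(tab)))
}

#' Aggregate a taxa-level table to a higher taxonomic rank
#'
#' @param m taxa-x-samples matrix.
#' @param rank_of character vector mapping each row to its rank label
#'   (e.g. genus), same length as \code{nrow(m)}.
#' @return matrix with one row per rank label (row-summed).
#' @export
aggregateByRank <- function(m, rank_of) {
    stopifnot(length(rank_of) == nrow(m))
    rowsum(as.matrix(m), group = rank_of)
}

# greedy insert-absorb compact letter display.
# sigdiff: logical matrix, TRUE where the pair differs significantly.
cldInsertAbsorb_ <- function(groupNames, sigdiff) {
    sets <- list(groupNames)
    pairs <- which(upper.tri(sigdiff) & sigdiff, arr.ind = TRUE)
    if (nrow(pairs)) {
        for (r in seq_len(nrow(pairs))) {
            gi <- groupNames[pairs[r, 1L]]
            gj <- groupNames[pairs[r, 2L]]
            newSets <- list()
            for (s in sets) {
                if (gi %in% s && gj %in% s) {
                    newSets <- c(newSets, list(setdiff(s, gi)),
                                 list(setdiff(s, gj)))
                } else newSets <- c(newSets, list(s))
            }
            # absorb: drop sets contained in another set
            keep <- rep(TRUE, length(newSets))
            for (i in seq_along(newSets)) for (j in seq_along(newSets)) {
                if (i != j && keep[i] && keep[j] &&
                    all(newSets[[i]] %in% newSets[[j]]) &&
                    (length(newSets[[i]]) < length(newSets[[j]]) || i > j))
                    keep[i] <- FALSE
            }
            sets <- newSets[keep]
        }
    }
    # order letters by the position of their first member
    ord <- order(vapply(sets, function(s)
        min(match(s, groupNames)), numeric(1)))
    sets <- sets[ord]
    letters_out <- vapply(groupNames, function(g)
        paste(letters[which(vapply(sets, function(s) g %in% s,
                                   logical(1)))], collapse = ""),
        character(1))
    letters_out
}

#' One-way ANOVA with Tukey-Kramer HSD and compact letter display
#'
#' Fits a one-way ANOVA, runs pairwise Tukey HSD (Tukey-Kramer for
#' unequal n), and summarises the pairwise outcome as compact letters
#' via the greedy insert-absorb algorithm: groups sharing a letter are
#' not significantly different at \code{alpha}. Groups are lettered in
#' input factor-level order; means and standard errors accompany the
#' letters as in standard survey tables.
#'
#' @param values numeric response.
#' @param groups factor of group labels.
#' @param alpha significance level (default 0.05).
#' @return list with \code{statistic} (F), \code{p_value},
#'   \code{summary} (data.frame: group, n, mean, se, letter),
#'   \code{tukey} (pairwise table), \code{degenerate} (TRUE when all
#'   within-group variance is zero).
#' @export
anovaTukey <- function(values, groups, alpha = 0.05) {
    groups <- droplevels(as.factor(groups))
    if (nlevels(groups) < 2) stop("need >= 2 groups")
    if (any(table(groups) < 2)) stop("every group needs >= 2 observations")
    wvar <- tapply(values, groups, stats::var)
    degenerate <- all(wvar < .Machine$double.eps)
    means <- tapply(values, groups, mean)
    ses <- tapply(values, groups, function(v) stats::sd(v) / sqrt(length(v)))
    ns <- as.integer(table(groups))
    if (degenerate) {
        eq <- isTRUE(max(means) - min(means) < .Machine$double.eps)
        letter <- if (eq) rep("a", nlevels(groups))
                  else letters[seq_len(nlevels(groups))]
        return(list(statistic = NA_real_, p_value = NA_real_,
            summary = data.frame(group = levels(groups), n = ns,
                mean = as.numeric(means), se = as.numeric(ses),
                letter = letter, row.names = NULL),
            tukey = NULL, degenerate = TRUE))
    }
    # hyphen-free internal level codes so the Tukey pair labels parse
    codes <- paste0("G", seq_len(nlevels(groups)))
    gcode <- factor(codes[as.integer(groups)], levels = codes)
    fit <- stats::aov(values ~ gcode)
    an <- summary(fit)[[1L]]
    tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$gcode
    k <- nlevels(groups)
    sigdiff <- matrix(FALSE, k, k, dimnames = list(codes, codes))
    comps <- strsplit(rownames(tuk), "-", fixed = TRUE)
    for (i in seq_along(comps)) {
        g1 <- comps[[i]][1L]; g2 <- comps[[i]][2L]
        sigdiff[g1, g2] <- sigdiff[g2, g1] <- tuk[i, "p adj"] < alpha
    }
    letter <- cldInsertAbsorb_(codes, sigdiff)
    tukTab <- as.data.frame(tuk)
    rownames(tukTab) <- vapply(comps, function(cc) paste(
        levels(groups)[match(cc, codes)], collapse = " vs "), character(1))
    list(statistic = an[["F value"]][1L], p_value = an[["Pr(>F)"]][1L],
         summary = data.frame(group = levels(groups), n = ns,
             mean = as.numeric(means), se = as.numeric(ses),
             letter = unname(letter), row.names = NULL),
         tukey = tukTab, degenerate = FALSE)
}

#' Spearman correlations between dominant taxa and environmental variables
#'
#' For the \code{top_n} most abundant taxa (by mean relative abundance)
#' and every environmental variable: Spearman rho with average ranks for
#' ties, two-sided p (exact enumeration below 10 samples, t
#' approximation otherwise), BH-adjusted q across the whole matrix, and
#' significance stars on the raw p as such heatmaps print them.
#' Constant variables yield missing rho.
#'
#' @param relabund taxa-x-samples relative-abundance matrix.
#' @param env data.frame of numeric variables, rows aligned to samples
#'   (a \code{sample_id} column, if present, is used for alignment and
#'   dropped).
#' @param top_n number of taxa to screen (default 50).
#' @param alpha significance level for the per-variable summary.
#' @return list with \code{table} (taxon, variable, rho, p, q, stars)
#'   and \code{by_variable} (per variable the fraction of top-n taxa
#'   significantly correlated at raw p < alpha).
#' @export
envCorrelation <- function(relabund, env, top_n = 50, alpha = 0.05) {
    relabund <- as.matrix(relabund)
    if ("sample_id" %in% colnames(env)) {
        rownames(env) <- env$sample_id
        env <- env[, setdiff(colnames(env), "sample_id"), drop = FALSE]
    }
    if (!is.null(colnames(relabund)) &&
        all(colnames(relabund) %in% rownames(env)))
        env <- env[colnames(relabund), , drop = FALSE]
    if (nrow(env) != ncol(relabund))
        stop("environmental rows must match samples")
    if (top_n > nrow(relabund)) stop("top_n exceeds number of taxa")
    top <- names(sort(rowMeans(relabund), decreasing = TRUE))[seq_len(top_n)]
    n <- ncol(relabund)
    rows <- list()
    for (tx in top) for (v in colnames(env)) {
        ev <- env[[v]]
        if (max(ev) == min(ev)) {
            rows[[length(rows) + 1L]] <- data.frame(taxon = tx,
                variable = v, rho = NA_real_, p = NA_real_)
            next
        }
        ct <- suppressWarnings(stats::cor.test(relabund[tx, ], ev,
            method = "spearman", exact = n < 10))
        rows[[length(rows) + 1L]] <- data.frame(taxon = tx, variable = v,
            rho = unname(ct$estimate), p = ct$p.value)
    }
    tab <- do.call(rbind, rows)
    tab$q <- stats::p.adjust(tab$p, "BH")
    tab$stars <- ifelse(is.na(tab$p), "",
        ifelse(tab$p < 0.001, "***",
        ifelse(tab$p < 0.01, "**", ifelse(tab$p < alpha, "*", ""))))
    byv <- do.call(rbind, lapply(split(tab, tab$variable), function(s) {
        ok <- !is.na(s$p)
        data.frame(variable = s$variable[1L],
                   n_significant = sum(s$p[ok] < alpha),
                   n_taxa = sum(ok),
                   fraction_significant =
                       if (any(ok)) sum(s$p[ok] < alpha) / sum(ok) else NA,
                   row.names = NULL)
    }))
    list(table = tab, by_variable = byv[order(-byv$fraction_significant), ])
}
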