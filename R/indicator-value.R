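# per-taxon IndVal statistic for one label assignment, all taxa at once.
# m: taxa x samples, groups: factor. Returns list(iv, best) where iv is
# the max over groups of A*B and best the argmax group.
indvalStat_ <- function(m, groups) {
    gs <- levels(groups)
    sizes <- as.vector(table(groups))                # in level order
    gm <- rowsum(t(m), groups)[gs, , drop = FALSE] / sizes
    gm <- t(gm)                                      # taxa x groups means
    tot <- rowSums(gm)
    A <- gm / ifelse(tot > 0, tot, 1)
    B <- t(rowsum(t(m > 0) + 0, groups)[gs, , drop = FALSE] / sizes)
    iv <- A * B
    best <- max.col(iv, ties.method = "first")
    list(iv = iv[cbind(seq_len(nrow(m)), best)],
         best = levels(groups)[best], A = A, B = B)
}

#' Dufrene-Legendre indicator species analysis
#'
#' For every taxon t and group g: specificity A = (mean relative
#' abundance of t in g) / (sum of t's group means) -- group means, not
#' raw sums, so unbalanced designs do not bias A -- and fidelity B =
#' fraction of g's samples where t is present (> 0). IndVal_g = A x B;
#' the taxon's IndVal is the maximum over groups and its best group the
#' argmax. Significance by permuting whole sample labels (taxon
#' covariance preserved): p = (1 + #\{perm IndVal >= obs\}) /
#' (1 + n_perm); with \code{exhaustive = TRUE} all distinct label
#' arrangements are enumerated (p = share with IndVal >= observed).
#'
#' @param relabund taxa-x-samples relative-abundance matrix.
#' @param groups factor of group labels (>= 2 groups, each >= 2
#'   samples).
#' @param n_perm Monte-Carlo permutations (default 999).
#' @param seed integer seed.
#' @param exhaustive enumerate all distinct label permutations.
#' @param indval_min,alpha thresholds for the strong-indicator flag
#'   (defaults IndVal > 0.7 and raw p < 0.05).
#' @return data.frame: \code{taxon_id}, \code{best_group}, \code{A},
#'   \code{B}, \code{indval}, \code{p}, \code{q} (BH), and
#'   \code{strong_flag} (IndVal > \code{indval_min} AND raw p <
#'   \code{alpha}). Taxa absent everywhere are skipped with a warning.
#' @export
indicatorValue <- function(relabund, groups, n_perm = 999, seed = 1L,
                           exhaustive = FALSE, indval_min = 0.7,
                           alpha = 0.05) {
    m <- as.matrix(relabund)
    groups <- droplevels(as.factor(groups))
    if (nlevels(groups) < 2) stop("need >= 2 groups")
    if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
    if (ncol(m) != length(groups)) stop("groups must match samples")
    absent <- rowSums(m) == 0
    if (any(absent)) {
        warning(sum(absent), " taxa absent everywhere; skipped")
        m <- m[!absent, , drop = FALSE]
    }
    obs <- indvalStat_(m, groups)
    nt <- nrow(m)
    if (exhaustive) {
        perms <- allLabelPermutations(as.character(groups))
        hits <- integer(nt); tot <- length(perms)
        for (lab in perms) {
            iv <- indvalStat_(m, factor(lab, levels = levels(groups)))$iv
            hits <- hits + (iv >= obs$iv - 1e-12)
        }
        p <- hits / tot
        n_eff <- tot
    } else {
        if (n_perm < 1) stop("n_perm must be >= 1")
        hits <- withSeed(seed, {
            h <- integer(nt)
            for (i in seq_len(n_perm)) {
                iv <- indvalStat_(m, sample(groups))$iv
                h <- h + (iv >= obs$iv - 1e-12)
            }
            h
        })
        p <- (1 + hits) / (1 + n_perm)
        n_eff <- n_perm
    }
    out <- data.frame(taxon_id = rownames(m), best_group = obs$best,
        A = obs$A[cbind(seq_len(nt), match(obs$best, levels(groups)))],
        B = obs$B[cbind(seq_len(nt), match(obs$best, levels(groups)))],
        indval = obs$iv, p = p, q = stats::p.adjust(p, "BH"),
        row.names = NULL)
    out$strong_flag <- out$indval > indval_min & out$p < alpha
    attr(out, "n_perm") <- n_eff
    out
}

#' Cross-tabulate indicators by region and abundance class
#'
#' Counts significant indicators (raw p < \code{alpha}) and strong
#' indicators (IndVal > \code{indval_min} AND p < \code{alpha}) per
#' best group and per AT/IT/RT class, plus the class shares among
#' indicators.
#'
#' @param results output of \code{\link{indicatorValue}}.
#' @param assignment output of \code{\link{classifyTaxa}}.
#' @param indval_min,alpha thresholds (defaults 0.7, 0.05).
#' @return list with \code{counts} (data.frame: region, label,
#'   n_indicator, n_strong), \code{class_share} (share of each class
#'   among significant indicators) and totals.
#' @export
summarizeIndicators <- function(results, assignment, indval_min = 0.7,
                                alpha = 0.05) {
    if (!nrow(results)) stop("empty indicator result set")
    lab <- assignment$label[match(results$taxon_id, assignment$taxon_id)]
    sig <- results$p < alpha
    strong <- sig & results$indval > indval_min
    regs <- sort(unique(results$best_group))
    cls <- levels(assignment$label)
    counts <- do.call(rbind, lapply(regs, function(r)
        do.call(rbind, lapply(cls, function(k) data.frame(
            region = r, label = k,
            n_indicator = sum(sig & results$best_group == r & lab == k,
                              na.rm = TRUE),
            n_strong = sum(strong & results$best_group == r & lab == k,
                           na.rm = TRUE), row.names = NULL)))))
    share <- if (any(sig)) {
        tab <- table(factor(lab[sig], levels = cls))
        as.numeric(tab) / sum(tab)
    } else rep(NA_real_, length(cls))
    names(share) <- cls
    list(counts = counts, class_share = share,
         n_indicator = sum(sig), n_strong = sum(strong))
}
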