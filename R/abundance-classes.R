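#' Partition OTUs into abundant, intermediate and rare taxa
#'
#' Dual-threshold classification on relative abundances, combining a
#' local (within-sample maximum) and a regional (mean across all
#' samples) criterion:
#' \itemize{
#'   \item abundant (\code{AT}): local relative abundance exceeds 1\% in
#'     at least one sample AND mean relative abundance across all
#'     samples is at least 0.1\%;
#'   \item rare (\code{RT}): local relative abundance stays below 0.01\%
#'     in every sample AND the mean is below 0.001\%;
#'   \item intermediate (\code{IT}): everything else.
#' }
#' The AT conditions use strict \code{>} on the local threshold and
#' \code{>=} on the mean; the RT conditions are strict \code{<} on both.
#' Classification is computed on the pooled table across all samples;
#' per-region membership is obtained downstream by intersecting with
#' regional presence.
#'
#' @param relabund numeric matrix of per-sample relative abundances
#'   (taxa x samples, columns summing to 1), e.g.
#'   \code{relAbundance(x)}.
#' @param thresholds named list overriding the defaults
#'   \code{list(at_local = 0.01, at_mean = 0.001, rt_local = 1e-4,
#'   rt_mean = 1e-5)}.
#' @return data.frame with columns \code{taxon_id}, \code{label}
#'   (factor \code{AT}/\code{IT}/\code{RT}), \code{max_local_relabund},
#'   \code{mean_relabund}.
#' @examples
#' m <- matrix(c(0.99, 0.01, 0.5, 0.5), nrow = 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' classifyTaxa(m)
#' @export
classifyTaxa <- function(relabund,
                         thresholds = list(at_local = 0.01, at_mean = 0.001,
                                           rt_local = 1e-4, rt_mean = 1e-5)) {
    relabund <- as.matrix(relabund)
    if (nrow(relabund) == 0L || ncol(relabund) == 0L)
        stop("empty relative-abundance table")
    stopifnot(thresholds$at_local > thresholds$at_mean,
              thresholds$at_mean > thresholds$rt_local,
              thresholds$rt_local > thresholds$rt_mean)
    mx <- apply(relabund, 1L, max)
    mn <- rowMeans(relabund)
    label <- rep("IT", nrow(relabund))
    label[mx > thresholds$at_local & mn >= thresholds$at_mean] <- "AT"
    label[mx < thresholds$rt_local & mn < thresholds$rt_mean] <- "RT"
    data.frame(taxon_id = rownames(relabund),
               label = factor(label, levels = c("AT", "IT", "RT")),
               max_local_relabund = mx, mean_relabund = mn,
               row.names = NULL)
}

#' Per-region richness and abundance share of each abundance class
#'
#' Cross-tabulates the AT/IT/RT assignment with regional presence:
#' for every region, the fraction of that region's OTUs in each class
#' (richness share) and the fraction of the region's pooled reads in
#' each class (abundance share). Heavy-tailed communities show the
#' characteristic decoupling -- rare taxa dominate richness while
#' abundant taxa dominate reads.
#'
#' @param assignment result of \code{\link{classifyTaxa}}.
#' @param x the \linkS4class{OtuExperiment} the assignment was computed
#'   from (must carry a \code{region} column).
#' @return data.frame with columns \code{region}, \code{label},
#'   \code{n_otus}, \code{richness_fraction}, \code{abundance_fraction}.
#'   Fractions sum to 1 within each region.
#' @export
classSummary <- function(assignment, x) {
    pool <- poolByRegion(x)
    lab <- assignment$label
    names(lab) <- assignment$taxon_id
    regs <- colnames(pool$pooled_relabund)
    out <- do.call(rbind, lapply(regs, function(r) {
        pres <- pool$present[[r]]
        relab <- pool$pooled_relabund[, r]
        cls <- lab[pres]
        n <- table(cls)
        ab <- vapply(levels(lab), function(k)
            sum(relab[pres[cls == k]]), numeric(1))
        data.frame(region = r, label = levels(lab),
                   n_otus = as.integer(n[levels(lab)]),
                   richness_fraction = as.numeric(n[levels(lab)] / length(pres)),
                   abundance_fraction = ab / sum(relab[pres]),
                   row.names = NULL)
    }))
    out
}

#' Write an abundance-class assignment to TSV
#'
#' @param assignment result of \code{\link{classifyTaxa}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeClassAssignment <- function(assignment, path) {
    utils::write.table(assignment, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
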