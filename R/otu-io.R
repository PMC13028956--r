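#' Construct an OtuExperiment
#'
#' @param counts integer matrix, taxa as rows (row names = taxon ids),
#'   samples as columns (column names = sample ids).
#' @param sampleData data.frame of per-sample metadata, one row per
#'   sample in column order (or with row names matching sample ids);
#'   typically holds \code{region}, \code{plot}, \code{replicate},
#'   \code{date}.
#' @param tree optional rooted \code{ape::phylo} covering all taxa.
#' @return a validated \linkS4class{OtuExperiment}.
#' @examples
#' m <- matrix(c(5, 3, 2, 0, 7, 3), nrow = 3,
#'             dimnames = list(paste0("OTU", 1:3), c("s1", "s2")))
#' OtuExperiment(m, data.frame(region = c("hPollut", "HABs")))
#' @export
OtuExperiment <- function(counts, sampleData = NULL, tree = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    if (is.null(sampleData))
        sampleData <- DataFrame(row.names = colnames(counts))
    else {
        sampleData <- DataFrame(sampleData)
        if (is.null(rownames(sampleData)) ||
            all(rownames(sampleData) == as.character(seq_len(nrow(sampleData)))))
            rownames(sampleData) <- colnames(counts)
        else {
            miss <- setdiff(colnames(counts), rownames(sampleData))
            if (length(miss))
                stop("samples without metadata: ", paste(miss, collapse = ", "))
            sampleData <- sampleData[colnames(counts), , drop = FALSE]
        }
    }
    se <- SummarizedExperiment(assays = list(counts = counts),
                               colData = sampleData)
    new("OtuExperiment", se, tree = tree)
}

#' Read an OTU count table from TSV
#'
#' Expects a tab-delimited UTF-8 file whose header row carries sample
#' ids and whose first column carries taxon ids. If the first header
#' field is \code{#sample_id} the table is stored transposed
#' (samples as rows) and is transposed back on read.
#'
#' @param path file path.
#' @return an \linkS4class{OtuExperiment} without sample metadata.
#' @export
readOtuTable <- function(path) {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
        check.names = FALSE, stringsAsFactors = FALSE, comment.char = "")
    first <- colnames(raw)[1L]
    ids <- as.character(raw[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate ids in first column of ", path, " (e.g. ",
             ids[duplicated(ids)][1L], ")")
    m <- as.matrix(raw[, -1L, drop = FALSE])
    if (anyDuplicated(colnames(m)))
        stop("duplicate ids in header of ", path)
    if (!is.numeric(m))
        stop("non-numeric cells in ", path)
    if (any(m < 0) || any(m != floor(m)))
        stop("counts must be non-negative integers in ", path)
    rownames(m) <- ids
    if (identical(first, "#sample_id")) m <- t(m)
    OtuExperiment(m)
}

#' Write an OTU count table to TSV (canonical formatting)
#'
#' Canonical form: first header field \code{taxon_id}, sample ids as the
#' remaining header fields, integer-formatted counts, Unix newlines.
#' \code{readOtuTable(writeOtuTable(x, f))} restores identical counts
#' and ids, and re-writing reproduces the file byte for byte.
#'
#' @param x an \linkS4class{OtuExperiment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeOtuTable <- function(x, path) {
    m <- otuCounts(x)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(c("taxon_id", colnames(m)), collapse = "\t"), con,
               sep = "\n")
    body <- apply(m, 1L, function(r)
        paste(format(r, scientific = FALSE, trim = TRUE), collapse = "\t"))
    writeLines(paste(rownames(m), body, sep = "\t"), con, sep = "\n")
    invisible(path)
}

#' Read sample metadata / environmental tables
#'
#' Plain TSV readers with joint-consistency checks: metadata must carry
#' \code{sample_id} and \code{region} columns; environmental tables must
#' carry \code{sample_id} plus numeric variables, all finite.
#'
#' @param path file path.
#' @return data.frame with \code{sample_id} row names.
#' @export
readSampleMetadata <- function(path) {
    d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("sample_id", "region") %in% colnames(d)))
        stop("metadata requires 'sample_id' and 'region' columns")
    if (anyDuplicated(d$sample_id))
        stop("duplicate sample_id in metadata")
    tab <- table(d$region)
    if (any(tab < 2))
        stop("every region needs >= 2 samples; offending: ",
             paste(names(tab)[tab < 2], collapse = ", "))
    rownames(d) <- d$sample_id
    d
}

#' @rdname readSampleMetadata
#' @export
readEnvTable <- function(path) {
    d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
    if (!"sample_id" %in% colnames(d))
        stop("environmental table requires a 'sample_id' column")
    num <- d[, setdiff(colnames(d), "sample_id"), drop = FALSE]
    if (!all(vapply(num, is.numeric, logical(1))))
        stop("environmental variables must be numeric")
    if (!all(vapply(num, function(v) all(is.finite(v)), logical(1))))
        stop("environmental values must be finite")
    rownames(d) <- d$sample_id
    d
}

#' Read a rooted Newick phylogeny
#'
#' @param path Newick file.
#' @param taxa optional taxon ids that must all be tips.
#' @return an \code{ape::phylo} object.
#' @export
readPhyloTree <- function(path, taxa = NULL) {
    tr <- ape::read.tree(path)
    if (is.null(tr$edge.length)) stop("tree has no branch lengths")
    if (any(tr$edge.length < 0)) stop("negative branch lengths")
    if (!is.null(taxa)) {
        miss <- setdiff(taxa, tr$tip.label)
        if (length(miss))
            stop(length(miss), " taxa missing from tree (e.g. ", miss[1L], ")")
    }
    tr
}

#' Rarefy counts to an even depth
#'
#' Random subsampling without replacement within each sample, the
#' standard normalisation before Shannon and Bray-Curtis comparisons of
#' unequal sequencing effort. Reproducible for a fixed seed.
#'
#' @param x an \linkS4class{OtuExperiment}.
#' @param depth target per-sample total; defaults to the minimum column
#'   sum.
#' @param seed integer seed.
#' @return an \linkS4class{OtuExperiment} whose columns all sum to
#'   \code{depth}.
#' @export
rarefyCounts <- function(x, depth = NULL, seed = 1L) {
    m <- otuCounts(x)
    cs <- colSums(m)
    if (is.null(depth)) depth <- min(cs)
    depth <- as.integer(depth)
    if (depth < 1) stop("depth must be positive")
    bad <- cs < depth
    if (any(bad))
        stop("depth ", depth, " exceeds total count of sample(s): ",
             paste(colnames(m)[bad], collapse = ", "))
    out <- withSeed(seed, {
        cols <- lapply(seq_len(ncol(m)), function(j) {
            pool <- rep.int(seq_len(nrow(m)), m[, j])
            tabulate(pool[sample.int(length(pool), depth)], nbins = nrow(m))
        })
        matrix(unlist(cols), nrow = nrow(m))
    })
    dimnames(out) <- dimnames(m)
    OtuExperiment(out, as.data.frame(colData(x)), tree = x@tree)
}

#' Pool samples by region: presence sets, Venn cells, shared fractions
#'
#' For each region, the set of OTUs with pooled count > 0; the all-region
#' shared (core) set, the region-specific sets, the full Venn cell
#' breakdown, and pooled per-region relative abundances. The shared
#' percentage is reported against two denominators -- the union of all
#' OTUs and the sum of per-region richness -- both labelled, because
#' per-region percentages in survey reports use inconsistent bases.
#'
#' @param x an \linkS4class{OtuExperiment} with a \code{region} column.
#' @return list with \code{present} (per-region taxon sets),
#'   \code{shared}, \code{specific}, \code{cells} (Venn cell sizes named
#'   by membership pattern), \code{richness}, \code{pooled_relabund}
#'   (taxa x regions), \code{shared_fraction_union},
#'   \code{shared_fraction_sum} and \code{shared_abundance_overall}.
#' @export
poolByRegion <- function(x) {
    m <- otuCounts(x)
    region <- sampleRegion(x)
    regs <- levels(region)
    pooled <- vapply(regs, function(r)
        rowSums(m[, region == r, drop = FALSE]), numeric(nrow(m)))
    present <- lapply(regs, function(r) rownames(m)[pooled[, r] > 0])
    names(present) <- regs
    inAny <- rowSums(pooled > 0) > 0
    union_set <- rownames(m)[inAny]
    shared <- rownames(m)[rowSums(pooled > 0) == length(regs)]
    specific <- lapply(regs, function(r)
        rownames(m)[pooled[, r] > 0 & rowSums(pooled > 0) == 1])
    names(specific) <- regs
    pattern <- apply(pooled > 0, 1L, function(z)
        paste(regs[z], collapse = "&"))
    cells <- table(pattern[inAny])
    relab <- sweep(pooled, 2L, colSums(pooled), "/")
    sharedMask <- rownames(m) %in% shared
    list(present = present,
         shared = shared,
         specific = specific,
         union = union_set,
         cells = cells,
         richness = colSums(pooled > 0),
         pooled_relabund = relab,
         shared_fraction_union = fractionTriple(length(shared),
             length(union_set), "shared OTUs / union of all OTUs"),
         shared_fraction_sum = fractionTriple(length(shared),
             sum(pooled > 0), "shared OTUs / sum of per-region richness"),
         shared_abundance_overall = sum(m[sharedMask, ]) / sum(m),
         shared_abundance_by_region = colSums(relab[sharedMask, ,
             drop = FALSE]))
}

#' Summed relative abundance of a taxon subset per region
#'
#' @param pool result of \code{\link{poolByRegion}}.
#' @param taxa character vector of taxon ids.
#' @return named numeric, one pooled relative-abundance share per region.
#' @export
subsetAbundanceByRegion <- function(pool, taxa) {
    colSums(pool$pooled_relabund[rownames(pool$pooled_relabund) %in% taxa, ,
                                 drop = FALSE])
}
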