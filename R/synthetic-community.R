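#' Simulation configuration for synthetic communities
#'
#' Bundles the generator's knobs with the defaults that emulate a
#' three-region, 48-sample lake survey: an unbalanced design of 18/12/18
#' samples (hPollut/HABs/SubmP; 3+2+3 plots x 3 replicates x 2 dates),
#' sequencing depth 20,000 reads per sample, and a heavy-tailed
#' log-normal metacommunity (meanlog 0, sdlog 2) so abundant,
#' intermediate and rare classes all arise and the abundant class
#' carries most reads.
#'
#' @param n_taxa number of taxa in the metacommunity (default 1000).
#' @param samples_per_region named integer vector (default
#'   \code{c(hPollut = 18, HABs = 12, SubmP = 18)}).
#' @param depth reads per sample (default 20000; a warning below 100,
#'   where abundance classes degenerate).
#' @param regime one of \code{"neutral"},
#'   \code{"filtering_heterogeneous"}, \code{"filtering_homogeneous"},
#'   \code{"dispersal_limited"}, \code{"mixed"}.
#' @param niche_breadth Gaussian niche width sigma, in units of the
#'   standard deviation of the niche optima across taxa (default 0.3:
#'   strong filtering; large values approach neutrality).
#' @param phylo_signal evolve niche optima with Brownian motion on the
#'   tree (TRUE) or shuffle them across tips (FALSE).
#' @param meanlog,sdlog log-normal metacommunity shape (defaults 0, 2).
#' @param drift_intensity Dirichlet concentration of per-sample
#'   demographic drift around the regime's expected composition
#'   (default 100, which yields the 0.2-0.4 between-replicate
#'   Bray-Curtis turnover typical of lake surveys; \code{Inf} disables
#'   drift, leaving pure multinomial sampling noise).
#' @param mixed_regimes named character vector assigning a regime per
#'   region when \code{regime = "mixed"}.
#' @param seed integer master seed.
#' @return a \code{SimulationConfig} list.
#' @export
simulationConfig <- function(n_taxa = 1000,
        samples_per_region = c(hPollut = 18, HABs = 12, SubmP = 18),
        depth = 20000, regime = "neutral", niche_breadth = 0.3,
        phylo_signal = TRUE, meanlog = 0, sdlog = 2,
        drift_intensity = 100,
        mixed_regimes = c(hPollut = "neutral",
                          HABs = "dispersal_limited",
                          SubmP = "filtering_heterogeneous"),
        seed = 1L) {
    regimes <- c("neutral", "filtering_heterogeneous",
                 "filtering_homogeneous", "dispersal_limited", "mixed")
    if (!regime %in% regimes)
        stop("unknown regime '", regime, "'")
    stopifnot(n_taxa >= 3, all(samples_per_region >= 1), depth >= 1,
              niche_breadth > 0, drift_intensity > 0)
    structure(list(n_taxa = as.integer(n_taxa),
        samples_per_region = samples_per_region, depth = as.integer(depth),
        regime = regime, niche_breadth = niche_breadth,
        phylo_signal = isTRUE(phylo_signal), meanlog = meanlog,
        sdlog = sdlog, drift_intensity = drift_intensity,
        mixed_regimes = mixed_regimes,
        seed = as.integer(seed)), class = "SimulationConfig")
}

#' Simulate an ultrametric Yule phylogeny
#'
#' Pure-birth tree with exponential waiting times, tips labelled
#' \code{OTU0001...}; branch lengths positive, tip-to-root depths equal.
#'
#' @param n_taxa number of tips (>= 3).
#' @param seed integer seed.
#' @return an \code{ape::phylo}.
#' @export
simulateTree <- function(n_taxa, seed = 1L) {
    if (n_taxa < 3) stop("n_taxa must be >= 3")
    tr <- withSeed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
    tr$tip.label <- sprintf("OTU%04d", seq_len(n_taxa))
    tr
}

#' Evolve phylogenetically conserved niche optima
#'
#' Brownian motion along branches (trait variance proportional to
#' branch length) yields the phylogenetic trait signal that betaNTI
#' presupposes. Because a single Brownian draw on a small tree can by
#' chance carry little tree-wide structure, draws are repeated until
#' the Mantel correlation between trait distance and patristic distance
#' reaches \code{min_signal} -- the conserved-trait contract this
#' generator exists to provide. With \code{signal = FALSE} the accepted
#' optima are shuffled across tips, destroying the signal while
#' preserving the marginal distribution.
#'
#' @param tree an \code{ape::phylo}.
#' @param signal keep the Brownian tip structure (default TRUE).
#' @param seed integer seed.
#' @param sigma Brownian rate (default 1).
#' @param min_signal minimum Spearman Mantel correlation between trait
#'   and patristic distances for an accepted draw (default 0.3,
#'   moderate conservation; set 0 to accept the first draw).
#' @param max_tries redraw budget (default 100; the best draw so far is
#'   returned with a warning if the floor is never reached).
#' @return named numeric vector of optima, one per tip.
#' @export
evolveNicheOptima <- function(tree, signal = TRUE, seed = 1L, sigma = 1,
                              min_signal = 0.3, max_tries = 100L) {
    withSeed(seed, {
        best <- NULL
        best_rho <- -Inf
        for (k in seq_len(max_tries)) {
            x <- ape::rTraitCont(tree, model = "BM", sigma = sigma)
            rho <- phyloSignalMantel(tree, x)
            if (is.na(rho)) rho <- -Inf   # e.g. zero-length trees
            if (is.null(best) || rho > best_rho) {
                best <- x
                best_rho <- rho
            }
            if (best_rho >= min_signal) break
        }
        if (best_rho < min_signal)
            warning(sprintf(
                "trait signal floor %.2f not reached (best %.2f)",
                min_signal, best_rho))
        x <- best
        if (!signal) {
            nm <- names(x)
            x <- sample(x)
            names(x) <- nm
        }
        x
    })
}

#' Mantel correlation between trait and patristic distances
#'
#' Spearman correlation across all tip pairs of |trait_i - trait_j|
#' against the patristic distance d(i, j): a simple scalar measure of
#' phylogenetic trait signal (positive when close relatives have
#' similar traits).
#'
#' @param tree an \code{ape::phylo}.
#' @param trait named numeric vector over the tips.
#' @return Spearman rho.
#' @export
phyloSignalMantel <- function(tree, trait) {
    D <- ape::cophenetic.phylo(tree)
    td <- as.matrix(stats::dist(trait[rownames(D)]))
    stats::cor(D[upper.tri(D)], td[upper.tri(td)], method = "spearman")
}

#' Simulate regional communities under a controlled assembly regime
#'
#' Metacommunity relative abundances are log-normal (heavy-tailed).
#' Per sample, the regime sets an expected composition, the local
#' community drifts around it (Dirichlet with concentration
#' \code{drift_intensity} -- demographic drift, so replicate samples
#' diverge compositionally, not just by sequencing noise), and counts
#' are a multinomial draw of \code{depth} reads. Regime-specific
#' expected compositions:
#' \itemize{
#'   \item \code{neutral}: weights = metacommunity (pure drift +
#'     homogenising sampling from one pool);
#'   \item \code{filtering_heterogeneous}: each region has its own
#'     environment on a one-dimensional latent gradient (the 5th, 50th
#'     and 95th percentiles of the niche optima), and weights are
#'     metacommunity x exp(-(optimum - E)^2 / (2 sigma^2)) -- distinct
#'     selective filters between regions;
#'   \item \code{filtering_homogeneous}: one common environment (median
#'     optimum) filters all samples identically;
#'   \item \code{dispersal_limited}: each region draws from a private
#'     metacommunity (an independent permutation of the abundances
#'     across taxa), producing strong compositional turnover without
#'     trait involvement;
#'   \item \code{mixed}: per-region regime assignment from
#'     \code{config$mixed_regimes}.
#' }
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param tree phylogeny with >= \code{n_taxa} handled tips; simulated
#'   via \code{\link{simulateTree}} when NULL.
#' @param optima named niche optima; evolved on the tree when NULL.
#' @return list with \code{otu} (an \linkS4class{OtuExperiment}
#'   carrying counts, region/plot/replicate/date metadata and the tree)
#'   and \code{truth} (regime, metacommunity, optima, per-sample
#'   environment).
#' @export
simulateCommunities <- function(config, tree = NULL, optima = NULL) {
    stopifnot(inherits(config, "SimulationConfig"))
    if (config$depth < 100)
        warning("depth < 100: abundance classes will be degenerate")
    if (is.null(tree))
        tree <- simulateTree(config$n_taxa, stageSeed(config$seed, "tree"))
    if (is.null(optima))
        optima <- evolveNicheOptima(tree, signal = config$phylo_signal,
            seed = stageSeed(config$seed, "optima"))
    taxa <- tree$tip.label[seq_len(config$n_taxa)]
    optima <- optima[taxa]
    spr <- config$samples_per_region
    regs <- names(spr)
    region <- factor(rep(regs, spr), levels = regs)
    n_s <- length(region)
    sample_id <- unlist(lapply(regs, function(r)
        sprintf("%s_%02d", r, seq_len(spr[[r]]))))
    meta <- data.frame(sample_id = sample_id, region = region,
        plot = unlist(lapply(spr, function(n)
            paste0("P", ((seq_len(n) - 1L) %/% 6L) + 1L))),
        replicate = unlist(lapply(spr, function(n)
            ((seq_len(n) - 1L) %% 3L) + 1L)),
        date = unlist(lapply(spr, function(n)
            ifelse(((seq_len(n) - 1L) %/% 3L) %% 2L == 0L,
                   "2024-07-16", "2024-10-15"))),
        row.names = sample_id)
    out <- withSeed(stageSeed(config$seed, "communities"), {
        metacomm <- stats::rlnorm(config$n_taxa, config$meanlog,
                                  config$sdlog)
        metacomm <- metacomm / sum(metacomm)
        names(metacomm) <- taxa
        sig <- config$niche_breadth * stats::sd(optima)
        E_het <- stats::quantile(optima, c(0.05, 0.5, 0.95), names = FALSE)
        names(E_het) <- regs
        E_hom <- stats::median(optima)
        privatePools <- lapply(regs, function(r)
            metacomm[sample.int(config$n_taxa)])
        names(privatePools) <- regs
        regimeOf <- function(r) {
            if (config$regime == "mixed") config$mixed_regimes[[r]]
            else config$regime
        }
        E_s <- numeric(n_s)
        counts <- matrix(0, config$n_taxa, n_s,
                         dimnames = list(taxa, sample_id))
        for (j in seq_len(n_s)) {
            r <- as.character(region[j])
            w <- switch(regimeOf(r),
                neutral = metacomm,
                filtering_heterogeneous = {
                    E_s[j] <- E_het[[r]]
                    metacomm * exp(-(optima - E_het[[r]])^2 / (2 * sig^2))
                },
                filtering_homogeneous = {
                    E_s[j] <- E_hom
                    metacomm * exp(-(optima - E_hom)^2 / (2 * sig^2))
                },
                dispersal_limited = unname(privatePools[[r]]),
                stop("unknown regime"))
            w <- w / sum(w)
            if (is.finite(config$drift_intensity)) {
                g <- stats::rgamma(config$n_taxa,
                    shape = config$drift_intensity * w)
                if (sum(g) > 0) w <- g / sum(g)
            }
            counts[, j] <- stats::rmultinom(1L, config$depth,
                                            prob = w)[, 1L]
        }
        list(counts = counts, metacomm = metacomm, E_s = E_s)
    })
    keepTips <- if (length(tree$tip.label) > config$n_taxa)
        ape::keep.tip(tree, taxa) else tree
    list(otu = OtuExperiment(out$counts, meta, tree = keepTips),
         truth = list(regime = config$regime, config = config,
                      metacommunity = out$metacomm, optima = optima,
                      environment = out$E_s))
}

#' Plant block-correlated taxa for network ground truth
#'
#' Latent multivariate normal with block-diagonal correlation
#' (\code{within_rho} inside blocks, zero between), exponentiated to
#' expected abundances and multinomially sampled to counts; returns the
#' planted module labels so network inference can be scored against
#' truth.
#'
#' @param n_blocks number of correlated blocks (default 3).
#' @param block_size taxa per block (default 10).
#' @param within_rho latent within-block correlation, in (0, 1) --
#'   0 is allowed and yields independent taxa for null calibration.
#' @param n_samples number of samples (default 30).
#' @param depth reads per sample (default 50000).
#' @param n_noise additional independent taxa (default 0).
#' @param seed integer seed.
#' @return list with \code{otu} (an \linkS4class{OtuExperiment}) and
#'   \code{blocks} (named integer vector; noise taxa = 0).
#' @export
injectNetworkStructure <- function(n_blocks = 3, block_size = 10,
                                   within_rho = 0.7, n_samples = 30,
                                   depth = 50000, n_noise = 0,
                                   seed = 1L) {
    if (within_rho < 0 || within_rho >= 1)
        stop("within_rho must be in [0, 1)")
    nt <- n_blocks * block_size + n_noise
    Sigma <- diag(nt)
    for (b in seq_len(n_blocks)) {
        idx <- ((b - 1) * block_size + 1):(b * block_size)
        Sigma[idx, idx] <- within_rho
        diag(Sigma)[idx] <- 1
    }
    taxa <- sprintf("OTU%04d", seq_len(nt))
    counts <- withSeed(seed, {
        Z <- MASS::mvrnorm(n_samples, mu = numeric(nt), Sigma = Sigma)
        lam <- exp(t(Z))          # taxa x samples expected abundance
        vapply(seq_len(n_samples), function(j)
            stats::rmultinom(1L, depth, prob = lam[, j])[, 1L],
            numeric(nt))
    })
    dimnames(counts) <- list(taxa, sprintf("S%02d", seq_len(n_samples)))
    blocks <- c(rep(seq_len(n_blocks), each = block_size),
                rep(0L, n_noise))
    names(blocks) <- taxa
    list(otu = OtuExperiment(counts), blocks = blocks)
}

#' Reference water-chemistry profile of the three survey regions
#'
#' Region means and standard errors for the 12 physicochemical
#' variables of the emulated survey (per-region n = 18/12/18), on the
#' scales the variables are conventionally reported in (mg/L for
#' nutrients and oxygen demand, ug/L chlorophyll-a, degrees C, uS/cm).
#'
#' @return data.frame: variable, region, mean, se, n.
#' @export
envReference <- function() {
    vars <- c("BOD5", "COD", "TP", "TN", "SS", "Chl_a", "CODMn", "pH",
              "DO", "temperature", "transparency", "conductivity")
    mean_tab <- rbind(
        c(4.1, 3.9, 3.64), c(36.2, 42.4, 42.5), c(0.13, 0.12, 0.10),
        c(3.2, 2.1, 1.90), c(29.1, 23, 22.56), c(94.1, 82.5, 65.9),
        c(8.1, 9.4, 9.16), c(9.02, 9.08, 9.02), c(10.7, 9.34, 8.63),
        c(23.9, 23.01, 22.69), c(43.4, 43.17, 45.89),
        c(485.9, 524.58, 528.78))
    se_tab <- rbind(
        c(0.2, 0.3, 0.21), c(1.9, 2.2, 1.14), c(0.01, 0.01, 0.01),
        c(0.11, 0.1, 0.06), c(3.3, 1.67, 1.45), c(11.1, 7.5, 4.5),
        c(0.5, 0.25, 0.21), c(0.1, 0.1, 0.07), c(0.3, 0.32, 0.35),
        c(0.4, 0.29, 0.28), c(3.5, 2.27, 1.8), c(11.8, 2.77, 1.78))
    regs <- c("hPollut", "HABs", "SubmP")
    ns <- c(hPollut = 18, HABs = 12, SubmP = 18)
    data.frame(variable = rep(vars, each = 3),
               region = rep(regs, times = length(vars)),
               mean = as.vector(t(mean_tab)), se = as.vector(t(se_tab)),
               n = rep(unname(ns), times = length(vars)),
               row.names = NULL)
}

#' Simulate a Table-1-like environmental table
#'
#' Per region and variable, draws Normal(mean, se * sqrt(n)) -- the
#' per-sample standard deviation implied by the reported standard
#' error -- with concentrations truncated at zero. An optional coupling
#' makes one variable rank-correlated with a supplied taxon-abundance
#' vector at a target Spearman rho (Gaussian-copula rank blending;
#' rho = 1 is exactly monotone), for correlation-recovery tests; the
#' coupled variable's regional structure is overridden by the coupling.
#'
#' @param meta sample metadata with \code{sample_id} and \code{region}.
#' @param seed integer seed.
#' @param reference reference profile as from \code{\link{envReference}}.
#' @param coupling optional list(variable =, abundance =, rho =).
#' @return data.frame with \code{sample_id} and the 12 variables.
#' @export
simulateEnvTable <- function(meta, seed = 1L, reference = envReference(),
                             coupling = NULL) {
    stopifnot(all(c("sample_id", "region") %in% colnames(meta)))
    nonneg <- c("BOD5", "COD", "TP", "TN", "SS", "Chl_a", "CODMn", "DO",
                "transparency", "conductivity")
    out <- data.frame(sample_id = meta$sample_id, row.names = NULL)
    withSeed(seed, {
        for (v in unique(reference$variable)) {
            vals <- numeric(nrow(meta))
            for (r in unique(meta$region)) {
                ref <- reference[reference$variable == v &
                                 reference$region == r, ]
                if (!nrow(ref))
                    stop("no reference entry for ", v, " in region ", r)
                idx <- which(meta$region == r)
                vals[idx] <- stats::rnorm(length(idx), ref$mean,
                                          ref$se * sqrt(ref$n))
            }
            if (v %in% nonneg) vals <- pmax(vals, 0)
            out[[v]] <- vals
        }
        if (!is.null(coupling)) {
            v <- coupling$variable
            a <- coupling$abundance
            rho <- coupling$rho
            stopifnot(length(a) == nrow(meta), v %in% colnames(out))
            z <- scale(rank(a, ties.method = "average"))[, 1L]
            latent <- rho * z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(length(z))
            out[[v]] <- sort(out[[v]])[rank(latent, ties.method = "first")]
        }
    })
    out
}

#' Write a simulation to disk in the package's exchange formats
#'
#' Counts as canonical TSV, metadata as TSV, the tree as Newick, and a
#' truth TSV (niche optimum and metacommunity share per taxon).
#'
#' @param sim result of \code{\link{simulateCommunities}}.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeOtuTable(sim$otu, file.path(dir, "otu_table.tsv"))
    utils::write.table(as.data.frame(colData(sim$otu)),
        file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    if (!is.null(phyloTree(sim$otu)))
        ape::write.tree(phyloTree(sim$otu), file.path(dir, "tree.nwk"))
    truth <- data.frame(taxon_id = names(sim$truth$metacommunity),
        metacommunity = as.numeric(sim$truth$metacommunity),
        niche_optimum = as.numeric(sim$truth$optima),
        regime = sim$truth$regime)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(dir)
}
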