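test_that("simulated trees are ultrametric Yule trees with labelled tips", {
    expect_error(simulateTree(2), "n_taxa")
    tr3 <- simulateTree(3, seed = 1)
    expect_equal(length(tr3$tip.label), 3L)
    expect_equal(tr3$Nnode, 2L)
    tr <- simulateTree(80, seed = 2)
    depths <- ape::node.depth.edgelength(tr)[seq_len(80)]
    expect_lt(max(depths) - min(depths), 1e-9)
    expect_true(all(tr$edge.length > 0))
    D <- patristicDistances(tr)
    expect_true(isSymmetric(D))
    expect_true(all(diag(D) == 0))
    expect_true(all(D[upper.tri(D)] > 0))
    expect_equal(tr$tip.label[1], "OTU0001")
})

test_that("niche optima carry (or lose) phylogenetic signal as requested", {
    tr <- simulateTree(128, seed = 3)
    opt <- evolveNicheOptima(tr, signal = TRUE, seed = 4)
    expect_gte(phyloSignalMantel(tr, opt), 0.2)
    opt0 <- evolveNicheOptima(tr, signal = FALSE, seed = 4)
    expect_lt(abs(phyloSignalMantel(tr, opt0)), 0.1)
    expect_setequal(names(opt), tr$tip.label)
    # identical marginal distribution under the shuffle
    expect_equal(sort(unname(opt)), sort(unname(opt0)))
})

test_that("zero-length branches leave no room for trait variance", {
    flat <- ape::read.tree(text = "(A:0,B:0,C:0);")
    opt <- suppressWarnings(
        evolveNicheOptima(flat, seed = 1, min_signal = 0))
    expect_lt(max(opt) - min(opt), 1e-12)
})

test_that("identical configuration and seed reproduce identical output", {
    cfg <- simulationConfig(n_taxa = 40,
        samples_per_region = c(hPollut = 3, HABs = 2, SubmP = 3),
        depth = 500, regime = "mixed", seed = 7)
    s1 <- simulateCommunities(cfg)
    s2 <- simulateCommunities(cfg)
    expect_identical(otuCounts(s1$otu), otuCounts(s2$otu))
    expect_identical(s1$truth$metacommunity, s2$truth$metacommunity)
})

test_that("the default design mirrors the unbalanced regional survey", {
    cfg <- simulationConfig(n_taxa = 12, depth = 300, seed = 1)
    sim <- simulateCommunities(cfg)
    expect_equal(as.vector(table(sampleRegion(sim$otu))[c("hPollut",
        "HABs", "SubmP")]), c(18L, 12L, 18L))
    md <- as.data.frame(SummarizedExperiment::colData(sim$otu))
    expect_setequal(unique(md$date), c("2024-07-16", "2024-10-15"))
    expect_true(all(md$replicate %in% 1:3))
})

test_that("infinitely wide niches reduce filtering to neutrality", {
    cfg <- simulationConfig(n_taxa = 50,
        samples_per_region = c(hPollut = 2, HABs = 2, SubmP = 2),
        depth = 1000, regime = "filtering_heterogeneous",
        niche_breadth = 1e6, seed = 8)
    sim <- simulateCommunities(cfg)
    meta <- sim$truth$metacommunity
    opt <- sim$truth$optima
    sig <- 1e6 * stats::sd(opt)
    for (E in unique(sim$truth$environment)) {
        w <- meta * exp(-(opt - E)^2 / (2 * sig^2))
        w <- w / sum(w)
        expect_lt(0.5 * sum(abs(w - meta)), 0.01)  # total variation
    }
})

test_that("dispersal limitation drives between-region turnover above within", {
    cfg <- simulationConfig(n_taxa = 64,
        samples_per_region = c(hPollut = 4, HABs = 4, SubmP = 4),
        depth = 20000, regime = "dispersal_limited", seed = 9)
    sim <- simulateCommunities(cfg)
    bc <- as.matrix(brayCurtis(sim$otu))
    reg <- sampleRegion(sim$otu)
    ut <- which(upper.tri(bc), arr.ind = TRUE)
    btw <- reg[ut[, 1]] != reg[ut[, 2]]
    v <- bc[upper.tri(bc)]
    expect_gt(mean(v[btw]), 0.85)
    expect_gt(mean(v[btw]), mean(v[!btw]) + 0.2)
})

test_that("planted network blocks respect the requested geometry", {
    sim <- injectNetworkStructure(n_blocks = 2, block_size = 5,
        within_rho = 0, n_samples = 10, depth = 5000, n_noise = 3,
        seed = 10)
    expect_equal(dim(otuCounts(sim$otu)), c(13L, 10L))
    expect_equal(unname(sim$blocks), c(rep(1L, 5), rep(2L, 5),
                                       rep(0L, 3)))
    expect_error(injectNetworkStructure(within_rho = 1.2), "within_rho")
})

test_that("environmental tables reproduce the regional reference profile", {
    cfg <- simulationConfig(n_taxa = 12, depth = 300, seed = 1)
    sim <- simulateCommunities(cfg)
    md <- as.data.frame(SummarizedExperiment::colData(sim$otu))
    env <- simulateEnvTable(md, seed = 2)
    expect_setequal(setdiff(colnames(env), "sample_id"),
                    unique(envReference()$variable))
    expect_true(all(vapply(env[-1], function(v) all(is.finite(v)),
                           logical(1))))
    # hPollut TN: sample mean of 18 draws within 3 reported SE of 3.2
    # (per-sample sd = se * sqrt(n), so the mean's se is the reported se)
    tn <- env$TN[md$region == "hPollut"]
    expect_lt(abs(mean(tn) - 3.2), 3 * 0.11)
    # concentrations stay non-negative
    expect_true(all(env$TP >= 0))
})

test_that("rank coupling injects a recoverable taxon-TN correlation", {
    cfg <- simulationConfig(n_taxa = 30,
        samples_per_region = c(hPollut = 4, HABs = 4, SubmP = 4),
        depth = 2000, seed = 11)
    sim <- simulateCommunities(cfg)
    md <- as.data.frame(SummarizedExperiment::colData(sim$otu))
    rl <- relAbundance(sim$otu)
    target <- rownames(rl)[which.max(rowMeans(rl))]
    env <- simulateEnvTable(md, seed = 3,
        coupling = list(variable = "TN", abundance = rl[target, ],
                        rho = 1))
    res <- envCorrelation(rl, env, top_n = 5)
    got <- res$table
    expect_equal(got$rho[got$taxon == target & got$variable == "TN"], 1)
})

test_that("regional TN effect sizes give the ANOVA letters power to separate", {
    cfg <- simulationConfig(n_taxa = 12, depth = 300, seed = 1)
    sim <- simulateCommunities(cfg)
    md <- as.data.frame(SummarizedExperiment::colData(sim$otu))
    hits <- vapply(1:200, function(i) {
        env <- simulateEnvTable(md, seed = 1000 + i)
        r <- anovaTukey(env$TN, factor(md$region,
            levels = c("hPollut", "HABs", "SubmP")))
        s <- r$summary
        s$letter[s$group == "hPollut"] != s$letter[s$group == "SubmP"]
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("simulations round-trip through the exchange formats", {
    cfg <- simulationConfig(n_taxa = 20,
        samples_per_region = c(hPollut = 2, HABs = 2, SubmP = 2),
        depth = 400, seed = 12)
    sim <- simulateCommunities(cfg)
    dir <- tempfile()
    writeSimulation(sim, dir)
    back <- readOtuTable(file.path(dir, "otu_table.tsv"))
    expect_identical(otuCounts(back), otuCounts(sim$otu))
    tr <- readPhyloTree(file.path(dir, "tree.nwk"), rownames(back))
    expect_setequal(tr$tip.label, rownames(back))
    truth <- utils::read.delim(file.path(dir, "truth.tsv"))
    expect_equal(nrow(truth), 20L)
})
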