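test_that("Shannon index matches closed forms and its uniform bound", {
    one <- matrix(5, 1, 1, dimnames = list("a", "s"))
    expect_equal(unname(shannonDiversity(one)), 0)
    unif <- matrix(rep(3, 10), 10, 1,
                   dimnames = list(paste0("t", 1:10), "s"))
    expect_equal(unname(shannonDiversity(unif)), log(10), tolerance = 1e-12)
    p <- matrix(c(0.5, 0.3, 0.2), 3, 1,
                dimnames = list(c("a", "b", "c"), "s"))
    expect_equal(unname(shannonDiversity(p)),
                 -(0.5 * log(0.5) + 0.3 * log(0.3) + 0.2 * log(0.2)),
                 tolerance = 1e-12)
    # H <= ln(richness), equality only at uniformity
    sim <- simulateCommunities(simulationConfig(n_taxa = 80,
        samples_per_region = c(hPollut = 2, HABs = 2, SubmP = 2),
        depth = 2000, seed = 11))
    H <- shannonDiversity(sim$otu)
    rich <- colSums(otuCounts(sim$otu) > 0)
    expect_true(all(H <= log(rich) + 1e-12))
    expect_true(all(H < log(rich)))  # simulated data are never uniform
})

test_that("Bray-Curtis matches hand evaluation and its bounds", {
    same <- matrix(c(1, 2, 3, 1, 2, 3), 3, 2,
                   dimnames = list(letters[1:3], c("s1", "s2")))
    expect_equal(max(abs(as.matrix(brayCurtis(same)))), 0)
    disj <- matrix(c(1, 1, 0, 0, 0, 0, 2, 2), 4, 2,
                   dimnames = list(letters[1:4], c("s1", "s2")))
    expect_equal(as.numeric(brayCurtis(disj)), 1)
    x <- matrix(c(0.5, 0.5, 0, 0.25, 0.25, 0.5), 3, 2,
                dimnames = list(letters[1:3], c("s1", "s2")))
    expect_equal(as.numeric(brayCurtis(x)), 0.5)
})

test_that("PCoA reproduces geometry: equidistant, collinear, Euclidean identity", {
    d3 <- matrix(1, 3, 3); diag(d3) <- 0
    dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
    fit <- pcoaOrdination(d3)
    pos <- fit$eig[fit$eig > 1e-10]
    expect_length(pos, 2)
    expect_equal(pos[1], pos[2], tolerance = 1e-9)

    dl <- as.matrix(dist(c(0, 1, 2)))
    dimnames(dl) <- list(paste0("s", 1:3), paste0("s", 1:3))
    fitl <- pcoaOrdination(dl)
    expect_equal(unname(fitl$relative_eig[1]), 1, tolerance = 1e-9)

    set.seed(4)
    pts <- matrix(rnorm(10), 5, 2)
    de <- dist(pts)
    fite <- pcoaOrdination(de)
    rec <- dist(fite$points[, 1:2])
    expect_lt(max(abs(as.numeric(de) - as.numeric(rec))), 1e-8)

    bad <- matrix(c(0, 1, 2, 0), 2, 2)
    expect_error(pcoaOrdination(bad), "symmetric")
})

test_that("PERMANOVA separates clusters, matches vegan, handles degeneracy", {
    # degenerate: all samples identical
    same <- matrix(1, 4, 6, dimnames = list(paste0("t", 1:4),
                                            paste0("s", 1:6)))
    d0 <- brayCurtis(sweep(same, 2, colSums(same), "/"))
    r0 <- permanovaTest(d0, rep(c("A", "B"), each = 3), n_perm = 99)
    expect_true(r0$degenerate)
    expect_equal(r0$p, 1)

    # two tight, well-separated clusters of 4
    set.seed(21)
    m <- cbind(matrix(abs(rnorm(40, 10, 0.1)), 10, 4),
               matrix(abs(rnorm(40, c(rep(0.01, 5), rep(20, 5)), 0.1)), 10, 4))
    dimnames(m) <- list(paste0("t", 1:10), paste0("s", 1:8))
    d <- brayCurtis(sweep(m, 2, colSums(m), "/"))
    grp <- rep(c("A", "B"), each = 4)
    r <- permanovaTest(d, grp, n_perm = 999, seed = 1)
    expect_lte(r$p, 0.03)

    # pseudo-F agrees with the vegan implementation
    ad <- vegan::adonis2(d ~ g, data = data.frame(g = grp),
                         permutations = 99)
    expect_equal(r$statistic, ad$F[1], tolerance = 1e-10)
})

test_that("Monte-Carlo PERMANOVA p agrees with exhaustive enumeration", {
    set.seed(31)
    m <- matrix(rlnorm(60), 10, 6,
                dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
    d <- brayCurtis(sweep(m, 2, colSums(m), "/"))
    grp <- rep(c("A", "B"), each = 3)
    pex <- permanovaTest(d, grp, exhaustive = TRUE)
    expect_equal(pex$n_perm, 20L)  # 6!/(3!3!) arrangements
    pmc <- permanovaTest(d, grp, n_perm = 4999, seed = 7)
    expect_lt(abs(pex$p - pmc$p), 0.02)
})

test_that("PERMANOVA permutation p is uniform under the null", {
    set.seed(55)
    ps <- vapply(1:200, function(i) {
        m <- matrix(rlnorm(96), 8, 12)
        dimnames(m) <- list(paste0("t", 1:8), paste0("s", 1:12))
        d <- brayCurtis(sweep(m, 2, colSums(m), "/"))
        permanovaTest(d, rep(c("A", "B", "C"), each = 4),
                      n_perm = 99, seed = i)$p
    }, numeric(1))
    # p-values sit on a discrete grid; jitter within grid cells for KS
    expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value),
              0.01)
})

test_that("per-taxon Kruskal-Wallis: constants, closed-form H, BH wiring", {
    grp <- factor(rep(c("A", "B", "C"), each = 6))
    m <- rbind(const = rep(2, 18),
               sep = c(1:6, 7:12, 13:18) / 18,
               noise = c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10, 12, 11,
                         14, 13, 16, 15, 18, 17) / 18)
    colnames(m) <- paste0("s", 1:18)
    res <- kruskalPerTaxon(m, grp)
    tab <- res$table
    expect_equal(tab$H[tab$taxon_id == "const"], 0)
    expect_equal(tab$p[tab$taxon_id == "const"], 1)
    # complete separation: H = 12/(N(N+1)) * sum n_g (Rbar_g-(N+1)/2)^2
    N <- 18
    Hmax <- 12 / (N * (N + 1)) *
        6 * ((3.5 - 9.5)^2 + (9.5 - 9.5)^2 + (15.5 - 9.5)^2)
    expect_equal(tab$H[tab$taxon_id == "sep"], Hmax, tolerance = 1e-10)
    # BH step-up on a known p vector flows through the same adjustment
    m2 <- m[c(2, 2, 2, 1), ]
    rownames(m2) <- paste0("t", 1:4)
    res2 <- kruskalPerTaxon(m2, grp)
    expect_true(all(res2$table$q >= res2$table$p))
    expect_equal(order(res2$table$q), order(res2$table$p))
})

test_that("ANOVA + Tukey letters: two-group identity, separation, degeneracy", {
    set.seed(12)
    v2 <- c(rnorm(6, 0), rnorm(6, 1.2))
    g2 <- factor(rep(c("A", "B"), each = 6))
    r2 <- anovaTukey(v2, g2)
    expect_equal(r2$tukey[["p adj"]][1], r2$p_value, tolerance = 1e-8)

    set.seed(13)
    v3 <- c(rnorm(6, 0), rnorm(6, 0), rnorm(6, 10))
    g3 <- factor(rep(c("g1", "g2", "g3"), each = 6))
    r3 <- anovaTukey(v3, g3)
    expect_equal(r3$summary$letter, c("a", "a", "b"))
    expect_lt(r3$p_value, 1e-6)

    rd <- anovaTukey(rep(c(1, 1, 2, 2), each = 3),
                     factor(rep(1:4, each = 3)))
    expect_true(rd$degenerate)
})

test_that("Tukey-letter type-I error under the null is near alpha", {
    set.seed(77)
    hits <- vapply(1:500, function(i) {
        v <- rnorm(18)
        r <- anovaTukey(v, factor(rep(c("A", "B", "C"), each = 6)))
        length(unique(r$summary$letter)) > 1
    }, logical(1))
    expect_gte(mean(hits), 0.03)
    expect_lte(mean(hits), 0.07)
})

test_that("environment correlations: perfect monotone, inverse, constants, null rate", {
    m <- matrix(c(1:8, 8:1, rep(2, 8)), 3, 8, byrow = TRUE,
                dimnames = list(c("up", "down", "flat"), paste0("s", 1:8)))
    env <- data.frame(TN = as.numeric(1:8), K = rep(5, 8),
                      row.names = paste0("s", 1:8))
    res <- envCorrelation(m, env, top_n = 3)
    tab <- res$table
    expect_equal(tab$rho[tab$taxon == "up" & tab$variable == "TN"], 1)
    expect_equal(tab$rho[tab$taxon == "down" & tab$variable == "TN"], -1)
    expect_true(is.na(tab$rho[tab$variable == "K"][1]))

    # null calibration: independent taxa vs a shuffled variable
    set.seed(42)
    nm <- matrix(rlnorm(50 * 12), 50, 12,
                 dimnames = list(paste0("t", 1:50), paste0("s", 1:12)))
    nenv <- data.frame(TN = sample(rnorm(12)),
                       row.names = paste0("s", 1:12))
    rnull <- envCorrelation(nm, nenv, top_n = 50)
    frac <- rnull$by_variable$fraction_significant[1]
    expect_gte(frac, 0)
    expect_lte(frac, 0.1)
})
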