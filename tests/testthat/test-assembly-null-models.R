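test_that("betaMNTD matches hand values and the double-loop oracle", {
    tr <- fourTipTree()
    D <- patristicDistances(tr)
    expect_true(isSymmetric(D))
    expect_equal(unname(D["A", "B"]), 2)
    expect_equal(unname(D["C", "D"]), 3)
    expect_equal(unname(D["A", "C"]), 6)

    # identical single-taxon communities
    m1 <- matrix(c(3, 3), 1, 2, dimnames = list("A", c("s1", "s2")))
    expect_equal(unname(betaMNTD(m1, D = D["A", "A", drop = FALSE])[1, 2]), 0)

    # identical multi-taxon communities
    m2 <- matrix(c(2, 1, 4, 2, 1, 4), 3, 2,
                 dimnames = list(c("A", "B", "C"), c("s1", "s2")))
    expect_equal(unname(betaMNTD(m2, tr)[1, 2]), 0)

    # {A,B} vs {C,D}: every nearest cross-taxon distance is 6
    m3 <- matrix(c(6, 4, 0, 0, 0, 0, 7, 3), 4, 2,
                 dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
    got <- betaMNTD(m3, tr)[1, 2]
    expect_equal(unname(got), 6, tolerance = 1e-12)
    expect_equal(unname(got), unname(bmntdOracle(m3[, 1], m3[, 2], D)),
                 tolerance = 1e-12)

    # random table vs oracle, weighted and unweighted
    set.seed(20)
    trr <- simulateTree(16, seed = 2)
    Dr <- patristicDistances(trr)
    mr <- matrix(rpois(16 * 4, 3), 16, 4,
                 dimnames = list(trr$tip.label, paste0("s", 1:4)))
    mr[mr == 0 & row(mr) %% 2 == 0] <- 1   # keep columns non-empty
    for (w in c(TRUE, FALSE)) {
        bm <- betaMNTD(mr, trr, weighted = w)
        for (k in 1:3) for (l in (k + 1):4)
            expect_equal(unname(bm[k, l]),
                unname(bmntdOracle(mr[, k], mr[, l], Dr, weighted = w)),
                tolerance = 1e-12)
    }
    expect_error(betaMNTD(rbind(mr, X1 = 1), trr), "X1")
})

test_that("betaMNTD agrees with picante's comdistnt", {
    skip_if_not_installed("picante")
    set.seed(21)
    tr <- simulateTree(20, seed = 3)
    m <- matrix(rpois(20 * 5, 2), 20, 5,
                dimnames = list(tr$tip.label, paste0("s", 1:5)))
    m[1, ] <- pmax(m[1, ], 1)
    bm <- betaMNTD(m, tr, weighted = TRUE)
    ref <- as.matrix(picante::comdistnt(t(m), stats::cophenetic(tr),
                                        abundance.weighted = TRUE))
    expect_equal(unname(bm), unname(ref[colnames(m), colnames(m)]),
                 tolerance = 1e-10)
})

test_that("betaNTI is invariant to uniform branch-length scaling", {
    tr <- simulateTree(24, seed = 4)
    set.seed(22)
    m <- matrix(rpois(24 * 6, 2), 24, 6,
                dimnames = list(tr$tip.label, paste0("s", 1:6)))
    m[1, ] <- pmax(m[1, ], 1)
    b1 <- betaNTI(m, tr, n_null = 99, seed = 9)
    tr3 <- tr
    tr3$edge.length <- tr3$edge.length * 3
    b3 <- betaNTI(m, tr3, n_null = 99, seed = 9)
    expect_equal(b1$bnti, b3$bnti, tolerance = 1e-9)
    expect_equal(b3$bmntd, 3 * b1$bmntd, tolerance = 1e-9)
})

test_that("a star phylogeny makes the betaNTI null degenerate", {
    star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
    m <- matrix(c(1, 2, 0, 0, 3,
                  0, 0, 2, 1, 4), 5, 2,
                dimnames = list(LETTERS[1:5], c("s1", "s2")))
    b <- betaNTI(m, star, n_null = 99, seed = 1)
    expect_true(b$degenerate[1, 2])
    expect_true(is.na(b$bnti[1, 2]))
})

test_that("RCbray hits its boundaries and stays in [-1, 1]", {
    set.seed(23)
    # pool of 12 taxa; two identical samples (obs BC = 0) -> RC = -1;
    # two disjoint samples with overlapping-by-construction nulls -> +1
    pool <- matrix(rpois(12 * 4, 4) + 1, 12, 4)
    ident <- cbind(a = pool[, 1], b = pool[, 1])
    disj <- cbind(c = c(rep(5, 6), rep(0, 6)),
                  d = c(rep(0, 6), rep(5, 6)))
    m <- cbind(ident, disj, e = pool[, 2], f = pool[, 3])
    rownames(m) <- paste0("t", 1:12)
    rc <- rcBray(m, n_null = 199, seed = 2)
    expect_equal(unname(rc["a", "b"]), -1)
    expect_equal(unname(rc["c", "d"]), 1)
    expect_true(all(rc >= -1 & rc <= 1))
})

test_that("RCbray is centred when observations come from the null's own pool model", {
    set.seed(24)
    pool_ab <- rlnorm(64, 0, 2)
    pool_occ <- pmin(12, 1 + rpois(64, 6))
    gen <- function(i) {
        sp <- sample.int(64, 40, prob = pool_occ)
        v <- rep(1, 40) + stats::rmultinom(1, 20000 - 40,
                                           prob = pool_ab[sp])[, 1]
        x <- numeric(64)
        x[sp] <- v
        x
    }
    m <- vapply(1:12, gen, numeric(64))
    dimnames(m) <- list(sprintf("t%02d", 1:64), sprintf("s%02d", 1:12))
    rc <- rcBray(m, n_null = 199, seed = 8)
    rv <- rc[upper.tri(rc)]
    expect_lt(abs(mean(rv)), 0.3)
    expect_gte(mean(abs(rv) <= 0.95), 0.85)
})

test_that("process partition applies the five threshold rules exactly", {
    ids <- paste0("s", 1:5)
    bnti <- matrix(0, 5, 5, dimnames = list(ids, ids))
    rc <- matrix(0, 5, 5, dimnames = list(ids, ids))
    setp <- function(i, j, b, r) {
        bnti[i, j] <<- bnti[j, i] <<- b
        rc[i, j] <<- rc[j, i] <<- r
    }
    # 10 pairs spanning all five rules
    setp(1, 2, 3.0, 0.0)     # heterogeneous selection
    setp(1, 3, -2.5, 0.99)   # homogeneous selection (betaNTI wins)
    setp(1, 4, 0.0, 0.99)    # dispersal limitation (the printed rule)
    setp(1, 5, 1.0, -0.99)   # homogenizing dispersal
    setp(2, 3, 0.5, 0.2)     # drift
    setp(2, 4, 2.01, -0.99)  # heterogeneous selection
    setp(2, 5, -3.0, 0.0)    # homogeneous selection
    setp(3, 4, 1.99, 0.951)  # dispersal limitation
    setp(3, 5, 0.0, -0.951)  # homogenizing dispersal
    setp(4, 5, -1.0, 0.95)   # drift (0.95 is not > 0.95)
    pp <- partitionProcesses(bnti, rc)
    tab <- table(pp$pairs$process)
    expect_equal(as.vector(tab[c("heterogeneous_selection",
        "homogeneous_selection", "dispersal_limitation",
        "homogenizing_dispersal", "drift")]), rep(2L, 5))
    fr <- pp$fractions[pp$fractions$scope == "all", ]
    expect_equal(fr$deterministic, 0.4)
    expect_equal(fr$stochastic, 0.6)
    procs <- c("heterogeneous_selection", "homogeneous_selection",
               "dispersal_limitation", "homogenizing_dispersal", "drift")
    expect_equal(sum(unlist(fr[procs])), 1, tolerance = 1e-9)
    # the printed rule in isolation
    one <- pp$pairs[pp$pairs$sample1 == "s1" & pp$pairs$sample2 == "s4", ]
    expect_equal(as.character(one$process), "dispersal_limitation")
})

test_that("partition groups pairs into within/between scopes with closing fractions", {
    ids <- paste0("s", 1:6)
    bnti <- matrix(3, 6, 6, dimnames = list(ids, ids))
    diag(bnti) <- 0
    rc <- matrix(0, 6, 6, dimnames = list(ids, ids))
    grp <- factor(rep(c("A", "B"), each = 3))
    pp <- partitionProcesses(bnti, rc, grp)
    expect_equal(sort(unique(pp$pairs$scope)),
                 c("between_regions", "within_A", "within_B"))
    fr <- pp$fractions[pp$fractions$scope == "all", ]
    expect_equal(fr$heterogeneous_selection, 1)
    expect_equal(fr$deterministic, 1)
    expect_error(partitionProcesses(bnti[1:5, 1:5], rc, grp[1:5]),
                 "align")
})

test_that("without a phylogeny the partition never infers selection", {
    ids <- paste0("s", 1:4)
    bnti <- matrix(NA_real_, 4, 4, dimnames = list(ids, ids))
    rc <- matrix(c(0, 0.99, 0.2, -0.99,
                   0.99, 0, 0.5, 0.3,
                   0.2, 0.5, 0, 0.96,
                   -0.99, 0.3, 0.96, 0), 4, 4,
                 dimnames = list(ids, ids))
    pp <- partitionProcesses(bnti, rc)
    expect_false(any(grepl("selection", pp$pairs$process)))
    # pairs (1,2) and (3,4) exceed 0.95; only (1,4) falls below -0.95
    expect_equal(sum(pp$pairs$process == "dispersal_limitation"), 2L)
    expect_equal(sum(pp$pairs$process == "homogenizing_dispersal"), 1L)
    expect_equal(sum(pp$pairs$process == "drift"), 3L)
})

test_that("assemblyAnalysis wires the stages together, with and without tree", {
    sim <- simulateCommunities(simulationConfig(n_taxa = 32,
        samples_per_region = c(hPollut = 3, HABs = 3, SubmP = 3),
        depth = 2000, seed = 6))
    asm <- assemblyAnalysis(sim$otu, n_null = 99, seed = 1)
    expect_true(all(abs(rowSums(as.matrix(
        asm$partition$fractions[, c("heterogeneous_selection",
            "homogeneous_selection", "dispersal_limitation",
            "homogenizing_dispersal", "drift")])) - 1) < 1e-9))

    bare <- OtuExperiment(otuCounts(sim$otu),
        as.data.frame(SummarizedExperiment::colData(sim$otu)))
    expect_message(
        asm2 <- assemblyAnalysis(bare, n_null = 99, seed = 1),
        "betaNTI skipped")
    expect_false(any(grepl("selection", asm2$partition$pairs$process)))
})
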