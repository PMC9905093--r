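test_that("profile simulation is reproducible and respects marker folds", {
    p1 <- simulateProfiles(100, 3, n_markers_per_type = 5, marker_fold = 4,
                           seed = 42)
    p2 <- simulateProfiles(100, 3, n_markers_per_type = 5, marker_fold = 4,
                           seed = 42)
    expect_identical(p1@means, p2@means)

    ## marker mean = fold x base mean, in the marker's own type only
    for (tp in colnames(p1@means)) {
        mk <- p1@markers[[tp]]
        others <- setdiff(colnames(p1@means), tp)
        expect_equal(p1@means[mk, tp], p1@means[mk, others[1]] * 4)
        expect_equal(p1@means[mk, others[1]], p1@means[mk, others[2]])
    }

    ## marker_fold = 1 leaves all types identical
    flat <- simulateProfiles(50, 2, n_markers_per_type = 5, marker_fold = 1,
                             seed = 1)
    expect_equal(flat@means[, 1], flat@means[, 2])

    expect_error(simulateProfiles(10, 3, n_markers_per_type = 5),
                 "exceeds")
})

test_that("scRNA generator is seed-reproducible and validates fractions", {
    prof <- simulateProfiles(60, 2, n_markers_per_type = 4, seed = 3)
    a <- simulateScrna(prof, c(healthy = 2, tumor = 2),
                       cells_per_sample = 30, seed = 9)
    b <- simulateScrna(prof, c(healthy = 2, tumor = 2),
                       cells_per_sample = 30, seed = 9)
    expect_identical(as.matrix(assay(a$dataset, "counts")),
                     as.matrix(assay(b$dataset, "counts")))
    expect_identical(as.data.frame(colData(a$dataset)),
                     as.data.frame(colData(b$dataset)))

    expect_error(simulateScrna(prof, c(bogus = 2), seed = 1), "fraction")
    expect_error(simulateScrna(prof, c(healthy = 2, tumor = 2),
                               cells_per_sample = 10,
                               planted_effects = data.frame(
                                   gene = "gene0001", cell_type = "type1",
                                   fraction = "nope", log2fc = 1)),
                 "fraction")
})

test_that("NB counts are overdispersed for phi > 0 and Poisson at phi = 0", {
    prof_od <- simulateProfiles(50, 1, n_markers_per_type = 0,
                                marker_fold = 1, base_mean = 5,
                                dispersion = 0.5, seed = 5)
    prof_po <- simulateProfiles(50, 1, n_markers_per_type = 0,
                                marker_fold = 1, base_mean = 5,
                                dispersion = 0, seed = 5)
    mk <- function(prof) {
        sim <- simulateScrna(prof, c(tumor = 1), cells_per_sample = 3000,
                             lib_meanlog = log(500), lib_sdlog = 0,
                             sample_effect_sd = 0, seed = 6)
        as.matrix(assay(sim$dataset, "counts"))
    }
    c_od <- mk(prof_od); c_po <- mk(prof_po)
    m_od <- rowMeans(c_od); v_od <- apply(c_od, 1, var)
    m_po <- rowMeans(c_po); v_po <- apply(c_po, 1, var)
    hi <- m_od > 2
    expect_true(all(v_od[hi] > m_od[hi] * 1.5))
    ## Poisson: variance/mean ratio near 1 within sampling error
    expect_lt(median(abs(v_po[m_po > 2] / m_po[m_po > 2] - 1)), 0.15)
})

test_that("planted fraction effects are recovered at the generator scale", {
    prof <- simulateProfiles(100, 1, n_markers_per_type = 0,
                             marker_fold = 1, base_mean = 2,
                             dispersion = 0.1, seed = 8)
    planted <- data.frame(gene = c("gene0005", "gene0010"),
                          cell_type = "type1", fraction = "tumor",
                          log2fc = 1)
    sim <- simulateScrna(prof, c(healthy = 1, tumor = 1),
                         cells_per_sample = 2000,
                         lib_meanlog = log(1500), lib_sdlog = 0.2,
                         planted_effects = planted, sample_effect_sd = 0,
                         seed = 10)
    cd <- colData(sim$dataset)
    norm <- assay(normalizeDepth(sim$dataset), "normalized")
    mt <- Matrix::rowMeans(norm[, cd$fraction == "tumor"])
    mh <- Matrix::rowMeans(norm[, cd$fraction == "healthy"])
    ratio <- as.numeric(mt[planted$gene] / mh[planted$gene])
    ## planted log2FC = 1: the empirical ratio approaches 2 (the planted gene
    ## slightly inflates the tumor library total, deflating normalized means)
    expect_true(all(abs(ratio / 2 - 1) < 0.10))

    ## null: essentially no gene shows |log2FC| > 0.5 without planted effects
    sim0 <- simulateScrna(prof, c(healthy = 1, tumor = 1),
                          cells_per_sample = 2000,
                          lib_meanlog = log(1500), lib_sdlog = 0.2,
                          sample_effect_sd = 0, seed = 11)
    cd0 <- colData(sim0$dataset)
    n0 <- assay(normalizeDepth(sim0$dataset), "normalized")
    l2 <- log2(Matrix::rowMeans(n0[, cd0$fraction == "tumor"]) /
               Matrix::rowMeans(n0[, cd0$fraction == "healthy"]))
    expect_lte(mean(abs(l2) > 0.5), 0.01)
})

test_that("puck admixture weights are a valid mixture and truth-consistent", {
    prof <- simulateProfiles(80, 2, n_markers_per_type = 6, marker_fold = 4,
                             seed = 12)
    pk <- simulatePuck(prof, width = 300, height = 300, seed = 13)
    W <- pk$truth@admixture_weights
    expect_equal(unname(rowSums(W)), rep(1, nrow(W)), tolerance = 1e-12)
    expect_true(all(W >= 0 & W <= 1))

    ## identical seeds give identical pucks
    pk2 <- simulatePuck(prof, width = 300, height = 300, seed = 13)
    expect_identical(as.matrix(assay(pk$dataset, "counts")),
                     as.matrix(assay(pk2$dataset, "counts")))

    ## self_weight = 1: every bead is its pure own-type profile (one-hot)
    pure <- simulatePuck(prof, width = 300, height = 300, self_weight = 1,
                         seed = 13)
    Wp <- pure$truth@admixture_weights
    expect_true(all(apply(Wp, 1, max) == 1))
    expect_identical(colnames(Wp)[apply(Wp, 1, which.max)],
                     colData(pure$dataset)$cell_type)

    ## beads farther than the kernel support (3 bandwidths) from any
    ## other-type bead are one-hot
    co <- beadCoords(pk$dataset)
    tp <- colData(pk$dataset)$cell_type
    D <- as.matrix(dist(co))
    iso <- vapply(seq_len(nrow(co)), function(i)
        min(D[i, tp != tp[i]]) > 3 * 30, logical(1))
    if (any(iso)) expect_true(all(apply(W[iso, , drop = FALSE], 1, max) == 1))
})

test_that("bead expression matches the truth-weighted expected mixture", {
    prof <- simulateProfiles(60, 3, n_markers_per_type = 5, marker_fold = 6,
                             base_mean = 2, dispersion = 0.05, seed = 14)
    doms <- list(
        list(name = "left", region = c(0, 200, 0, 400),
             composition = c(type1 = 0.5, type2 = 0.5)),
        list(name = "right", region = c(200, 400, 0, 400),
             composition = c(type1 = 0.5, type3 = 0.5)))
    pk <- simulatePuck(prof, domains = doms, width = 400, height = 400,
                       umi_per_bead = 2000, lib_sdlog = 0, seed = 15,
                       doublet_certain_rate = 0, reject_rate = 0)
    W <- pk$truth@admixture_weights
    counts <- as.matrix(assay(pk$dataset, "counts"))
    expected <- prof@means %*% t(W)
    expected <- sweep(expected, 2, colSums(expected), "/") * 2000
    ## pseudo-bulk of target type per domain matches the expected mixture
    cd <- colData(pk$dataset)
    for (d in c("left", "right")) {
        sel <- cd$domain == d & cd$cell_type == "type1"
        obs <- rowSums(counts[, sel])
        exp_d <- rowSums(expected[, sel])
        hi <- exp_d >= 10
        expect_lt(median(abs(obs[hi] / exp_d[hi] - 1)), 0.1)
    }
    ## type1's profile is identical in both domains, so differences in its
    ## pseudo-bulk between domains are attributable to admixture: the type2
    ## markers lean left, type3 markers lean right
    selL <- cd$domain == "left" & cd$cell_type == "type1"
    selR <- cd$domain == "right" & cd$cell_type == "type1"
    pbL <- rowSums(counts[, selL]) / sum(counts[, selL])
    pbR <- rowSums(counts[, selR]) / sum(counts[, selR])
    expect_true(mean(pbL[prof@markers$type2] > pbR[prof@markers$type2]) >
                0.8)
    expect_true(mean(pbR[prof@markers$type3] > pbL[prof@markers$type3]) >
                0.8)
})

test_that("puck generator rejects empty or non-covering domains", {
    prof <- simulateProfiles(30, 2, n_markers_per_type = 2, seed = 1)
    doms <- list(list(name = "left", region = c(0, 100, 0, 200),
                      composition = c(type1 = 1)),
                 list(name = "gap", region = c(500, 600, 0, 200),
                      composition = c(type2 = 1)))
    expect_error(simulatePuck(prof, domains = doms, width = 200,
                              height = 200, seed = 2), "empty domain|cover")
})

test_that("bulk cohorts separate by composition and are seed-stable", {
    prof <- simulateProfiles(80, 2, n_markers_per_type = 8, marker_fold = 8,
                             seed = 20)
    ## noiseless disjoint compositions: malignant-marker means separate
    ## tumor from normal perfectly
    b <- simulateBulkCohort(prof, 8, 8, c(type1 = 1), c(type2 = 1),
                            noise_sd = 0, seed = 21)
    sc <- colMeans(b$expr[prof@markers$type1, ])
    expect_gt(min(sc[b$labels == "tumor"]), max(sc[b$labels == "normal"]))

    b2 <- simulateBulkCohort(prof, 8, 8, c(type1 = 1), c(type2 = 1),
                             noise_sd = 0, seed = 21)
    expect_identical(b$expr, b2$expr)

    expect_error(simulateBulkCohort(prof, 4, 4, c(type1 = 0.6),
                                    c(type2 = 1), seed = 1), "sum to 1")

    ## identical compositions: labels carry no signal, AUC centers on 0.5
    aucs <- vapply(1:20, function(s) {
        bi <- simulateBulkCohort(prof, 10, 10, c(type1 = 0.5, type2 = 0.5),
                                 c(type1 = 0.5, type2 = 0.5),
                                 noise_sd = 0.3, seed = s)
        evaluateBulkAUC(bi$expr, bi$labels, prof@markers$type1)$auc
    }, numeric(1))
    expect_lt(abs(mean(aucs) - 0.5), 0.1)
})
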