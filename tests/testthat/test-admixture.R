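test_that("pseudobulk sums member columns exactly", {
    counts <- matrix(c(1, 2, 3, 4, 10, 20), 2, 3,
                     dimnames = list(c("g1", "g2"), paste0("b", 1:3)))
    ds <- SpatialDataset(counts, x = 1:3, y = 1:3,
                         cell_type = c("T", "T", "other"))
    pb <- pseudobulk(ds, c("u1", "u1", "u1"), "T")
    expect_equal(unname(pseudobulkCounts(pb)[, 1]), c(4, 6))  # [1,2]+[3,4]
    expect_equal(unname(pb@n_members), 2L)

    ## reject beads are excluded; empty units warn
    ds2 <- SpatialDataset(counts, x = 1:3, y = 1:3,
                          cell_type = rep("T", 3),
                          annotation_class = c("singlet", "reject",
                                               "singlet"))
    expect_warning(pb2 <- pseudobulk(ds2, c("u1", "u1", "u2"), "T"),
                   NA)
    expect_equal(unname(pseudobulkCounts(pb2)[, "u1"]), c(1, 2))
    expect_warning(pseudobulk(ds2, c("u1", "u1", NA), "T"), NA)
    ds3 <- SpatialDataset(counts, x = 1:3, y = 1:3,
                          cell_type = c("T", "T", "other"))
    expect_warning(pseudobulk(ds3, c("u1", "u1", "u2"), "T"), "u2")
})

test_that("admixture fit recovers simplex weights", {
    set.seed(80)
    P <- matrix(rlnorm(300 * 3), 300, 3,
                dimnames = list(NULL, c("target", "B", "C")))
    Pn <- sweep(P, 2, colSums(P), "/")

    ## identity mixture
    fit <- estimateAdmixture(Pn[, "target"], P, "target")
    w <- admixtureWeights(fit)
    expect_equal(unname(w["target"]), 1, tolerance = 1e-8)
    expect_lt(max(w[c("B", "C")]), 1e-8)

    ## noiseless 0.7 / 0.3 mixture, cross-checked against the grid-search
    ## oracle over the simplex
    y <- 0.7 * Pn[, "target"] + 0.3 * Pn[, "B"]
    fit2 <- estimateAdmixture(y, P, "target")
    w2 <- admixtureWeights(fit2)
    expect_equal(unname(w2[c("target", "B", "C")]), c(0.7, 0.3, 0),
                 tolerance = 1e-6)
    worc <- oracle_simplex_weights(y, Pn)
    expect_equal(unname(w2[c("target", "B", "C")]), worc,
                 tolerance = 1e-4)

    ## duplicate contaminant columns trigger the ill-conditioning fallback
    Pd <- cbind(P, B2 = P[, "B"])
    expect_warning(fd <- estimateAdmixture(y, Pd, "target"),
                   "ill-conditioned")
    expect_true(fd@ridged)
})

test_that("profile correction subtracts contamination, floored at zero", {
    set.seed(81)
    P <- matrix(rlnorm(200 * 2, log(5)), 200, 2,
                dimnames = list(sprintf("g%03d", 1:200),
                                c("target", "B")))
    Pn <- sweep(P, 2, colSums(P), "/")
    ## zero contamination: identity
    obs <- round(5000 * Pn[, "target"])
    fit <- estimateAdmixture(Pn[, "target"], P, "target")
    expect_equal(unname(correctProfile(obs, fit)), unname(obs))

    ## floor at zero when predicted contamination exceeds the observation:
    ## the contaminant concentrates half its mass on gene 1, so the bead's
    ## observed 5 counts there are swamped by the predicted ~7
    Pc <- Pn
    Pc[, "B"] <- c(0.5, rep(0.5 / 199, 199))
    fit2 <- methods::new("AdmixtureFit", target_type = "target",
                         weights = c(target = 0.3, B = 0.7),
                         references = Pc, residual_norm = 0,
                         condition_number = 1, ridged = FALSE)
    tiny <- c(5, rep(0.075, 199))  # depth 19.9 -> predicted contamination ~7
    expect_equal(unname(correctProfile(tiny, fit2)[1]), 0)
    expect_true(all(correctProfile(tiny, fit2) >= 0))

    ## noiseless mixture: corrected counts match the true target component
    ## within 5% on well-covered genes
    depth <- 2e5
    y <- depth * (0.7 * Pn[, "target"] + 0.3 * Pn[, "B"])
    fit3 <- estimateAdmixture(y, P, "target")
    corr <- correctProfile(round(y), fit3)
    truth <- depth * 0.7 * Pn[, "target"]
    hi <- truth >= 10
    expect_lt(max(abs(corr[hi] / truth[hi] - 1)), 0.05)
})

test_that("context DE demands replicates and names the tiling fallback", {
    counts <- matrix(rpois(40, 50), 10, 4)
    rownames(counts) <- paste0("g", 1:10)
    expect_error(contextDE(counts, c("a", "a", "a", "b")), "tilePuck")
    expect_error(contextDE(counts, c("a", "a", "b", "c")), "2 levels")
})

test_that("NB pseudo-bulk test is calibrated and finds planted effects", {
    set.seed(82)
    ## permutation null: identical generating process on both sides
    ps <- unlist(lapply(1:12, function(r) {
        mu <- rlnorm(150, log(40), 1)
        counts <- sapply(1:8, function(j) rnbinom(150, mu = mu, size = 20))
        rownames(counts) <- paste0("g", 1:150)
        contextDE(counts, rep(c("a", "b"), each = 4))$p
    }))
    expect_lt(mean(ps < 0.05), 0.08)
    expect_gt(mean(ps < 0.05), 0.02)
    ## super-uniform or uniform: the empirical CDF never sits far above
    ## the diagonal
    for (a in c(0.01, 0.1, 0.25)) expect_lt(mean(ps <= a), a + 0.03)

    ## planted 4-fold effects on 20 genes are recovered
    set.seed(83)
    mu <- rlnorm(200, log(40), 1)
    de_idx <- 1:20
    cA <- sapply(1:4, function(j) rnbinom(200, mu = mu, size = 20))
    muB <- mu; muB[de_idx] <- muB[de_idx] * 4
    cB <- sapply(1:4, function(j) rnbinom(200, mu = muB, size = 20))
    counts <- cbind(cA, cB); rownames(counts) <- paste0("g", 1:200)
    res <- contextDE(counts, rep(c("a", "b"), each = 4))
    expect_gte(mean(res$q[de_idx] < 0.05), 0.8)
    expect_true(all(res$q >= res$p))
    ## q is monotone non-decreasing in BH rank order
    o <- order(res$p)
    expect_true(all(diff(cummax(res$q[o])) >= 0))
})

test_that("log2 fold changes agree with an independent DE engine", {
    skip_if_not_installed("edgeR")
    set.seed(84)
    mu <- rlnorm(300, log(60), 1)
    muB <- mu * 2^rnorm(300, 0, 0.5)
    counts <- cbind(sapply(1:4, function(j) rnbinom(300, mu = mu,
                                                    size = 10)),
                    sapply(1:4, function(j) rnbinom(300, mu = muB,
                                                    size = 10)))
    rownames(counts) <- paste0("g", 1:300)
    keep <- rowSums(counts) > 0
    ours <- contextDE(counts[keep, ], rep(c("a", "b"), each = 4))
    y <- edgeR::DGEList(counts = counts[keep, ],
                        group = rep(c("a", "b"), each = 4))
    y <- edgeR::estimateDisp(y, model.matrix(~rep(c(0, 1), each = 4)))
    et <- edgeR::exactTest(y)
    expect_gt(cor(ours$log2fc, et$table$logFC), 0.95)
})

test_that("admixture correction removes the neighbor-composition confound", {
    cp <- confound_puck(seed = 85)
    raw <- target_tile_profiles(cp$pk, cp$prof, correct = FALSE)
    cor_ <- target_tile_profiles(cp$pk, cp$prof, correct = TRUE)
    de_raw <- contextDE(raw$counts, raw$ctx)
    de_cor <- contextDE(cor_$counts, cor_$ctx)
    nb_markers <- c(cp$prof@markers$type2, cp$prof@markers$type3)
    hit_raw <- mean(de_raw$q[de_raw$gene %in% nb_markers] < 0.05)
    hit_cor <- mean(de_cor$q[de_cor$gene %in% nb_markers] < 0.05)
    expect_gt(hit_raw, 0.2)
    expect_lte(hit_cor, 0.1)
    ## fold changes of the confounded markers deflate after correction
    mr <- abs(de_raw$log2fc[de_raw$gene %in% nb_markers])
    mc <- abs(de_cor$log2fc[de_cor$gene %in% nb_markers])
    expect_lt(median(mc), median(mr))
})

test_that("fraction DE enforces the 10-cell rule and recovers effects", {
    ## planted genes are a small share of the transcriptome so the planted
    ## mass does not distort total-count normalization of the other genes
    prof <- simulateProfiles(300, 2, n_markers_per_type = 5,
                             marker_fold = 3, base_mean = 2,
                             dispersion = 0.05, seed = 86)
    planted <- data.frame(gene = sprintf("gene%04d", 50:59),
                          cell_type = "type1", fraction = "tumor",
                          log2fc = 1.5)
    sim <- simulateScrna(prof, c(healthy = 3, tumor = 3),
                         cells_per_sample = 120,
                         planted_effects = planted, sample_effect_sd = 0.1,
                         seed = 87)
    res <- fractionDE(sim$dataset, "type1", "healthy", "tumor")
    expect_gte(mean(res$q[res$gene %in% planted$gene] < 0.05), 0.8)
    expect_lte(mean(res$q[!res$gene %in% planted$gene] < 0.05), 0.1)

    ## a sample with fewer than 10 cells of the type is excluded (9 < 10,
    ## 10 kept), and losing too many samples is an error naming them
    cd <- colData(sim$dataset)
    keep <- rep(TRUE, ncol(sim$dataset))
    h1 <- cd$sample_id == "healthy_s01" & cd$cell_type == "type1"
    keep[which(h1)[-seq_len(9)]] <- FALSE   # leave exactly 9 cells
    ds9 <- sim$dataset[, keep]
    expect_message(fractionDE(ds9, "type1", "healthy", "tumor"),
                   "healthy_s01")
    h23 <- colData(ds9)$sample_id %in% c("healthy_s02", "healthy_s03") &
        colData(ds9)$cell_type == "type1"
    ds_few <- ds9[, !h23]
    expect_error(suppressMessages(
        fractionDE(ds_few, "type1", "healthy", "tumor")), ">= 2")
})
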