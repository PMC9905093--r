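## Simulation fixtures shared between the module suites and the acceptance
## suite.

## rook-adjacency grid as a plain sparse weight matrix
rook_grid <- function(nr, nc) {
    n <- nr * nc
    id <- function(r, c) (c - 1) * nr + r
    i <- integer(0); j <- integer(0)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
        if (r < nr) { i <- c(i, id(r, c)); j <- c(j, id(r + 1, c)) }
        if (c < nc) { i <- c(i, id(r, c)); j <- c(j, id(r, c + 1)) }
    }
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(n, n))
    methods::as(A, "CsparseMatrix")
}

## two-domain puck in which the target type (type1) has identical expression
## everywhere but the neighboring composition differs between contexts:
## a pure admixture confound
confound_puck <- function(seed, n_genes = 150, planted = NULL) {
    prof <- simulateProfiles(n_genes, 3, n_markers_per_type = 10,
                             marker_fold = 4, base_mean = 2,
                             dispersion = 0.05, seed = 1000 + seed)
    doms <- list(
        list(name = "ctxA", region = c(0, 180, 0, 360),
             composition = c(type1 = 0.5, type2 = 0.5)),
        list(name = "ctxB", region = c(180, 360, 0, 360),
             composition = c(type1 = 0.5, type3 = 0.5)))
    pk <- simulatePuck(prof, domains = doms, width = 360, height = 360,
                       self_weight = 0.7, planted_context_de = planted,
                       umi_per_bead = 800, reject_rate = 0, seed = seed)
    list(prof = prof, pk = pk)
}

## per-(context x tile) pseudo-bulk of the target type, optionally passed
## through the admixture correction; tiles are y-axis strata within each
## domain so every replicate is spatially disjoint
target_tile_profiles <- function(pk, prof, correct = TRUE, ny = 4) {
    ds <- pk$dataset
    yb <- cut(SummarizedExperiment::colData(ds)$y, breaks = ny,
              labels = FALSE)
    tiles <- paste(SummarizedExperiment::colData(ds)$domain, yb)
    pb <- pseudobulk(ds, tiles, "type1")
    counts <- pseudobulkCounts(pb)
    if (correct) {
        for (j in seq_len(ncol(counts))) {
            fit <- estimateAdmixture(counts[, j], prof@means, "type1")
            counts[, j] <- correctProfile(counts[, j], fit)
        }
    }
    ctx <- ifelse(grepl("ctxA", colnames(counts)), "ctxA", "ctxB")
    list(counts = counts, ctx = ctx)
}
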