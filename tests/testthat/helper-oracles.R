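## Independent brute-force oracles and small fixture builders shared across
## the suite. The oracles deliberately avoid the package's own code paths.

## Exact two-sided rank-sum p by enumerating every assignment of the pooled
## values to the two groups, scoring each by the Mann-Whitney U computed by
## direct pair counting (ties count one half).
oracle_ranksum_p <- function(x, y) {
    pool <- c(x, y)
    n1 <- length(x); n <- length(pool)
    u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    mu <- n1 * (n - n1) / 2
    obs <- abs(u_of(x, y) - mu)
    combs <- utils::combn(n, n1)
    devs <- apply(combs, 2, function(idx)
        abs(u_of(pool[idx], pool[-idx]) - mu))
    mean(devs >= obs - 1e-12)
}

## AUC by direct enumeration of all positive-negative pairs.
oracle_auc <- function(scores, positive_mask) {
    pos <- scores[positive_mask]; neg <- scores[!positive_mask]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(pairs)
}

## Moran's I by direct evaluation of the formula, one term at a time.
oracle_moran <- function(values, W, row_standardize = TRUE) {
    W <- as.matrix(W)
    n <- length(values)
    if (row_standardize) {
        rs <- rowSums(W)
        W <- sweep(W, 1, ifelse(rs > 0, rs, 1), "/")
        W[rowSums(W) == 0, ] <- 0
    }
    z <- values - mean(values)
    num <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
        num <- num + W[i, j] * z[i] * z[j]
    (n / sum(W)) * num / sum(z^2)
}

## Spatial LR score by row-wise direct evaluation of the double sum.
oracle_spatial_lr <- function(L, R, in_A, in_B, M) {
    M <- as.matrix(M)
    s <- 0
    for (i in which(in_A)) {
        jb <- which(in_B)
        s <- s + L[i] * sum(M[i, jb] * R[jb]) - R[i] * sum(M[i, jb] * L[jb])
    }
    unname(s)
}

## Dense grid search over the 2-simplex (step 1e-3) for a 3-column NNLS fit,
## followed by local refinement; used as the deconvolution oracle.
oracle_simplex_weights <- function(y, P) {
    stopifnot(ncol(P) == 3)
    best <- NULL; best_val <- Inf
    for (w1 in seq(0, 1, by = 0.01)) for (w2 in seq(0, 1 - w1, by = 0.01)) {
        w <- c(w1, w2, 1 - w1 - w2)
        v <- sum((y - P %*% w)^2)
        if (v < best_val) { best_val <- v; best <- w }
    }
    for (step in c(1e-3, 1e-4, 1e-5, 1e-6)) {
        improved <- TRUE
        while (improved) {
            improved <- FALSE
            for (a in 1:3) for (b in 1:3) {
                if (a == b) next
                w <- best
                if (w[a] < step) next
                w[a] <- w[a] - step; w[b] <- w[b] + step
                v <- sum((y - P %*% w)^2)
                if (v < best_val - 1e-18) {
                    best_val <- v; best <- w; improved <- TRUE
                }
            }
        }
    }
    best
}

## Small spatial fixture with a hand-chosen normalized assay.
make_spatial_fixture <- function(norm, x, y, cell_type,
                                 annotation_class = "singlet") {
    counts <- matrix(round(norm), nrow(norm), ncol(norm),
                     dimnames = dimnames(norm))
    ds <- SpatialDataset(counts, x = x, y = y, cell_type = cell_type,
                         annotation_class = annotation_class)
    SummarizedExperiment::assay(ds, "normalized", withDimnames = FALSE) <-
        Matrix::Matrix(norm, sparse = TRUE)
    ds
}

## Small dissociated fixture with an explicit normalized assay.
make_expression_fixture <- function(norm, sample_id, fraction, cell_type,
                                    counts = NULL, ...) {
    if (is.null(counts)) counts <- round(norm)
    ds <- ExpressionDataset(counts, sample_id = sample_id,
                            fraction = fraction, cell_type = cell_type, ...)
    SummarizedExperiment::assay(ds, "normalized", withDimnames = FALSE) <-
        Matrix::Matrix(norm, sparse = TRUE)
    ds
}

## Lightweight random LR instance (no expression container): coordinates,
## binary union-kNN graph, masks and lognormal expression vectors. Used by
## the high-volume oracle-equivalence and antisymmetry suites, which
## exercise the score kernel directly.
random_lr_components <- function(n, k = 5) {
    coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    graph <- buildKnnGraph(coords, k = k)
    types <- sample(c("A", "B"), n, replace = TRUE)
    list(M = graphAdjacency(graph), a = as.numeric(types == "A"),
         b = as.numeric(types == "B"), L = rlnorm(n), R = rlnorm(n))
}

## Random small LR instance used by the oracle-equivalence and antisymmetry
## suites: coordinates, binary union-kNN graph, lognormal expression.
random_lr_instance <- function(n, k = 5, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    graph <- buildKnnGraph(coords, k = k)
    types <- sample(c("A", "B"), n, replace = TRUE)
    norm <- rbind(L = rlnorm(n), R = rlnorm(n))
    colnames(norm) <- sprintf("b%03d", seq_len(n))
    ds <- make_spatial_fixture(norm, coords[, 1], coords[, 2], types)
    list(ds = ds, graph = graph, types = types, norm = norm)
}
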