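## Spatial statistics: union-symmetrized Euclidean kNN graphs, textbook
## Moran's I with binary (optionally row-standardized) weights, cell-type
## autocorrelation on membership indicators, and automated tumor /
## tumor-adjacent context segmentation from local tumor-bead density.

#' Build a k-nearest-neighbor graph over bead coordinates
#'
#' Euclidean kNN with ties broken by lower bead index; edges are
#' symmetrized by union and weights are binary.
#'
#' @param coords two-column matrix of finite coordinates (microns)
#' @param k neighbors per bead, default 10
#' @return a \linkS4class{SpatialGraph}
#' @export
buildKnnGraph <- function(coords, k = 10) {
    coords <- as.matrix(coords)
    n <- nrow(coords)
    if (n < k + 1) stop("need at least k+1 beads (k = ", k, ", n = ", n, ")")
    stopifnot(all(is.finite(coords)))
    D <- as.matrix(stats::dist(coords))
    diag(D) <- Inf
    from <- integer(0); to <- integer(0)
    for (i in seq_len(n)) {
        nb <- order(D[i, ], seq_len(n))[seq_len(k)]
        from <- c(from, rep.int(i, k)); to <- c(to, nb)
    }
    A <- sparseMatrix(i = from, j = to, x = 1, dims = c(n, n))
    A <- methods::as((A + Matrix::t(A)) > 0, "CsparseMatrix") * 1
    A <- methods::as(A, "CsparseMatrix")
    if (!is.null(rownames(coords))) dimnames(A) <- list(rownames(coords),
                                                        rownames(coords))
    methods::new("SpatialGraph", adjacency = A, k = as.integer(k))
}

#' Moran's I spatial autocorrelation
#'
#' \deqn{I = \frac{n}{\sum_{ij} W_{ij}}
#'   \frac{\sum_{ij} W_{ij}(x_i-\bar x)(x_j-\bar x)}{\sum_i (x_i-\bar x)^2}}
#' With row-standardized weights the leading factor is 1. Positive I means
#' spatially clustered values; negative, alternating/dispersed ones.
#'
#' @param values numeric vector over all graph nodes (non-constant)
#' @param graph a \linkS4class{SpatialGraph} (or a symmetric weight matrix)
#' @param row_standardize divide each row of W by its sum (default TRUE)
#' @return Moran's I
#' @export
moransI <- function(values, graph, row_standardize = TRUE) {
    W <- if (methods::is(graph, "SpatialGraph")) graph@adjacency else graph
    n <- length(values)
    stopifnot(nrow(W) == n)
    z <- values - mean(values)
    s2 <- sum(z^2)
    if (s2 == 0) stop("zero variance: values are constant")
    if (row_standardize) {
        rs <- Matrix::rowSums(W)
        W <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% W
    }
    S0 <- sum(W)
    as.numeric((n / S0) * sum(z * (W %*% z)) / s2)
}

#' Cell-type spatial autocorrelation
#'
#' Moran's I of the binary membership indicator of a cell type over the
#' singlet / doublet-certain beads.
#'
#' @param spatial a \linkS4class{SpatialDataset}
#' @param graph \linkS4class{SpatialGraph} over the dataset's beads (all
#'   beads, or the non-reject beads)
#' @param cell_type cell type present on at least 2 beads
#' @param row_standardize passed to \code{\link{moransI}}
#' @return Moran's I of the indicator
#' @export
celltypeAutocorrelation <- function(spatial, graph, cell_type,
                                    row_standardize = TRUE) {
    cd <- colData(spatial)
    keep <- cd$annotation_class != "reject"
    W <- graph@adjacency
    if (nrow(W) == ncol(spatial) && !all(keep))
        W <- W[keep, keep, drop = FALSE]
    else if (nrow(W) != sum(keep))
        stop("graph size matches neither all beads nor the non-reject beads")
    ind <- as.numeric(cd$cell_type[keep] == cell_type)
    if (sum(ind) < 2) stop(sprintf(
        "cell type '%s' present on %d non-reject bead(s); need >= 2",
        cell_type, sum(ind)))
    moransI(ind, W, row_standardize = row_standardize)
}

#' Segment a puck into tumor and tumor-adjacent contexts
#'
#' Per bead, the local tumor fraction is the share of tumor-annotated beads
#' among the non-reject beads within \code{smoothing_hops} graph hops
#' (inclusive of self); beads at or above \code{density_threshold} form the
#' tumor context, the remaining non-reject beads the adjacent context, and
#' reject-class beads are excluded.
#'
#' @param spatial a \linkS4class{SpatialDataset}
#' @param graph \linkS4class{SpatialGraph} over all beads of the dataset
#' @param tumor_type_label the bead annotation that marks tumor cells
#' @param density_threshold tumor-context cutoff on the local fraction
#'   (inclusive), default 0.3
#' @param smoothing_hops neighborhood radius in graph hops, default 1
#' @return factor per bead with levels \code{tumor_context},
#'   \code{adjacent_context}, \code{excluded}
#' @export
segmentContexts <- function(spatial, graph, tumor_type_label,
                            density_threshold = 0.3, smoothing_hops = 1) {
    cd <- colData(spatial)
    A <- graph@adjacency
    stopifnot(nrow(A) == ncol(spatial))
    valid <- cd$annotation_class != "reject"
    tum <- valid & cd$cell_type == tumor_type_label
    if (!any(tum))
        warning(sprintf("no '%s' beads: all beads assigned adjacent_context",
                        tumor_type_label))
    R <- Matrix::Diagonal(nrow(A)) + A
    if (smoothing_hops > 1)
        for (h in seq_len(smoothing_hops - 1)) R <- R %*% (Matrix::Diagonal(
            nrow(A)) + A)
    R <- methods::as(R > 0, "CsparseMatrix") * 1
    n_tumor <- as.vector(R %*% as.numeric(tum))
    n_valid <- as.vector(R %*% as.numeric(valid))
    frac <- ifelse(n_valid > 0, n_tumor / n_valid, 0)
    ctx <- ifelse(!valid, "excluded",
                  ifelse(frac >= density_threshold, "tumor_context",
                         "adjacent_context"))
    factor(ctx, levels = c("tumor_context", "adjacent_context", "excluded"))
}
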