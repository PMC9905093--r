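## Derivation of a compact malignant-cell gene signature: per-gene rank-sum
## marker statistics, the healthy-expression exclusion filter, score-based
## malignant calls, and ROC/AUC evaluation on bulk cohorts.

#' Per-gene rank-sum marker statistics between two cell groups
#'
#' Each gene is tested A vs B on normalized expression with the two-sided
#' rank-sum test (\code{\link{rankSumTest}}); Z is the signed standard-normal
#' quantile of the p-value, positive when the gene is higher in A. The
#' expression fraction (share of cells with raw count > 0) is reported per
#' group. Genes that are all-zero in both groups get Z = 0.
#'
#' @param dataset an \linkS4class{ExpressionDataset} with a normalized assay
#' @param cells_A,cells_B column indices, names, or logical masks; both
#'   non-empty, disjoint
#' @return \linkS4class{DataFrame}: \code{gene}, \code{Z}, \code{p},
#'   \code{frac_a}, \code{frac_b}
#' @export
rankMarkers <- function(dataset, cells_A, cells_B) {
    norm <- as.matrix(.getNormalized(dataset))
    counts <- .getCounts(dataset)
    A <- norm[, cells_A, drop = FALSE]
    B <- norm[, cells_B, drop = FALSE]
    stopifnot(ncol(A) > 0, ncol(B) > 0)
    fa <- Matrix::rowMeans(counts[, cells_A, drop = FALSE] > 0)
    fb <- Matrix::rowMeans(counts[, cells_B, drop = FALSE] > 0)
    res <- t(vapply(seq_len(nrow(norm)), function(g) {
        t <- rankSumTest(A[g, ], B[g, ])
        c(t$Z, t$p)
    }, numeric(2)))
    DataFrame(gene = rownames(norm), Z = res[, 1], p = res[, 2],
              frac_a = as.numeric(fa), frac_b = as.numeric(fb))
}

#' Per-gene detection fraction
#'
#' Share of the selected cells in which each gene has raw count > 0
#' ("expressed" means detected at least once).
#'
#' @param dataset dataset or counts matrix
#' @param cells optional column selection (default: all cells)
#' @return named numeric vector in [0, 1]
#' @export
expressionFraction <- function(dataset, cells = NULL) {
    m <- .getCounts(dataset)
    if (!is.null(cells)) m <- m[, cells, drop = FALSE]
    f <- Matrix::rowMeans(m > 0)
    stats::setNames(as.numeric(f), rownames(m))
}

#' Derive a compact tumor signature from marker statistics
#'
#' Keeps genes upregulated in the malignant group with Z strictly greater
#' than \code{z_threshold} AND expressed in strictly less than
#' \code{healthy_fraction_max} of healthy epithelial cells, ordered by
#' descending Z. An empty result is returned with a warning, not an error.
#'
#' @param markers \linkS4class{DataFrame} from \code{\link{rankMarkers}}
#'   (malignant vs non-malignant comparison; positive Z = up in malignant)
#' @param healthy_fractions named per-gene detection fractions over all
#'   healthy epithelial cells (\code{\link{expressionFraction}})
#' @param z_threshold strict lower Z bound, default 3
#' @param healthy_fraction_max strict upper bound on the healthy detection
#'   fraction, default 0.05
#' @param score_threshold malignant-call threshold stored in the signature,
#'   default 0.1
#' @return a \linkS4class{TumorSignature}
#' @export
deriveSignature <- function(markers, healthy_fractions, z_threshold = 3,
                            healthy_fraction_max = 0.05,
                            score_threshold = 0.1) {
    stopifnot(all(c("gene", "Z") %in% colnames(markers)))
    if (!all(markers$gene %in% names(healthy_fractions)))
        stop("healthy_fractions must cover every marker gene")
    hf <- healthy_fractions[markers$gene]
    keep <- markers$Z > z_threshold & hf < healthy_fraction_max
    genes <- markers$gene[keep]
    if (length(genes) == 0)
        warning("no genes pass the signature filters; empty signature")
    genes <- genes[order(-markers$Z[keep])]
    methods::new("TumorSignature", genes = as.character(genes),
                 z_threshold = z_threshold,
                 healthy_fraction_max = healthy_fraction_max,
                 score_threshold = score_threshold)
}

#' Call malignant cells from signature scores
#'
#' A cell is called malignant iff its signature score is strictly greater
#' than the threshold.
#'
#' @param cell_scores per-cell signature scores (means of signature genes on
#'   normalized expression, see \code{\link{scoreCells}})
#' @param score_threshold default 0.1
#' @return logical vector
#' @export
classifyCells <- function(cell_scores, score_threshold = 0.1) {
    as.vector(cell_scores > score_threshold)
}

#' Evaluate a signature on a bulk cohort by ROC AUC
#'
#' Per-sample score = mean expression of the signature genes (optionally
#' z-scored per gene first). AUC is the Mann-Whitney concordance probability
#' (ties counted one half), computed from ranks; ROC points are returned at
#' every threshold.
#'
#' @param bulk genes x samples expression matrix
#' @param labels per-sample class labels
#' @param signature a \linkS4class{TumorSignature} or character vector of
#'   genes
#' @param positive label of the positive (tumor) class, default
#'   \code{"tumor"}
#' @param standardize z-score each gene across samples before averaging
#'   (default FALSE)
#' @return list: \code{auc}, \code{roc} (DataFrame threshold/fpr/tpr),
#'   \code{scores}
#' @export
evaluateBulkAUC <- function(bulk, labels, signature, positive = "tumor",
                            standardize = FALSE) {
    genes <- if (methods::is(signature, "TumorSignature"))
        signature@genes else as.character(signature)
    present <- intersect(genes, rownames(bulk))
    if (length(present) == 0) stop("no signature gene present in the matrix")
    labels <- as.character(labels)
    pos <- labels == positive
    if (!any(pos) || all(pos))
        stop("need at least one sample in each class")
    m <- bulk[present, , drop = FALSE]
    if (standardize) {
        sds <- apply(m, 1, stats::sd)
        m <- (m - rowMeans(m)) / ifelse(sds > 0, sds, 1)
    }
    scores <- colMeans(m)
    r <- rank(scores)
    n1 <- sum(pos); n0 <- sum(!pos)
    auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    thr <- sort(unique(scores), decreasing = TRUE)
    roc <- DataFrame(threshold = c(Inf, thr),
                     tpr = c(0, vapply(thr, function(t)
                         mean(scores[pos] >= t), numeric(1))),
                     fpr = c(0, vapply(thr, function(t)
                         mean(scores[!pos] >= t), numeric(1))))
    list(auc = auc, roc = roc, scores = scores)
}
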