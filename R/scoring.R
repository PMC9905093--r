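## Gene-set signature scoring (plain means over depth-normalized expression),
## sample-level aggregation, Wilcoxon rank-sum group comparisons, and the
## inter-individual expression-distance metric.

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p by full enumeration of all label assignments when both groups have
#' at most \code{exact_max} observations (ties handled exactly via midranks);
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction. The signed Z score is the standard-normal quantile
#' of the two-sided p, signed by the direction of \code{mean(x) - mean(y)}.
#'
#' @param x,y numeric vectors (both non-empty)
#' @param exact_max enumeration cutoff per group (default 8)
#' @return list with \code{p}, \code{Z}, \code{U} (Mann-Whitney U of x) and
#'   \code{exact}
#' @export
rankSumTest <- function(x, y, exact_max = 8) {
    stopifnot(length(x) >= 1, length(y) >= 1)
    n1 <- length(x); n2 <- length(y); n <- n1 + n2
    r <- rank(c(x, y))
    W <- sum(r[seq_len(n1)])
    U <- W - n1 * (n1 + 1) / 2
    muU <- n1 * n2 / 2
    if (stats::var(c(x, y)) == 0 || isTRUE(all.equal(stats::sd(c(x, y)), 0)))
        return(list(p = 1, Z = 0, U = U, exact = TRUE))
    exact <- n1 <= exact_max && n2 <= exact_max
    if (exact) {
        combs <- utils::combn(n, n1)
        W_all <- colSums(matrix(r[combs], nrow = n1))
        dev <- abs(W_all - (n1 * (n1 + 1) / 2) - muU)
        p <- mean(dev >= abs(U - muU) - 1e-12)
    } else {
        tab <- table(r)
        tie <- sum(tab^3 - tab)
        sig2 <- n1 * n2 / 12 * ((n + 1) - tie / (n * (n - 1)))
        z <- (abs(U - muU) - 0.5) / sqrt(sig2)
        z <- max(z, 0)
        p <- min(1, 2 * stats::pnorm(-z))
    }
    s <- sign(mean(x) - mean(y))
    Z <- if (p >= 1 || s == 0) 0 else s * stats::qnorm(p / 2,
                                                       lower.tail = FALSE)
    list(p = p, Z = Z, U = U, exact = exact)
}

#' Per-cell gene-set signature scores
#'
#' The score of a cell is the arithmetic mean, over the set's genes present
#' in the matrix, of its depth-normalized expression. Genes absent from the
#' matrix are dropped with a warning listing them; zero overlap is an error.
#'
#' @param x an object with a \code{normalized} assay (see
#'   \code{\link{normalizeDepth}}) or a normalized matrix
#' @param gene_set a \linkS4class{GeneSet}
#' @return named numeric vector of per-cell scores
#' @export
scoreCells <- function(x, gene_set) {
    stopifnot(methods::is(gene_set, "GeneSet"))
    m <- .getNormalized(x)
    present <- intersect(gene_set@genes, rownames(m))
    if (length(present) == 0)
        stop(sprintf("no genes of set '%s' are present in the matrix",
                     gene_set@name))
    missing <- setdiff(gene_set@genes, present)
    if (length(missing))
        warning(sprintf("set '%s': dropping %d absent gene(s): %s",
                        gene_set@name, length(missing),
                        paste(missing, collapse = ", ")))
    Matrix::colMeans(m[present, , drop = FALSE])
}

#' Aggregate per-cell scores to per-sample scores
#'
#' The per-sample (and optionally per-stratum) score is the exact arithmetic
#' mean of its member cells' scores.
#'
#' @param cell_scores numeric vector, one score per cell
#' @param cell_meta data.frame/DataFrame with a \code{sample_id} column and
#'   any stratification columns (e.g. the \code{colData} of the dataset)
#' @param stratify_by character vector of metadata columns to stratify by
#'   (e.g. \code{c("fraction", "cell_type")})
#' @return \linkS4class{DataFrame} with one row per sample x strata:
#'   grouping keys, \code{score}, \code{n_cells}
#' @export
scoreSamples <- function(cell_scores, cell_meta, stratify_by = character()) {
    cell_meta <- as.data.frame(cell_meta)
    stopifnot(length(cell_scores) == nrow(cell_meta),
              "sample_id" %in% colnames(cell_meta),
              all(stratify_by %in% colnames(cell_meta)))
    keys <- c("sample_id", stratify_by)
    key <- do.call(paste, c(cell_meta[keys], sep = "\r"))
    agg <- tapply(cell_scores, key, mean)
    ncell <- tapply(cell_scores, key, length)
    parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
    out <- DataFrame(parts)
    colnames(out) <- keys
    out$score <- as.numeric(agg)
    out$n_cells <- as.integer(ncell)
    out[order(out$sample_id), , drop = FALSE]
}

#' Pairwise two-sided rank-sum comparison of group scores
#'
#' For every unordered pair of groups, the two-sided Wilcoxon rank-sum p
#' (exact by enumeration when both groups have <= 8 samples, tie- and
#' continuity-corrected normal approximation otherwise).
#'
#' @param sample_scores numeric vector of per-sample scores
#' @param group_labels group label per sample
#' @return \linkS4class{DataFrame}: \code{group_a}, \code{group_b},
#'   \code{n_a}, \code{n_b}, \code{p}, \code{Z}
#' @export
compareGroups <- function(sample_scores, group_labels) {
    group_labels <- as.factor(group_labels)
    lv <- levels(group_labels)
    counts <- table(group_labels)
    if (sum(counts > 0) < 2) stop("need >= 2 non-empty groups")
    rows <- list()
    for (i in seq_along(lv)) for (j in seq_along(lv)) {
        if (j <= i) next
        if (counts[lv[i]] == 0 || counts[lv[j]] == 0) {
            warning(sprintf("pair (%s, %s) skipped: empty group",
                            lv[i], lv[j]))
            next
        }
        t <- rankSumTest(sample_scores[group_labels == lv[i]],
                         sample_scores[group_labels == lv[j]])
        rows[[length(rows) + 1L]] <-
            DataFrame(group_a = lv[i], group_b = lv[j],
                      n_a = as.integer(counts[lv[i]]),
                      n_b = as.integer(counts[lv[j]]),
                      p = t$p, Z = t$Z)
    }
    do.call(rbind, rows)
}

#' Inter-individual expression distance per fraction
#'
#' For each cell type, the distance between two samples is one minus the
#' Pearson correlation of their mean normalized profiles (computed over
#' samples contributing at least \code{min_cells} cells of that type).
#' Per-pair distances are averaged across cell types with weights equal to
#' the pair's minimum cell count per type, then grouped by fraction.
#' Fractions with fewer than two samples are omitted.
#'
#' @param dataset an \linkS4class{ExpressionDataset} with a normalized assay
#' @param cell_types cell types to include (default: all)
#' @param min_cells minimum cells per (sample, type) profile, default 10
#' @return \linkS4class{DataFrame}: \code{fraction}, \code{sample_a},
#'   \code{sample_b}, \code{distance} (in [0, 2])
#' @export
sampleExpressionDistance <- function(dataset, cell_types = NULL,
                                     min_cells = 10) {
    m <- .getNormalized(dataset)
    cd <- colData(dataset)
    if (is.null(cell_types)) cell_types <- unique(cd$cell_type)
    rows <- list()
    for (f in unique(cd$fraction)) {
        samples <- unique(cd$sample_id[cd$fraction == f])
        if (length(samples) < 2) next
        ## per (sample, type): mean profile + cell count
        prof <- list(); nc <- list()
        for (s in samples) for (tp in cell_types) {
            sel <- cd$fraction == f & cd$sample_id == s & cd$cell_type == tp
            if (sum(sel) >= min_cells) {
                prof[[paste(s, tp)]] <-
                    Matrix::rowMeans(m[, sel, drop = FALSE])
                nc[[paste(s, tp)]] <- sum(sel)
            }
        }
        for (a_i in seq_along(samples)) for (b_i in seq_along(samples)) {
            if (b_i <= a_i) next
            a <- samples[a_i]; b <- samples[b_i]
            num <- 0; den <- 0
            for (tp in cell_types) {
                ka <- paste(a, tp); kb <- paste(b, tp)
                if (is.null(prof[[ka]]) || is.null(prof[[kb]])) next
                d <- 1 - stats::cor(prof[[ka]], prof[[kb]])
                w <- min(nc[[ka]], nc[[kb]])
                num <- num + w * d; den <- den + w
            }
            if (den > 0)
                rows[[length(rows) + 1L]] <-
                    DataFrame(fraction = f, sample_a = a, sample_b = b,
                              distance = num / den)
        }
    }
    if (!length(rows))
        return(DataFrame(fraction = character(), sample_a = character(),
                         sample_b = character(), distance = numeric()))
    do.call(rbind, rows)
}
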