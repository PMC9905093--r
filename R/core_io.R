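## File I/O (MTX + TSV + GMT), QC filters and depth normalization.
## On-disk convention: genes are MTX rows (CellRanger orientation); TSVs are
## UTF-8 with a header row and no quoting — a tab inside an id is an error.

#' @importFrom utils read.delim write.table head
NULL

.read_tsv <- function(path) {
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "")
}

.write_tsv <- function(df, path) {
    bad <- vapply(df, function(col) any(grepl("\t", as.character(col))),
                  logical(1))
    if (any(bad))
        stop("tab character inside a field (columns: ",
             paste(names(df)[bad], collapse = ", "),
             "); the TSV dialect does not quote tabs")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
}

#' Read a dissociated expression dataset from MTX + TSV files
#'
#' @param matrix_path Matrix Market coordinate file, genes as rows.
#' @param genes_path TSV with header, first column = gene ids.
#' @param meta_path TSV with header; columns \code{sample_id},
#'   \code{fraction}, \code{cell_type} required, plus any of \code{subtype},
#'   \code{malignant}, \code{doublet_score}.
#' @return an \linkS4class{ExpressionDataset}; integer counts are preserved
#'   exactly.
#' @export
readExpression <- function(matrix_path, genes_path, meta_path) {
    m <- methods::as(Matrix::readMM(matrix_path), "CsparseMatrix")
    genes <- .read_tsv(genes_path)
    meta <- .read_tsv(meta_path)
    if (nrow(genes) != nrow(m))
        stop(sprintf("dimension mismatch: %s has %d genes but %s lists %d",
                     matrix_path, nrow(m), genes_path, nrow(genes)))
    if (nrow(meta) != ncol(m))
        stop(sprintf("dimension mismatch: %s has %d cells but %s lists %d",
                     matrix_path, ncol(m), meta_path, nrow(meta)))
    if (any(m@x != round(m@x)))
        stop(sprintf("non-integer entries in %s", matrix_path))
    rownames(m) <- genes[[1]]
    if ("cell_id" %in% colnames(meta)) colnames(m) <- meta$cell_id
    ExpressionDataset(m,
                      sample_id = meta$sample_id, fraction = meta$fraction,
                      cell_type = meta$cell_type, subtype = meta$subtype,
                      malignant = meta$malignant,
                      doublet_score = meta$doublet_score)
}

#' Write an ExpressionDataset as MTX + TSV
#'
#' Produces \code{matrix.mtx}, \code{genes.tsv} and \code{cell_meta.tsv}
#' under \code{out_dir}, readable by \code{\link{readExpression}} with
#' bit-exact integer counts.
#'
#' @param dataset an \linkS4class{ExpressionDataset}
#' @param out_dir output directory (created if needed)
#' @return invisibly, the three file paths
#' @export
writeExpression <- function(dataset, out_dir) {
    stopifnot(methods::is(dataset, "ExpressionDataset"))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, c("matrix.mtx", "genes.tsv", "cell_meta.tsv"))
    Matrix::writeMM(methods::as(assay(dataset, "counts"), "generalMatrix"),
                    paths[1])
    .write_tsv(data.frame(gene_id = rownames(dataset)), paths[2])
    .write_tsv(cbind(data.frame(cell_id = colnames(dataset)),
                     as.data.frame(colData(dataset))), paths[3])
    invisible(paths)
}

#' Read a spatial dataset from MTX + TSV files
#'
#' @param matrix_path MTX counts, genes as rows.
#' @param genes_path TSV, first column = gene ids.
#' @param beads_path TSV with columns \code{x}, \code{y}, \code{cell_type},
#'   \code{annotation_class}.
#' @return a \linkS4class{SpatialDataset}
#' @export
readSpatial <- function(matrix_path, genes_path, beads_path) {
    m <- methods::as(Matrix::readMM(matrix_path), "CsparseMatrix")
    genes <- .read_tsv(genes_path)
    meta <- .read_tsv(beads_path)
    if (nrow(genes) != nrow(m) || nrow(meta) != ncol(m))
        stop("dimension mismatch between matrix and gene/bead files")
    rownames(m) <- genes[[1]]
    if ("bead_id" %in% colnames(meta)) colnames(m) <- meta$bead_id
    SpatialDataset(m, x = meta$x, y = meta$y, cell_type = meta$cell_type,
                   annotation_class = meta$annotation_class)
}

#' Write a SpatialDataset as MTX + TSV
#' @param dataset a \linkS4class{SpatialDataset}
#' @param out_dir output directory
#' @return invisibly, the file paths
#' @export
writeSpatial <- function(dataset, out_dir) {
    stopifnot(methods::is(dataset, "SpatialDataset"))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, c("matrix.mtx", "genes.tsv", "bead_meta.tsv"))
    Matrix::writeMM(methods::as(assay(dataset, "counts"), "generalMatrix"),
                    paths[1])
    .write_tsv(data.frame(gene_id = rownames(dataset)), paths[2])
    .write_tsv(cbind(data.frame(bead_id = colnames(dataset)),
                     as.data.frame(colData(dataset))), paths[3])
    invisible(paths)
}

#' Read gene sets from a GMT file
#'
#' GMT dialect: one set per line, tab-separated \code{name},
#' \code{description}, then gene ids. Duplicate genes within a line are
#' dropped with a warning.
#'
#' @param gmt_path path to a GMT file
#' @return list of \linkS4class{GeneSet}
#' @export
readGeneSets <- function(gmt_path) {
    lines <- readLines(gmt_path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    out <- vector("list", length(lines))
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3L)
            stop(sprintf("GMT parse error at line %d: %d field(s), need >= 3",
                         i, length(f)))
        genes <- f[-(1:2)]
        if (anyDuplicated(genes)) {
            warning(sprintf("duplicate gene(s) removed from set '%s': %s",
                            f[1], paste(unique(genes[duplicated(genes)]),
                                        collapse = ", ")))
            genes <- unique(genes)
        }
        out[[i]] <- GeneSet(f[1], genes)
    }
    out
}

#' Write gene sets to a GMT file
#' @param sets a \linkS4class{GeneSet} or list of them
#' @param path output path
#' @export
writeGeneSets <- function(sets, path) {
    if (methods::is(sets, "GeneSet")) sets <- list(sets)
    lines <- vapply(sets, function(s)
        paste(c(s@name, "na", s@genes), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a ligand-receptor pair table
#'
#' TSV with header columns \code{ligand}, \code{receptor}, \code{pair_id}
#' (CellPhoneDB-style single-gene pairs).
#'
#' @param path TSV path
#' @return data.frame with those three character columns
#' @export
readLRTable <- function(path) {
    df <- .read_tsv(path)
    need <- c("ligand", "receptor", "pair_id")
    if (!all(need %in% colnames(df)))
        stop("LR table must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(df$pair_id)) stop("pair_id values must be unique")
    if (any(!nzchar(df$ligand)) || any(!nzchar(df$receptor)))
        stop("ligand/receptor gene ids must be non-empty")
    df[need]
}

## ---------------------------------------------------------------------------
## QC filters
## ---------------------------------------------------------------------------

#' Filter cells (or beads) by total UMI
#'
#' Keeps columns whose total count is at least \code{min_umi}; cells with
#' strictly fewer are removed ("low quality"). The same rule serves the
#' 600-UMI scRNA-seq cutoff and the 100-UMI Slide-seq bead cutoff.
#'
#' @param dataset \linkS4class{ExpressionDataset} or
#'   \linkS4class{SpatialDataset}
#' @param min_umi minimum total count to keep (>= 0)
#' @return the filtered dataset, column order preserved
#' @export
filterCellsByUMI <- function(dataset, min_umi) {
    stopifnot(min_umi >= 0)
    keep <- Matrix::colSums(assay(dataset, "counts")) >= min_umi
    if (!any(keep))
        warning("no cells pass the UMI filter (min_umi = ", min_umi, ")")
    dataset[, keep]
}

#' Remove likely doublets by score
#'
#' Removes cells whose doublet score is strictly greater than
#' \code{max_score} (scores "above" the cutoff are omitted).
#'
#' @param dataset an \linkS4class{ExpressionDataset} with a
#'   \code{doublet_score} column
#' @param max_score default 0.4
#' @return the filtered dataset
#' @export
filterDoublets <- function(dataset, max_score = 0.4) {
    ds <- colData(dataset)$doublet_score
    if (is.null(ds) || anyNA(ds))
        stop("doublet_score is missing for some cells; ",
             "skip this filter if scores are unavailable")
    dataset[, ds <= max_score]
}

## ---------------------------------------------------------------------------
## Normalization
## ---------------------------------------------------------------------------

#' Depth-normalize counts
#'
#' Scales every cell column so it sums to \code{scale_constant} (linear
#' counts-per-constant; no log transform by default). Zero-depth columns are
#' left at zero with a warning.
#'
#' @param dataset an \linkS4class{ExpressionDataset} or
#'   \linkS4class{SpatialDataset} (or a plain counts matrix)
#' @param scale_constant target column sum, default 10000
#' @param log1p if TRUE, apply \code{log1p} after scaling (off by default;
#'   signature averages and LR products are defined on linear magnitudes)
#' @return the input object with a \code{normalized} assay added (for
#'   matrices, the normalized matrix with attribute \code{scale_constant})
#' @export
normalizeDepth <- function(dataset, scale_constant = 1e4, log1p = FALSE) {
    stopifnot(scale_constant > 0)
    m <- if (methods::is(dataset, "SummarizedExperiment"))
        assay(dataset, "counts") else dataset
    depth <- Matrix::colSums(m)
    if (any(depth == 0))
        warning(sum(depth == 0), " zero-depth column(s) left at zero")
    sf <- ifelse(depth > 0, scale_constant / depth, 0)
    norm <- m %*% Matrix::Diagonal(x = sf)
    dimnames(norm) <- dimnames(m)
    if (log1p) norm <- log1p(norm)
    if (methods::is(dataset, "SummarizedExperiment")) {
        SummarizedExperiment::assay(dataset, "normalized") <- norm
        dataset
    } else {
        attr(norm, "scale_constant") <- scale_constant
        norm
    }
}

## Retrieve a normalized matrix from a dataset or pass a matrix through.
.getNormalized <- function(x) {
    if (methods::is(x, "SummarizedExperiment")) {
        if (!"normalized" %in% assayNames(x))
            stop("no 'normalized' assay; run normalizeDepth() first")
        assay(x, "normalized")
    } else x
}

.getCounts <- function(x) {
    if (methods::is(x, "SummarizedExperiment")) assay(x, "counts") else x
}
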