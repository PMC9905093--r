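#' @import methods
#' @importFrom Matrix Matrix rowSums colSums t sparseMatrix
#' @importClassesFrom Matrix CsparseMatrix
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment assay assays assayNames colData rowData
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

.FRACTIONS <- c("healthy", "adj_normal", "tumor")
.ANNOT_CLASSES <- c("singlet", "doublet_certain", "reject")

## ---------------------------------------------------------------------------
## ExpressionDataset: gene x cell counts with sample/fraction/cell-type metadata
## ---------------------------------------------------------------------------

#' Dissociated single-cell expression dataset
#'
#' A \linkS4class{SingleCellExperiment} holding a sparse non-negative integer
#' \code{counts} assay (genes as rows) and per-cell metadata columns
#' \code{sample_id}, \code{fraction} (one of \code{healthy}, \code{adj_normal},
#' \code{tumor}), \code{cell_type}, and optionally \code{subtype},
#' \code{malignant} and \code{doublet_score}.
#'
#' @export
setClass("ExpressionDataset", contains = "SingleCellExperiment")

.check_counts <- function(m) {
    x <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
    if (any(x < 0)) return("counts contain negative entries")
    if (any(x != round(x))) return("counts contain non-integer entries")
    NULL
}

setValidity("ExpressionDataset", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        bad <- .check_counts(assay(object, "counts"))
        if (!is.null(bad)) msg <- c(msg, bad)
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be unique")
    cd <- colData(object)
    for (col in c("sample_id", "fraction", "cell_type"))
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("cell metadata column '%s' is required", col))
    if ("fraction" %in% colnames(cd) &&
        !all(as.character(cd$fraction) %in% .FRACTIONS))
        msg <- c(msg, sprintf("fraction values must be one of: %s",
                              paste(.FRACTIONS, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param counts sparse or dense non-negative integer matrix, genes x cells,
#'   with unique rownames.
#' @param sample_id,fraction,cell_type per-cell character vectors; fraction
#'   must be one of \code{"healthy"}, \code{"adj_normal"}, \code{"tumor"}.
#' @param subtype,malignant,doublet_score optional per-cell columns.
#' @return A validated \linkS4class{ExpressionDataset}.
#' @export
ExpressionDataset <- function(counts, sample_id, fraction, cell_type,
                              subtype = NULL, malignant = NULL,
                              doublet_score = NULL) {
    counts <- methods::as(Matrix(counts, sparse = TRUE), "CsparseMatrix")
    cd <- DataFrame(sample_id = as.character(sample_id),
                    fraction = as.character(fraction),
                    cell_type = as.character(cell_type))
    if (!is.null(subtype)) cd$subtype <- as.character(subtype)
    if (!is.null(malignant)) cd$malignant <- as.logical(malignant)
    if (!is.null(doublet_score)) cd$doublet_score <- as.numeric(doublet_score)
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("cell_%d", seq_len(ncol(counts)))
    rownames(cd) <- colnames(counts)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), colData = cd)
    methods::validObject(out <- methods::new("ExpressionDataset", sce))
    out
}

## ---------------------------------------------------------------------------
## SpatialDataset: gene x bead counts with coordinates and bead annotations
## ---------------------------------------------------------------------------

#' Slide-seq-style spatial dataset
#'
#' A \linkS4class{SingleCellExperiment} whose columns are beads, with a sparse
#' integer \code{counts} assay and per-bead metadata \code{x}, \code{y}
#' (micron coordinates), \code{cell_type} and \code{annotation_class}
#' (\code{singlet}, \code{doublet_certain} or \code{reject}).
#'
#' @export
setClass("SpatialDataset", contains = "SingleCellExperiment")

setValidity("SpatialDataset", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        bad <- .check_counts(assay(object, "counts"))
        if (!is.null(bad)) msg <- c(msg, bad)
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be unique")
    cd <- colData(object)
    for (col in c("x", "y", "cell_type", "annotation_class"))
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("bead metadata column '%s' is required", col))
    if (all(c("x", "y") %in% colnames(cd)) &&
        !all(is.finite(cd$x) & is.finite(cd$y)))
        msg <- c(msg, "bead coordinates must be finite")
    if ("annotation_class" %in% colnames(cd) &&
        !all(as.character(cd$annotation_class) %in% .ANNOT_CLASSES))
        msg <- c(msg, sprintf("annotation_class values must be one of: %s",
                              paste(.ANNOT_CLASSES, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct a SpatialDataset
#'
#' @param counts sparse/dense non-negative integer matrix, genes x beads.
#' @param x,y finite bead coordinates in microns.
#' @param cell_type per-bead dominant cell-type call.
#' @param annotation_class per-bead confidence class: \code{"singlet"},
#'   \code{"doublet_certain"} or \code{"reject"}.
#' @param extra optional DataFrame of additional bead columns.
#' @return A validated \linkS4class{SpatialDataset}.
#' @export
SpatialDataset <- function(counts, x, y, cell_type,
                           annotation_class = "singlet", extra = NULL) {
    counts <- methods::as(Matrix(counts, sparse = TRUE), "CsparseMatrix")
    if (length(annotation_class) == 1L)
        annotation_class <- rep(annotation_class, ncol(counts))
    cd <- DataFrame(x = as.numeric(x), y = as.numeric(y),
                    cell_type = as.character(cell_type),
                    annotation_class = as.character(annotation_class))
    if (!is.null(extra)) cd <- cbind(cd, extra)
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("bead_%d", seq_len(ncol(counts)))
    rownames(cd) <- colnames(counts)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), colData = cd)
    methods::validObject(out <- methods::new("SpatialDataset", sce))
    out
}

#' Bead coordinates of a SpatialDataset
#' @param x a \linkS4class{SpatialDataset}
#' @return two-column numeric matrix of micron coordinates
#' @export
beadCoords <- function(x) {
    stopifnot(methods::is(x, "SpatialDataset"))
    cbind(x = colData(x)$x, y = colData(x)$y)
}

## ---------------------------------------------------------------------------
## GeneSet
## ---------------------------------------------------------------------------

#' A named gene set
#' @slot name set name
#' @slot genes unique, non-empty character vector of gene ids
#' @export
setClass("GeneSet", representation(name = "character", genes = "character"))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "name must be a single non-empty string")
    if (length(object@genes) == 0L)
        msg <- c(msg, "gene set is empty")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "gene set contains duplicates")
    if (length(msg)) msg else TRUE
})

#' @param name set name
#' @param genes character vector of gene ids
#' @rdname GeneSet-class
#' @export
GeneSet <- function(name, genes) {
    methods::new("GeneSet", name = as.character(name),
                 genes = as.character(genes))
}

setMethod("show", "GeneSet", function(object) {
    cat(sprintf("GeneSet '%s' with %d genes\n", object@name,
                length(object@genes)))
})

## ---------------------------------------------------------------------------
## SpatialGraph
## ---------------------------------------------------------------------------

#' Symmetric spatial bead graph
#'
#' Binary symmetric adjacency over beads (zero diagonal), built by
#' union-symmetrized Euclidean k-nearest neighbors.
#'
#' @slot adjacency symmetric sparse 0/1 matrix with zero diagonal
#' @slot k the k used during construction
#' @export
setClass("SpatialGraph",
         representation(adjacency = "CsparseMatrix", k = "integer"))

setValidity("SpatialGraph", function(object) {
    A <- object@adjacency
    msg <- character()
    if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
    if (any(Matrix::diag(A) != 0)) msg <- c(msg, "diagonal must be zero")
    if (!Matrix::isSymmetric(A)) msg <- c(msg, "adjacency must be symmetric")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SpatialGraph", function(object) {
    cat(sprintf("SpatialGraph: %d beads, %d undirected edges (k = %d)\n",
                nrow(object@adjacency),
                as.integer(Matrix::nnzero(object@adjacency) / 2), object@k))
})

#' Adjacency matrix of a SpatialGraph
#' @param graph a \linkS4class{SpatialGraph}
#' @return sparse symmetric 0/1 matrix
#' @export
graphAdjacency <- function(graph) {
    stopifnot(methods::is(graph, "SpatialGraph"))
    graph@adjacency
}

## ---------------------------------------------------------------------------
## TumorSignature
## ---------------------------------------------------------------------------

#' Compact tumor gene signature
#'
#' Genes surviving the marker-Z and healthy-expression filters, ordered by
#' descending Z, together with the derivation thresholds.
#'
#' @slot genes ordered character vector
#' @slot z_threshold strict lower bound on the marker Z score
#' @slot healthy_fraction_max strict upper bound on the expression fraction in
#'   healthy epithelial cells
#' @slot score_threshold strict lower bound for calling a cell malignant from
#'   its signature score
#' @export
setClass("TumorSignature",
         representation(genes = "character", z_threshold = "numeric",
                        healthy_fraction_max = "numeric",
                        score_threshold = "numeric"))

setMethod("show", "TumorSignature", function(object) {
    cat(sprintf(
        "TumorSignature: %d genes (Z > %g, healthy fraction < %g, score > %g)\n",
        length(object@genes), object@z_threshold,
        object@healthy_fraction_max, object@score_threshold))
    if (length(object@genes))
        cat(" ", paste(utils::head(object@genes, 12), collapse = ", "),
            if (length(object@genes) > 12) "..." else "", "\n")
})

#' Genes of a TumorSignature
#' @param signature a \linkS4class{TumorSignature}
#' @export
signatureGenes <- function(signature) {
    stopifnot(methods::is(signature, "TumorSignature"))
    signature@genes
}

## ---------------------------------------------------------------------------
## AdmixtureFit
## ---------------------------------------------------------------------------

#' Constrained linear-regression admixture fit
#'
#' Non-negative mixing weights of reference cell-type profiles explaining an
#' observed pseudo-bulk profile, normalized to sum to one.
#'
#' @slot target_type name of the target cell type
#' @slot weights named non-negative weights over target + contaminant types,
#'   summing to one
#' @slot references normalized reference profile matrix used in the fit
#'   (genes x types, columns summing to one)
#' @slot residual_norm Euclidean norm of the proportion-space residual
#' @slot condition_number condition number of the design
#' @slot ridged TRUE when the ill-conditioning fallback (ridge) was used
#' @export
setClass("AdmixtureFit",
         representation(target_type = "character", weights = "numeric",
                        references = "matrix", residual_norm = "numeric",
                        condition_number = "numeric", ridged = "logical"))

setValidity("AdmixtureFit", function(object) {
    msg <- character()
    if (any(object@weights < -1e-12)) msg <- c(msg, "weights must be >= 0")
    if (abs(sum(object@weights) - 1) > 1e-8)
        msg <- c(msg, "weights must sum to 1")
    if (!object@target_type %in% names(object@weights))
        msg <- c(msg, "target_type must be among the weight names")
    if (length(msg)) msg else TRUE
})

setMethod("show", "AdmixtureFit", function(object) {
    cat(sprintf("AdmixtureFit for target '%s'%s\n", object@target_type,
                if (object@ridged) " (ridge fallback)" else ""))
    print(round(object@weights, 4))
    cat(sprintf("residual norm %.4g, condition number %.3g\n",
                object@residual_norm, object@condition_number))
})

#' Mixing weights of an AdmixtureFit
#' @param fit an \linkS4class{AdmixtureFit}
#' @export
admixtureWeights <- function(fit) {
    stopifnot(methods::is(fit, "AdmixtureFit"))
    fit@weights
}

## ---------------------------------------------------------------------------
## PseudobulkSet
## ---------------------------------------------------------------------------

#' Per-unit pseudo-bulk profiles of one cell type
#'
#' Exact integer column sums of the member cells/beads of a given cell type
#' within each unit (context, sample, or spatial tile).
#'
#' @slot counts integer matrix, genes x units
#' @slot n_members number of contributing cells/beads per unit
#' @slot cell_type the summarized cell type
#' @export
setClass("PseudobulkSet",
         representation(counts = "matrix", n_members = "integer",
                        cell_type = "character"))

setValidity("PseudobulkSet", function(object) {
    msg <- character()
    if (ncol(object@counts) != length(object@n_members))
        msg <- c(msg, "n_members length must match number of units")
    if (any(object@n_members < 1L))
        msg <- c(msg, "every unit must have >= 1 member")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PseudobulkSet", function(object) {
    cat(sprintf("PseudobulkSet '%s': %d genes x %d units (members: %s)\n",
                object@cell_type, nrow(object@counts), ncol(object@counts),
                paste(object@n_members, collapse = ", ")))
})

#' Pseudo-bulk count matrix
#' @param x a \linkS4class{PseudobulkSet}
#' @export
pseudobulkCounts <- function(x) {
    stopifnot(methods::is(x, "PseudobulkSet"))
    x@counts
}

## ---------------------------------------------------------------------------
## CellTypeProfiles & SimulationTruth (synthetic-data module)
## ---------------------------------------------------------------------------

#' Reference expression profiles per cell type
#'
#' @slot means non-negative mean-expression matrix, genes x cell types
#' @slot markers named list: per type, the marker gene ids
#' @slot marker_fold fold enrichment of markers in their own type
#' @slot dispersion per-gene NB dispersion phi (variance m + phi m^2)
#' @export
setClass("CellTypeProfiles",
         representation(means = "matrix", markers = "list",
                        marker_fold = "numeric", dispersion = "numeric"))

setValidity("CellTypeProfiles", function(object) {
    msg <- character()
    if (any(object@means < 0)) msg <- c(msg, "profile means must be >= 0")
    if (any(object@dispersion < 0)) msg <- c(msg, "dispersion must be >= 0")
    mk <- unlist(object@markers, use.names = FALSE)
    if (anyDuplicated(mk))
        msg <- c(msg, "each marker gene must belong to exactly one type")
    if (!all(mk %in% rownames(object@means)))
        msg <- c(msg, "marker genes must be valid gene ids")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CellTypeProfiles", function(object) {
    cat(sprintf("CellTypeProfiles: %d genes x %d types (%s)\n",
                nrow(object@means), ncol(object@means),
                paste(colnames(object@means), collapse = ", ")))
})

#' Ground truth of a simulated dataset
#'
#' @slot planted_de data.frame (gene, cell_type, condition, log2fc)
#' @slot admixture_weights beads x cell-types mixing matrix (rows sum to 1),
#'   or a 0-row matrix for non-spatial simulations
#' @slot planted_lr data.frame (ligand, receptor, sender_type, receiver_type,
#'   strength)
#' @slot seed the seed used
#' @export
setClass("SimulationTruth",
         representation(planted_de = "data.frame",
                        admixture_weights = "matrix",
                        planted_lr = "data.frame", seed = "integer"))

setMethod("show", "SimulationTruth", function(object) {
    cat(sprintf(paste0("SimulationTruth: %d planted DE effects, %d planted LR",
                       " pairs, admixture for %d beads (seed %d)\n"),
                nrow(object@planted_de), nrow(object@planted_lr),
                nrow(object@admixture_weights), object@seed))
})
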