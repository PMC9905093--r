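## Ligand-receptor screening. Dissociated mode: product of per-type mean
## expression with a cluster-label-shuffling null (1,000 permutations).
## Spatial mode: the antisymmetric neighborhood co-expression score
##   S = sum_ij Lexp_i Rexp_j M_ij - sum_ij Rexp_i Lexp_j M_ij
## over sender beads i and receiver beads j of a symmetric binary kNN graph
## M, with a bead-label-shuffling null (2,000 permutations). One-sided
## upper-tail p with the +1 pseudo-count; BH across all tested rows.

#' Genes expressed in a cell type
#'
#' Genes detected (raw count > 0) in at least \code{min_fraction} of the
#' cells/beads of the given type (inclusive boundary). Reject-class beads
#' are ignored for spatial data.
#'
#' @param dataset \linkS4class{ExpressionDataset} or
#'   \linkS4class{SpatialDataset}
#' @param cell_type the type to assess
#' @param min_fraction detection-fraction cutoff, default 0.10
#' @return character vector of gene ids
#' @export
filterExpressed <- function(dataset, cell_type, min_fraction = 0.10) {
    cd <- colData(dataset)
    sel <- cd$cell_type == cell_type
    if ("annotation_class" %in% colnames(cd))
        sel <- sel & cd$annotation_class != "reject"
    if (!any(sel)) stop("cell type '", cell_type, "' not present")
    f <- expressionFraction(dataset, sel)
    names(f)[f >= min_fraction]
}

.typeCells <- function(dataset, type) {
    cd <- colData(dataset)
    sel <- cd$cell_type == type
    if ("annotation_class" %in% colnames(cd))
        sel <- sel & cd$annotation_class != "reject"
    sel
}

#' Dissociated LR pair score: product of mean expression
#'
#' Mean normalized ligand expression over the sender-type cells times mean
#' normalized receptor expression over the receiver-type cells.
#'
#' @param dataset dataset with a normalized assay
#' @param ligand,receptor gene ids
#' @param sender_type,receiver_type cell types
#' @return the score S
#' @export
lrScoreDissociated <- function(dataset, ligand, receptor, sender_type,
                               receiver_type) {
    m <- .getNormalized(dataset)
    stopifnot(ligand %in% rownames(m), receptor %in% rownames(m))
    s <- .typeCells(dataset, sender_type)
    r <- .typeCells(dataset, receiver_type)
    if (!any(s)) stop("sender type '", sender_type, "' not present")
    if (!any(r)) stop("receiver type '", receiver_type, "' not present")
    mean(m[ligand, s]) * mean(m[receptor, r])
}

#' Permutation p-value for a dissociated LR score
#'
#' The null is built by shuffling the cell-type labels over all cells and
#' recomputing the score each round;
#' \code{p = (1 + #\{S_perm >= S_obs\}) / (n_perm + 1)} (one-sided upper
#' tail).
#'
#' @inheritParams lrScoreDissociated
#' @param n_perm permutation rounds, default 1000
#' @param seed integer seed
#' @return list with \code{score}, \code{p}, \code{n_perm}
#' @export
permuteDissociated <- function(dataset, ligand, receptor, sender_type,
                               receiver_type, n_perm = 1000, seed = 0) {
    m <- .getNormalized(dataset)
    obs <- lrScoreDissociated(dataset, ligand, receptor, sender_type,
                              receiver_type)
    lab <- colData(dataset)$cell_type
    L <- as.numeric(m[ligand, ]); R <- as.numeric(m[receptor, ])
    p <- .withSeed(seed, .permDissociatedP(L, R, lab, sender_type,
                                           receiver_type, obs, n_perm))
    list(score = obs, p = p, n_perm = n_perm)
}

## Directed edge list of a SpatialGraph (both orientations of each edge).
.edgeList <- function(graph) {
    A <- methods::as(graph@adjacency, "TsparseMatrix")
    list(i = A@i + 1L, j = A@j + 1L)
}

## Eq-style antisymmetric score kernel on plain vectors: a, b are 0/1
## sender/receiver masks, M the symmetric binary adjacency.
.spatialScoreKernel <- function(L, R, a, b, M) {
    as.numeric((a * L) %*% (M %*% (b * R)) - (a * R) %*% (M %*% (b * L)))
}

## Permutation worker on plain vectors + edge list; assumes the caller set
## the RNG state. Returns the upper-tail p with the +1 pseudo-count.
.permSpatialP <- function(L, R, lab, type_A, type_B, ei, ej, obs, n_perm) {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
        pl <- lab[sample.int(length(lab))]
        mask <- pl[ei] == type_A & pl[ej] == type_B
        ii <- ei[mask]; jj <- ej[mask]
        sp <- sum(L[ii] * R[jj]) - sum(R[ii] * L[jj])
        if (sp >= obs) exceed <- exceed + 1L
    }
    (1 + exceed) / (n_perm + 1)
}

## Dissociated permutation worker on plain vectors.
.permDissociatedP <- function(L, R, lab, sender, receiver, obs, n_perm) {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
        pl <- lab[sample.int(length(lab))]
        sp <- mean(L[pl == sender]) * mean(R[pl == receiver])
        if (sp >= obs) exceed <- exceed + 1L
    }
    (1 + exceed) / (n_perm + 1)
}

#' Spatial LR pair score on a kNN graph
#'
#' \code{S = sum_{i in A} sum_{j in B} Lexp_i Rexp_j M_ij -
#' sum_{i in A} sum_{j in B} Rexp_i Lexp_j M_ij} with normalized expression
#' and the binary symmetric adjacency M: directional co-expression of ligand
#' (in senders) and receptor (in receivers) across spatially adjacent beads,
#' minus the swapped term that absorbs admixture leakage. Computed by sparse
#' products.
#'
#' @param puck \linkS4class{SpatialDataset} with a normalized assay
#' @param graph \linkS4class{SpatialGraph} over the same beads
#' @param ligand,receptor gene ids
#' @param type_A,type_B sender and receiver cell types
#' @return the score S
#' @export
lrScoreSpatial <- function(puck, graph, ligand, receptor, type_A, type_B) {
    m <- .getNormalized(puck)
    stopifnot(ligand %in% rownames(m), receptor %in% rownames(m),
              nrow(graph@adjacency) == ncol(m))
    a <- as.numeric(.typeCells(puck, type_A))
    b <- as.numeric(.typeCells(puck, type_B))
    if (!any(a > 0)) stop("type '", type_A, "' not present")
    if (!any(b > 0)) stop("type '", type_B, "' not present")
    L <- as.numeric(m[ligand, ]); R <- as.numeric(m[receptor, ])
    .spatialScoreKernel(L, R, a, b, graph@adjacency)
}

#' Permutation p-value for a spatial LR score
#'
#' The null shuffles bead cell-type labels globally across the puck
#' (expression vectors stay attached to their beads/positions) and
#' recomputes S each round; one-sided upper-tail p with the +1 pseudo-count.
#'
#' @inheritParams lrScoreSpatial
#' @param n_perm permutation rounds, default 2000
#' @param seed integer seed
#' @return list with \code{score}, \code{p}, \code{n_perm}
#' @export
permuteSpatial <- function(puck, graph, ligand, receptor, type_A, type_B,
                           n_perm = 2000, seed = 0) {
    m <- .getNormalized(puck)
    obs <- lrScoreSpatial(puck, graph, ligand, receptor, type_A, type_B)
    lab <- colData(puck)$cell_type
    L <- as.numeric(m[ligand, ]); R <- as.numeric(m[receptor, ])
    e <- .edgeList(graph)
    p <- .withSeed(seed, .permSpatialP(L, R, lab, type_A, type_B,
                                       e$i, e$j, obs, n_perm))
    list(score = obs, p = p, n_perm = n_perm)
}

#' Screen a ligand-receptor table
#'
#' Scores every (pair, ordered sender-receiver type pair) whose ligand and
#' receptor pass the expression filter in their respective types, builds the
#' label-shuffling null (permutation draws are shared across pairs within a
#' round), and BH-adjusts p across all tested rows. Pairs failing the filter
#' are kept in the output with \code{tested = FALSE}.
#'
#' @param dataset \linkS4class{ExpressionDataset} (dissociated mode) or
#'   \linkS4class{SpatialDataset} (spatial mode), with a normalized assay
#' @param lr_table data.frame with columns \code{ligand}, \code{receptor},
#'   \code{pair_id} (see \code{\link{readLRTable}})
#' @param mode \code{"dissociated"} or \code{"spatial"}
#' @param type_pairs data.frame with columns \code{sender}, \code{receiver}:
#'   the ordered type pairs to screen (default: all ordered pairs of
#'   distinct observed types)
#' @param graph \linkS4class{SpatialGraph}, required in spatial mode
#' @param n_perm permutation rounds (default 1000 dissociated, 2000 spatial)
#' @param min_fraction expression-filter cutoff, default 0.10
#' @param seed integer seed
#' @return \linkS4class{DataFrame} sorted by q: \code{pair_id},
#'   \code{ligand}, \code{receptor}, \code{sender_type},
#'   \code{receiver_type}, \code{score}, \code{p}, \code{q},
#'   \code{n_permutations}, \code{tested}
#' @export
runLRScreen <- function(dataset, lr_table,
                        mode = c("dissociated", "spatial"),
                        type_pairs = NULL, graph = NULL, n_perm = NULL,
                        min_fraction = 0.10, seed = 0) {
    mode <- match.arg(mode)
    if (is.null(n_perm)) n_perm <- if (mode == "spatial") 2000 else 1000
    empty <- DataFrame(pair_id = character(), ligand = character(),
                       receptor = character(), sender_type = character(),
                       receiver_type = character(), score = numeric(),
                       p = numeric(), q = numeric(),
                       n_permutations = integer(), tested = logical())
    if (NROW(lr_table) == 0) return(empty)
    if (mode == "spatial" && is.null(graph))
        stop("spatial mode requires a graph")
    m <- .getNormalized(dataset)
    cd <- colData(dataset)
    valid <- if ("annotation_class" %in% colnames(cd))
        cd$annotation_class != "reject" else rep(TRUE, ncol(m))
    lab <- as.character(cd$cell_type)
    types <- sort(unique(lab[valid]))
    if (is.null(type_pairs))
        type_pairs <- expand.grid(sender = types, receiver = types,
                                  stringsAsFactors = FALSE)
    type_pairs <- type_pairs[type_pairs$sender != type_pairs$receiver |
                             mode == "dissociated", , drop = FALSE]

    expressed <- lapply(stats::setNames(types, types), function(tp)
        filterExpressed(dataset, tp, min_fraction))

    rows <- do.call(rbind, lapply(seq_len(nrow(type_pairs)), function(k) {
        data.frame(pair_id = lr_table$pair_id, ligand = lr_table$ligand,
                   receptor = lr_table$receptor,
                   sender_type = type_pairs$sender[k],
                   receiver_type = type_pairs$receiver[k],
                   stringsAsFactors = FALSE)
    }))
    rows$tested <- mapply(function(l, r, s, rc)
        l %in% expressed[[s]] && r %in% expressed[[rc]],
        rows$ligand, rows$receptor, rows$sender_type, rows$receiver_type)

    genes <- unique(c(rows$ligand, rows$receptor))
    genes <- intersect(genes, rownames(m))
    X <- as.matrix(m[genes, , drop = FALSE])
    li <- match(rows$ligand, genes); ri <- match(rows$receptor, genes)
    tested <- which(rows$tested)
    score <- rep(NA_real_, nrow(rows)); p <- rep(NA_real_, nrow(rows))

    if (length(tested)) {
        if (mode == "dissociated") {
            scoreAll <- function(pl) {
                mu <- vapply(types, function(tp)
                    rowMeans(X[, pl == tp & valid, drop = FALSE]),
                    numeric(nrow(X)))
                mu[cbind(li[tested], match(rows$sender_type[tested],
                                           types))] *
                    mu[cbind(ri[tested], match(rows$receiver_type[tested],
                                               types))]
            }
        } else {
            e <- .edgeList(graph)
            ev <- valid[e$i] & valid[e$j]
            ei <- e$i[ev]; ej <- e$j[ev]
            tp_key <- paste(rows$sender_type, rows$receiver_type)
            keys <- unique(tp_key[tested])
            scoreAll <- function(pl) {
                ti <- pl[ei]; tj <- pl[ej]
                out <- numeric(length(tested))
                for (ky in keys) {
                    rws <- tested[tp_key[tested] == ky]
                    pos <- match(rws, tested)
                    ab <- strsplit(ky, " ", fixed = TRUE)[[1]]
                    mk <- ti == ab[1] & tj == ab[2]
                    if (!any(mk)) { out[pos] <- 0; next }
                    ii <- ei[mk]; jj <- ej[mk]
                    out[pos] <- rowSums(X[li[rws], ii, drop = FALSE] *
                                        X[ri[rws], jj, drop = FALSE]) -
                        rowSums(X[ri[rws], ii, drop = FALSE] *
                                X[li[rws], jj, drop = FALSE])
                }
                out
            }
        }
        obs <- scoreAll(lab)
        exceed <- .withSeed(seed, {
            ex <- integer(length(tested))
            for (b in seq_len(n_perm)) {
                pl <- lab
                pl[valid] <- lab[valid][sample.int(sum(valid))]
                ex <- ex + (scoreAll(pl) >= obs)
            }
            ex
        })
        score[tested] <- obs
        p[tested] <- (1 + exceed) / (n_perm + 1)
    }
    q <- rep(NA_real_, nrow(rows))
    q[tested] <- stats::p.adjust(p[tested], method = "BH")
    out <- DataFrame(rows[c("pair_id", "ligand", "receptor", "sender_type",
                            "receiver_type")],
                     score = score, p = p, q = q,
                     n_permutations = ifelse(rows$tested, n_perm, 0L),
                     tested = rows$tested)
    out[order(!out$tested, out$q, out$p), , drop = FALSE]
}
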