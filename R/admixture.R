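## Admixture-corrected context-dependent differential expression:
## pseudo-bulk aggregation, the constrained (non-negative) linear-regression
## admixture fit, count-space subtraction of the contaminant component, and a
## self-contained pseudo-bulk negative-binomial test (moment dispersion
## shrunk toward a common value, Wald statistic on a t reference) used for
## both spatial context DE and scRNA fraction DE.

#' Pseudo-bulk profiles of one cell type per unit
#'
#' Exact integer column sums over the members of \code{cell_type} within
#' each unit. For spatial data only singlet / doublet-certain beads
#' contribute. Units with no members are omitted with a warning.
#'
#' @param dataset \linkS4class{ExpressionDataset} or
#'   \linkS4class{SpatialDataset}
#' @param unit_assignment per-column unit id (context, sample or tile);
#'   \code{NA} columns are ignored
#' @param cell_type the cell type to aggregate
#' @return a \linkS4class{PseudobulkSet}
#' @export
pseudobulk <- function(dataset, unit_assignment, cell_type) {
    m <- .getCounts(dataset)
    cd <- colData(dataset)
    unit_assignment <- as.character(unit_assignment)
    stopifnot(length(unit_assignment) == ncol(m))
    sel <- !is.na(unit_assignment) & cd$cell_type == cell_type
    if ("annotation_class" %in% colnames(cd))
        sel <- sel & cd$annotation_class != "reject"
    units <- unique(unit_assignment[!is.na(unit_assignment)])
    keep <- vapply(units, function(u) any(sel & unit_assignment == u),
                   logical(1))
    if (any(!keep))
        warning("unit(s) with no members omitted: ",
                paste(units[!keep], collapse = ", "))
    units <- units[keep]
    if (!length(units)) stop("no unit has any member of '", cell_type, "'")
    counts <- vapply(units, function(u)
        as.numeric(Matrix::rowSums(m[, sel & unit_assignment == u,
                                     drop = FALSE])),
        numeric(nrow(m)))
    rownames(counts) <- rownames(m)
    methods::new("PseudobulkSet", counts = counts,
                 n_members = vapply(units, function(u)
                     as.integer(sum(sel & unit_assignment == u)),
                     integer(1)),
                 cell_type = cell_type)
}

#' Assign beads to spatial tiles
#'
#' Splits the puck's bounding box into an \code{nx} x \code{ny} grid of
#' equal-area tiles — the replicate fallback when only one puck per
#' condition is available.
#'
#' @param spatial a \linkS4class{SpatialDataset}
#' @param nx,ny tiles per axis (default 2 x 2)
#' @return character vector of tile ids per bead
#' @export
tilePuck <- function(spatial, nx = 2, ny = 2) {
    co <- beadCoords(spatial)
    ix <- pmin(1L + floor(nx * (co[, 1] - min(co[, 1])) /
                          (diff(range(co[, 1])) + 1e-9)), nx)
    iy <- pmin(1L + floor(ny * (co[, 2] - min(co[, 2])) /
                          (diff(range(co[, 2])) + 1e-9)), ny)
    sprintf("tile_%d_%d", ix, iy)
}

#' Constrained linear-regression admixture fit
#'
#' Solves \eqn{\min_{w \ge 0} \|y - Pw\|_2} where \eqn{y} is the observed
#' pseudo-bulk profile normalized to sum 1 and the columns of \eqn{P} are
#' the normalized reference profiles of the target type and its candidate
#' contaminants (Lawson-Hanson NNLS). Weights are reported normalized to
#' sum 1. An ill-conditioned design (condition number above
#' \code{condition_cap}) triggers a warning and a ridge-regularized
#' fallback, flagged in the fit.
#'
#' @param target_profile observed gene vector (counts or proportions) of the
#'   target type's pseudo-bulk; names must match the reference rows
#' @param reference_profiles genes x types matrix of reference profiles,
#'   including a column for the target type itself
#' @param target_type column name of the target's own reference
#' @param condition_cap documented conditioning cap, default 1e8
#' @param ridge_lambda ridge penalty used by the fallback, default 1e-4
#' @return an \linkS4class{AdmixtureFit}
#' @export
estimateAdmixture <- function(target_profile, reference_profiles,
                              target_type, condition_cap = 1e8,
                              ridge_lambda = 1e-4) {
    P <- as.matrix(reference_profiles)
    stopifnot(target_type %in% colnames(P), ncol(P) >= 2,
              length(target_profile) == nrow(P))
    P <- sweep(P, 2, colSums(P), "/")
    y <- as.numeric(target_profile)
    stopifnot(sum(y) > 0)
    y <- y / sum(y)
    cond <- kappa(P, exact = TRUE)
    ridged <- is.finite(cond) && cond > condition_cap || !is.finite(cond)
    if (ridged) {
        warning(sprintf(
            "ill-conditioned design (condition number %.3g > %.3g); %s",
            cond, condition_cap, "using ridge-regularized fallback"))
        Paug <- rbind(P, sqrt(ridge_lambda) * diag(ncol(P)))
        w <- pracma::lsqnonneg(Paug, c(y, numeric(ncol(P))))$x
    } else {
        w <- pracma::lsqnonneg(P, y)$x
    }
    names(w) <- colnames(P)
    resid <- sqrt(sum((y - P %*% w)^2))
    if (sum(w) == 0) w[target_type] <- 1
    methods::new("AdmixtureFit", target_type = target_type,
                 weights = w / sum(w), references = P,
                 residual_norm = resid, condition_number = cond,
                 ridged = ridged)
}

#' Subtract the estimated contaminant component from a profile
#'
#' \code{corrected = observed - sum_k w_k * depth * P_k} over the
#' contaminant types only (the target's own component is retained), floored
#' at zero elementwise and rounded to integers for count-model
#' compatibility. With all contaminant weights zero this is the identity.
#'
#' @param observed raw count vector of the target pseudo-bulk (same gene
#'   universe as the fit)
#' @param fit an \linkS4class{AdmixtureFit}
#' @return corrected integer gene vector
#' @export
correctProfile <- function(observed, fit) {
    stopifnot(methods::is(fit, "AdmixtureFit"),
              length(observed) == nrow(fit@references))
    w <- fit@weights
    contam <- setdiff(names(w), fit@target_type)
    pred <- as.vector(fit@references[, contam, drop = FALSE] %*% w[contam]) *
        sum(observed)
    out <- round(pmax(as.numeric(observed) - pred, 0))
    names(out) <- names(observed)
    out
}

## ---------------------------------------------------------------------------
## Self-contained pseudo-bulk NB test
## ---------------------------------------------------------------------------

## counts: genes x samples integer matrix; group: 2-level factor.
## Per-gene NB Wald test at moment dispersion shrunk toward the common
## dispersion, offsets = log library size, p from a moderated t reference
## whose df is residual df + dispersion prior df (the shrunken dispersion
## carries information worth prior_df extra df, as in moderated-statistic
## pipelines). Returns DataFrame(gene, log2fc, p, q).
.nbTest <- function(counts, group, prior_df = 10) {
    counts <- as.matrix(counts)
    group <- droplevels(as.factor(group))
    stopifnot(nlevels(group) == 2, ncol(counts) == length(group))
    n <- ncol(counts)
    df_resid <- n - 2
    stopifnot(df_resid >= 1)
    N <- colSums(counts)
    stopifnot(all(N > 0))
    y <- sweep(counts, 2, mean(N) / N, "*")
    g2 <- group == levels(group)[2]

    ## moment dispersions, pooled within group
    m1 <- rowMeans(y[, !g2, drop = FALSE]); m2 <- rowMeans(y[, g2, drop = FALSE])
    v1 <- apply(y[, !g2, drop = FALSE], 1, stats::var)
    v2 <- apply(y[, g2, drop = FALSE], 1, stats::var)
    n1 <- sum(!g2); n2 <- sum(g2)
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    mbar <- (n1 * m1 + n2 * m2) / n
    phi_hat <- pmin(pmax((s2 - mbar) / mbar^2, 0), 10)
    ok <- is.finite(phi_hat) & mbar >= 1
    phi0 <- if (any(ok)) stats::median(phi_hat[ok]) else 0.1
    phi <- pmax((prior_df * phi0 + df_resid *
                 ifelse(is.finite(phi_hat), phi_hat, phi0)) /
                (prior_df + df_resid), 1e-8)

    X <- cbind(1, as.numeric(g2))
    off <- log(N)
    lfc <- numeric(nrow(counts)); p <- rep(1, nrow(counts))
    for (g in seq_len(nrow(counts))) {
        cg <- counts[g, ]
        if (all(cg == 0)) next
        fam <- MASS::negative.binomial(theta = 1 / phi[g])
        fit <- tryCatch(
            suppressWarnings(stats::glm.fit(X, cg, offset = off,
                                            family = fam,
                                            control = list(maxit = 50))),
            error = function(e) NULL)
        if (is.null(fit) || anyNA(fit$coefficients)) next
        Rinv <- tryCatch(chol2inv(qr.R(fit$qr)), error = function(e) NULL)
        if (is.null(Rinv)) next
        se <- sqrt(Rinv[2, 2])
        beta <- fit$coefficients[2]
        lfc[g] <- beta / log(2)
        if (se > 0)
            p[g] <- 2 * stats::pt(-abs(beta / se),
                                  df = df_resid + prior_df)
    }
    DataFrame(gene = rownames(counts), log2fc = lfc, p = p,
              q = stats::p.adjust(p, method = "BH"))
}

#' Context-dependent differential expression on pseudo-bulk profiles
#'
#' Per-gene negative-binomial test of tumor context vs adjacent context on
#' (admixture-corrected) pseudo-bulk replicate profiles: total-count
#' normalization, tagwise moment dispersion shrunk toward the common
#' dispersion, Wald-type test on the log2 fold change with a small-sample t
#' reference, BH adjustment. Replicates are pucks, or disjoint spatial tiles
#' of one puck (see \code{\link{tilePuck}}).
#'
#' @param counts genes x replicates matrix of pseudo-bulk counts (both
#'   contexts' replicates as columns)
#' @param contexts per-column context label (exactly two levels, >= 2
#'   replicates each)
#' @param prior_df prior degrees of freedom for dispersion shrinkage
#' @return \linkS4class{DataFrame}: \code{gene}, \code{log2fc} (second level
#'   vs first), \code{p}, \code{q}
#' @export
contextDE <- function(counts, contexts, prior_df = 10) {
    contexts <- droplevels(as.factor(contexts))
    if (nlevels(contexts) != 2)
        stop("contexts must have exactly 2 levels")
    if (any(table(contexts) < 2))
        stop("need >= 2 replicate profiles per context; with a single puck, ",
             "use tilePuck() to form spatial tile replicates")
    .nbTest(counts, contexts, prior_df = prior_df)
}

#' Fraction-level differential expression from scRNA-seq data
#'
#' Per-sample pseudo-bulk profiles of one cell type are compared between two
#' sample fractions with the same negative-binomial test as
#' \code{\link{contextDE}}. Samples contributing fewer than \code{min_cells}
#' cells of the type are excluded.
#'
#' @param dataset an \linkS4class{ExpressionDataset}
#' @param cell_type the cell type to test
#' @param fraction_A,fraction_B the two fractions to compare (log2fc is
#'   \code{fraction_B} vs \code{fraction_A})
#' @param min_cells minimum cells of the type per sample, default 10
#' @param prior_df dispersion shrinkage prior df
#' @return \linkS4class{DataFrame} as in \code{\link{contextDE}}
#' @export
fractionDE <- function(dataset, cell_type, fraction_A, fraction_B,
                       min_cells = 10, prior_df = 10) {
    cd <- colData(dataset)
    stopifnot(all(c(fraction_A, fraction_B) %in% cd$fraction))
    unit <- ifelse(cd$fraction %in% c(fraction_A, fraction_B) &
                   cd$cell_type == cell_type, cd$sample_id, NA)
    pb <- suppressWarnings(pseudobulk(dataset, unit, cell_type))
    keep <- pb@n_members >= min_cells
    excluded <- colnames(pb@counts)[!keep]
    if (length(excluded))
        message("excluded sample(s) with < ", min_cells, " cells of '",
                cell_type, "': ", paste(excluded, collapse = ", "))
    counts <- pb@counts[, keep, drop = FALSE]
    samp_frac <- cd$fraction[match(colnames(counts), cd$sample_id)]
    nA <- sum(samp_frac == fraction_A); nB <- sum(samp_frac == fraction_B)
    if (nA < 2 || nB < 2)
        stop(sprintf(
            "need >= 2 surviving samples per fraction (have %d vs %d)%s",
            nA, nB,
            if (length(excluded)) paste0("; excluded: ",
                                         paste(excluded, collapse = ", "))
            else ""))
    .nbTest(counts, factor(samp_frac, levels = c(fraction_A, fraction_B)),
            prior_df = prior_df)
}
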