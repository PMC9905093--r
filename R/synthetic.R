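## Synthetic-data generators: NB scRNA-seq with planted markers and
## fraction-level effects, spatial pucks with proximity-weighted admixture and
## planted context effects / co-localized LR pairs, and bulk tumor/normal
## cohorts as noisy mixtures of cell-type profiles. Every generator is
## bit-reproducible under a fixed seed and returns its ground truth.

## Run expr under a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## NB(mu, phi) with variance mu + phi mu^2; phi = 0 degenerates to Poisson.
.rnb <- function(n, mu, phi) {
    phi <- rep_len(phi, n)
    mu <- rep_len(mu, n)
    out <- integer(n)
    pois <- phi <= 0
    if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
    if (any(!pois)) out[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                                 size = 1 / phi[!pois])
    out
}

#' Simulate per-type reference expression profiles
#'
#' Per-gene baseline means are drawn log-normally around \code{base_mean} and
#' shared across types; each type receives \code{n_markers_per_type} marker
#' genes whose mean is multiplied by \code{marker_fold} in that type only.
#'
#' @param n_genes,n_types problem size
#' @param n_markers_per_type markers per type (disjoint across types)
#' @param marker_fold fold enrichment of a marker in its own type (> 1 for
#'   distinguishable markers; 1 makes all types identical)
#' @param base_mean median baseline mean expression
#' @param dispersion NB dispersion phi, scalar or per gene
#' @param seed integer seed
#' @return a \linkS4class{CellTypeProfiles}
#' @export
simulateProfiles <- function(n_genes, n_types, n_markers_per_type = 10,
                             marker_fold = 4, base_mean = 1, dispersion = 0.1,
                             seed = 0) {
    stopifnot(n_genes >= 1, n_types >= 1, base_mean > 0, marker_fold >= 1)
    if (n_markers_per_type * n_types > n_genes)
        stop("n_markers_per_type * n_types exceeds n_genes")
    .withSeed(seed, {
        genes <- sprintf("gene%04d", seq_len(n_genes))
        types <- sprintf("type%d", seq_len(n_types))
        base <- stats::rlnorm(n_genes, meanlog = log(base_mean), sdlog = 0.5)
        means <- matrix(base, n_genes, n_types,
                        dimnames = list(genes, types))
        markers <- rep(list(character()), n_types)
        names(markers) <- types
        if (n_markers_per_type > 0) {
            idx <- matrix(seq_len(n_markers_per_type * n_types),
                          nrow = n_markers_per_type)
            for (t in seq_len(n_types)) {
                mg <- idx[, t]
                means[mg, t] <- means[mg, t] * marker_fold
                markers[[t]] <- genes[mg]
            }
        }
        methods::new("CellTypeProfiles", means = means, markers = markers,
                     marker_fold = marker_fold,
                     dispersion = rep_len(dispersion, n_genes))
    })
}

.empty_truth <- function(seed, n_types = 0L, type_names = character()) {
    methods::new("SimulationTruth",
                 planted_de = data.frame(gene = character(),
                                         cell_type = character(),
                                         condition = character(),
                                         log2fc = numeric()),
                 admixture_weights = matrix(numeric(), 0, n_types,
                                            dimnames = list(NULL, type_names)),
                 planted_lr = data.frame(ligand = character(),
                                         receptor = character(),
                                         sender_type = character(),
                                         receiver_type = character(),
                                         strength = numeric()),
                 seed = as.integer(seed))
}

.check_planted <- function(planted, profiles, conditions, cond_name) {
    if (is.null(planted) || nrow(planted) == 0) {
        return(data.frame(gene = character(), cell_type = character(),
                          condition = character(), log2fc = numeric()))
    }
    planted <- as.data.frame(planted)
    names(planted)[names(planted) == cond_name] <- "condition"
    stopifnot(all(c("gene", "cell_type", "condition", "log2fc") %in%
                  names(planted)))
    if (!all(planted$gene %in% rownames(profiles@means)))
        stop("planted effect references unknown gene(s)")
    if (!all(planted$cell_type %in% colnames(profiles@means)))
        stop("planted effect references unknown cell type(s)")
    if (!all(planted$condition %in% conditions))
        stop("planted effect references unknown ", cond_name, "(s): ",
             paste(setdiff(planted$condition, conditions), collapse = ", "))
    if (!all(is.finite(planted$log2fc))) stop("log2fc must be finite")
    planted[c("gene", "cell_type", "condition", "log2fc")]
}

#' Simulate a multi-sample dissociated scRNA-seq dataset
#'
#' Counts are NB(mean = library size x type profile x planted fold x
#' per-sample effect, dispersion phi). Defaults mirror a multi-donor prostate
#' cohort design: 5 healthy, 14 adjacent-normal and 17 tumor samples.
#'
#' @param profiles a \linkS4class{CellTypeProfiles}
#' @param samples_per_fraction named integer vector over
#'   \code{healthy}/\code{adj_normal}/\code{tumor}
#' @param cells_per_sample cells simulated per sample
#' @param lib_meanlog,lib_sdlog log-normal library-size parameters
#' @param planted_effects optional data.frame (gene, cell_type, fraction,
#'   log2fc): multiplies the type profile by 2^log2fc for cells of that type
#'   in that fraction
#' @param type_props optional named composition over cell types (default
#'   uniform)
#' @param sample_effect_sd per-fraction (or scalar) sd of a log-normal
#'   per-sample, per-gene random effect — inter-individual variability
#' @param malignant_types cell types flagged \code{malignant = TRUE}
#' @param seed integer seed
#' @return \code{list(dataset = ExpressionDataset, truth = SimulationTruth)}
#' @export
simulateScrna <- function(profiles,
                          samples_per_fraction = c(healthy = 5,
                                                   adj_normal = 14,
                                                   tumor = 17),
                          cells_per_sample = 200,
                          lib_meanlog = log(2000), lib_sdlog = 0.4,
                          planted_effects = NULL, type_props = NULL,
                          sample_effect_sd = 0.1,
                          malignant_types = character(), seed = 0) {
    stopifnot(methods::is(profiles, "CellTypeProfiles"))
    if (!all(names(samples_per_fraction) %in% .FRACTIONS))
        stop("invalid fraction name(s): ",
             paste(setdiff(names(samples_per_fraction), .FRACTIONS),
                   collapse = ", "))
    types <- colnames(profiles@means)
    n_genes <- nrow(profiles@means)
    planted <- .check_planted(planted_effects, profiles, .FRACTIONS,
                              "fraction")
    if (is.null(type_props))
        type_props <- stats::setNames(rep(1 / length(types), length(types)),
                                      types)
    stopifnot(all(names(type_props) %in% types))
    sfx <- names(samples_per_fraction)
    eff_sd <- if (is.null(names(sample_effect_sd)))
        stats::setNames(rep_len(sample_effect_sd, length(sfx)), sfx)
    else sample_effect_sd

    .withSeed(seed, {
        sample_ids <- unlist(lapply(sfx, function(f)
            sprintf("%s_s%02d", f, seq_len(samples_per_fraction[[f]]))))
        sample_fraction <- rep(sfx, times = unlist(samples_per_fraction))
        n_cells <- length(sample_ids) * cells_per_sample
        cell_sample <- rep(sample_ids, each = cells_per_sample)
        cell_fraction <- rep(sample_fraction, each = cells_per_sample)
        cell_type <- sample(names(type_props), n_cells, replace = TRUE,
                            prob = type_props)
        lib <- stats::rlnorm(n_cells, lib_meanlog, lib_sdlog)

        ## per-sample multiplicative gene effects (inter-individual noise)
        samp_eff <- vapply(seq_along(sample_ids), function(i) {
            s <- eff_sd[[sample_fraction[i]]]
            if (s <= 0) rep(1, n_genes)
            else stats::rlnorm(n_genes, -s^2 / 2, s)
        }, numeric(n_genes))
        colnames(samp_eff) <- sample_ids

        ## per-(type, fraction) planted fold matrix applied to the profile
        mu <- matrix(0, n_genes, n_cells,
                     dimnames = list(rownames(profiles@means), NULL))
        for (f in unique(cell_fraction)) {
            for (tp in unique(cell_type)) {
                sel <- which(cell_fraction == f & cell_type == tp)
                if (!length(sel)) next
                prof <- profiles@means[, tp]
                pl <- planted[planted$condition == f &
                              planted$cell_type == tp, ]
                if (nrow(pl))
                    prof[pl$gene] <- prof[pl$gene] * 2^pl$log2fc
                rel <- prof * samp_eff[, cell_sample[sel], drop = FALSE]
                rel <- sweep(rel, 2, colSums(rel), "/")
                mu[, sel] <- sweep(rel, 2, lib[sel], "*")
            }
        }
        counts <- matrix(.rnb(length(mu), as.vector(mu),
                              rep(profiles@dispersion, n_cells)),
                         n_genes, n_cells,
                         dimnames = list(rownames(profiles@means),
                                         sprintf("cell_%06d",
                                                 seq_len(n_cells))))
        ds <- ExpressionDataset(counts, sample_id = cell_sample,
                                fraction = cell_fraction,
                                cell_type = cell_type,
                                malignant = cell_type %in% malignant_types,
                                doublet_score = stats::runif(n_cells, 0, 0.3))
        truth <- .empty_truth(seed, length(types), types)
        truth@planted_de <- planted
        list(dataset = ds, truth = truth)
    })
}

#' Simulate a Slide-seq-style spatial puck with bead admixture
#'
#' Beads are laid on a jittered hexagonal grid (default 20 um spacing,
#' mimicking ~10 um beads) or a spatial Poisson process. Each bead gets a
#' dominant cell type from its domain's composition; its expected expression
#' is \code{self_weight} x own-type profile plus the remaining mass spread
#' over neighboring beads' type profiles with Gaussian distance weights
#' (bandwidth in microns, truncated at 3 bandwidths). Context-specific
#' effects modify the target type's own profile inside designated domains
#' only; planted LR pairs boost ligand expression in sender-type beads with a
#' receiver-type bead within one bandwidth, and receptor expression in those
#' receivers.
#'
#' @param profiles a \linkS4class{CellTypeProfiles}
#' @param domains list of domains, each
#'   \code{list(name =, region = c(xmin, xmax, ymin, ymax), composition =
#'   named probability vector over cell types)}; together they must cover
#'   every bead and each must contain at least one bead
#' @param width,height puck extent in microns
#' @param spacing bead grid spacing (um); \code{jitter} is the uniform
#'   positional jitter as a fraction of spacing
#' @param layout \code{"hex"} grid or \code{"poisson"} (intensity matched to
#'   the grid density)
#' @param bandwidth Gaussian admixture kernel bandwidth (um)
#' @param self_weight fraction of a bead's expression from its own cell,
#'   in (0, 1]
#' @param planted_context_de data.frame (gene, cell_type, domain, log2fc)
#' @param planted_lr data.frame (ligand, receptor, sender_type,
#'   receiver_type, strength)
#' @param umi_per_bead median bead depth; \code{lib_sdlog} its log-normal sd
#' @param doublet_certain_rate,reject_rate fractions of beads labeled
#'   \code{doublet_certain} / \code{reject}
#' @param seed integer seed
#' @return \code{list(dataset = SpatialDataset, truth = SimulationTruth)};
#'   bead domain names are kept in \code{colData(dataset)$domain} and the
#'   per-bead type mixing weights in \code{truth@admixture_weights}
#' @export
simulatePuck <- function(profiles, domains = NULL, width = 600, height = 600,
                         spacing = 20, jitter = 0.3, layout = c("hex",
                                                                "poisson"),
                         bandwidth = 30, self_weight = 0.7,
                         planted_context_de = NULL, planted_lr = NULL,
                         umi_per_bead = 500, lib_sdlog = 0.3,
                         doublet_certain_rate = 0.1, reject_rate = 0.05,
                         seed = 0) {
    stopifnot(methods::is(profiles, "CellTypeProfiles"),
              self_weight > 0, self_weight <= 1)
    layout <- match.arg(layout)
    types <- colnames(profiles@means)
    n_genes <- nrow(profiles@means)
    if (is.null(domains))
        domains <- list(list(name = "all",
                             region = c(0, width, 0, height),
                             composition = stats::setNames(
                                 rep(1 / length(types), length(types)),
                                 types)))
    dom_names <- vapply(domains, `[[`, character(1), "name")
    planted <- .check_planted(planted_context_de, profiles, dom_names,
                              "domain")
    plr <- if (is.null(planted_lr) || NROW(planted_lr) == 0)
        .empty_truth(0L)@planted_lr
    else {
        plr <- as.data.frame(planted_lr)
        stopifnot(all(c("ligand", "receptor", "sender_type", "receiver_type",
                        "strength") %in% names(plr)),
                  all(c(plr$ligand, plr$receptor) %in%
                      rownames(profiles@means)),
                  all(c(plr$sender_type, plr$receiver_type) %in% types))
        plr
    }

    .withSeed(seed, {
        ## bead layout
        if (layout == "hex") {
            ys <- seq(spacing / 2, height, by = spacing * sqrt(3) / 2)
            pts <- do.call(rbind, lapply(seq_along(ys), function(r) {
                off <- if (r %% 2 == 0) spacing / 2 else 0
                xs <- seq(spacing / 2 + off, width, by = spacing)
                cbind(xs, ys[r])
            }))
            pts <- pts + matrix(stats::runif(length(pts), -jitter * spacing,
                                             jitter * spacing), ncol = 2)
            pts[, 1] <- pmin(pmax(pts[, 1], 0), width)
            pts[, 2] <- pmin(pmax(pts[, 2], 0), height)
        } else {
            n <- stats::rpois(1, width * height / (spacing^2 * sqrt(3) / 2))
            pts <- cbind(stats::runif(n, 0, width), stats::runif(n, 0, height))
        }
        n_beads <- nrow(pts)

        ## domain membership (first matching region wins)
        bead_dom <- rep(NA_integer_, n_beads)
        for (d in seq_along(domains)) {
            r <- domains[[d]]$region
            hit <- is.na(bead_dom) & pts[, 1] >= r[1] & pts[, 1] <= r[2] &
                pts[, 2] >= r[3] & pts[, 2] <= r[4]
            bead_dom[hit] <- d
        }
        if (anyNA(bead_dom))
            stop("domains do not cover the full puck region")
        if (!all(seq_along(domains) %in% bead_dom))
            stop("empty domain: ",
                 paste(dom_names[setdiff(seq_along(domains),
                                         unique(bead_dom))], collapse = ", "))

        bead_type <- character(n_beads)
        for (d in seq_along(domains)) {
            comp <- domains[[d]]$composition
            stopifnot(abs(sum(comp) - 1) < 1e-6,
                      all(names(comp) %in% types))
            sel <- bead_dom == d
            bead_type[sel] <- sample(names(comp), sum(sel), replace = TRUE,
                                     prob = comp)
        }

        ## admixture weights over types: Gaussian kernel, truncated at 3h
        D <- as.matrix(stats::dist(pts))
        K <- exp(-D^2 / (2 * bandwidth^2))
        K[D > 3 * bandwidth | D == 0] <- 0
        type_idx <- match(bead_type, types)
        W <- matrix(0, n_beads, length(types),
                    dimnames = list(NULL, types))
        ksum <- rowSums(K)
        for (i in seq_len(n_beads)) {
            W[i, type_idx[i]] <- W[i, type_idx[i]] + self_weight
            if (ksum[i] > 0) {
                share <- (1 - self_weight) * K[i, ] / ksum[i]
                for (tt in seq_along(types)) {
                    sel <- type_idx == tt
                    W[i, tt] <- W[i, tt] + sum(share[sel])
                }
            } else W[i, type_idx[i]] <- 1
        }

        ## per-domain (context) profile matrices with planted effects
        dom_prof <- lapply(seq_along(domains), function(d) {
            P <- profiles@means
            pl <- planted[planted$condition == dom_names[d], ]
            for (k in seq_len(nrow(pl)))
                P[pl$gene[k], pl$cell_type[k]] <-
                    P[pl$gene[k], pl$cell_type[k]] * 2^pl$log2fc[k]
            P
        })

        ## expected relative expression per bead
        rel <- matrix(0, n_genes, n_beads,
                      dimnames = list(rownames(profiles@means), NULL))
        for (i in seq_len(n_beads))
            rel[, i] <- dom_prof[[bead_dom[i]]] %*% W[i, ]

        ## planted LR boosts conditional on spatial adjacency
        for (k in seq_len(nrow(plr))) {
            near <- D <= bandwidth & D > 0
            senders <- which(bead_type == plr$sender_type[k] &
                             rowSums(near[, bead_type ==
                                            plr$receiver_type[k],
                                          drop = FALSE]) > 0)
            receivers <- which(bead_type == plr$receiver_type[k] &
                               rowSums(near[, bead_type ==
                                              plr$sender_type[k],
                                            drop = FALSE]) > 0)
            rel[plr$ligand[k], senders] <-
                rel[plr$ligand[k], senders] * plr$strength[k]
            rel[plr$receptor[k], receivers] <-
                rel[plr$receptor[k], receivers] * plr$strength[k]
        }

        depth <- stats::rlnorm(n_beads, log(umi_per_bead), lib_sdlog)
        mu <- sweep(sweep(rel, 2, colSums(rel), "/"), 2, depth, "*")
        counts <- matrix(.rnb(length(mu), as.vector(mu),
                              rep(profiles@dispersion, n_beads)),
                         n_genes, n_beads,
                         dimnames = list(rownames(profiles@means),
                                         sprintf("bead_%05d",
                                                 seq_len(n_beads))))
        ann <- sample(c("singlet", "doublet_certain", "reject"), n_beads,
                      replace = TRUE,
                      prob = c(1 - doublet_certain_rate - reject_rate,
                               doublet_certain_rate, reject_rate))
        ds <- SpatialDataset(counts, x = pts[, 1], y = pts[, 2],
                             cell_type = bead_type, annotation_class = ann,
                             extra = DataFrame(domain = dom_names[bead_dom]))
        truth <- .empty_truth(seed, length(types), types)
        truth@planted_de <- planted
        truth@planted_lr <- plr
        truth@admixture_weights <- W
        list(dataset = ds, truth = truth)
    })
}

#' Simulate a bulk tumor/normal expression cohort
#'
#' Each sample is a composition-weighted sum of the cell-type mean profiles,
#' multiplied by per-gene log-normal noise — the structure of the public
#' bulk cohorts used to validate compact tumor signatures.
#'
#' @param profiles a \linkS4class{CellTypeProfiles}
#' @param n_tumor,n_normal samples per class
#' @param comp_tumor,comp_normal named probability vectors over cell types
#'   (must sum to 1 within 1e-8)
#' @param noise_sd sd of the log-normal multiplicative noise (0 = noiseless)
#' @param seed integer seed
#' @return \code{list(expr = genes x samples matrix, labels = factor
#'   tumor/normal, truth = SimulationTruth)}
#' @export
simulateBulkCohort <- function(profiles, n_tumor, n_normal, comp_tumor,
                               comp_normal, noise_sd = 0.2, seed = 0) {
    stopifnot(methods::is(profiles, "CellTypeProfiles"))
    types <- colnames(profiles@means)
    for (comp in list(comp_tumor, comp_normal)) {
        if (abs(sum(comp) - 1) > 1e-8)
            stop("composition does not sum to 1")
        stopifnot(all(names(comp) %in% types), all(comp >= 0))
    }
    .withSeed(seed, {
        n_genes <- nrow(profiles@means)
        base <- function(comp) {
            v <- numeric(length(types))
            names(v) <- types
            v[names(comp)] <- comp
            as.vector(profiles@means %*% v)
        }
        one <- function(comp) base(comp) *
            if (noise_sd > 0) stats::rlnorm(n_genes, -noise_sd^2 / 2,
                                            noise_sd) else 1
        expr <- cbind(
            vapply(seq_len(n_tumor), function(i) one(comp_tumor),
                   numeric(n_genes)),
            vapply(seq_len(n_normal), function(i) one(comp_normal),
                   numeric(n_genes)))
        dimnames(expr) <- list(rownames(profiles@means),
                               c(sprintf("tumor_%02d", seq_len(n_tumor)),
                                 sprintf("normal_%02d", seq_len(n_normal))))
        labels <- factor(rep(c("tumor", "normal"), c(n_tumor, n_normal)),
                         levels = c("normal", "tumor"))
        list(expr = expr, labels = labels,
             truth = .empty_truth(seed, length(types), types))
    })
}
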