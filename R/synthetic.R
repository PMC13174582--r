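# Seeded synthetic-data generators. Every generator is a pure function of
# (configuration, seed) and returns, next to the data, a `truth` list carrying
# the planted ground truth needed to score recovery tests.

#' Simulate cell positions in a lane
#'
#' Seeded spatial point process inside the lane rectangle (cells keep a margin
#' of one radius from the walls). `"uniform"` draws a Poisson number of
#' uniformly placed cells (or exactly `n_cells` when given); `"clustered"` is
#' a Thomas process: Poisson-distributed parents with Gaussian-scattered
#' offspring, emulating non-uniform loading.
#'
#' @param layout A `lane_layout`.
#' @param n_cells Exact number of cells; overrides `density_per_mm2`.
#' @param density_per_mm2 Expected cell density (cells per mm^2).
#' @param spatial_mode `"uniform"` or `"clustered"`.
#' @param parent_density_per_mm2,cluster_sd_um Thomas-process parameters:
#'   expected parent density and offspring scatter SD.
#' @param radius_um Cell radius (single value or sampled mean; default 8).
#' @param cell_types,type_probs Optional ground-truth type labels sampled per
#'   cell.
#' @param seed Integer seed.
#' @return A cell record data frame (with `truth_type` when types given).
#' @export
simulate_lane_sample <- function(layout, n_cells = NULL,
                                 density_per_mm2 = 75,
                                 spatial_mode = c("uniform", "clustered"),
                                 parent_density_per_mm2 = 2,
                                 cluster_sd_um = 60, radius_um = 8,
                                 cell_types = NULL, type_probs = NULL,
                                 seed = 1L) {
  spatial_mode <- match.arg(spatial_mode)
  area_mm2 <- layout$width_um * layout$height_um / 1e6
  with_seed(seed, {
    if (spatial_mode == "uniform") {
      n <- if (!is.null(n_cells)) n_cells else
        stats::rpois(1, density_per_mm2 * area_mm2)
      x <- stats::runif(n, radius_um, layout$width_um - radius_um)
      y <- stats::runif(n, radius_um, layout$height_um - radius_um)
    } else {
      n_par <- stats::rpois(1, parent_density_per_mm2 * area_mm2)
      mean_total <- if (!is.null(n_cells)) n_cells else
        density_per_mm2 * area_mm2
      per_parent <- if (n_par > 0) mean_total / n_par else 0
      xs <- list(); ys <- list()
      if (n_par > 0) {
        pxc <- stats::runif(n_par, 0, layout$width_um)
        pyc <- stats::runif(n_par, 0, layout$height_um)
        for (p in seq_len(n_par)) {
          m <- stats::rpois(1, per_parent)
          if (m == 0) next
          xs[[length(xs) + 1]] <- stats::rnorm(m, pxc[p], cluster_sd_um)
          ys[[length(ys) + 1]] <- stats::rnorm(m, pyc[p], cluster_sd_um)
        }
      }
      x <- unlist(xs) %||% numeric(0); y <- unlist(ys) %||% numeric(0)
      keep <- x >= radius_um & x <= layout$width_um - radius_um &
        y >= radius_um & y <= layout$height_um - radius_um
      x <- x[keep]; y <- y[keep]
    }
    tt <- if (!is.null(cell_types))
      sample(cell_types, length(x), replace = TRUE, prob = type_probs)
    cell_records(x, y, radius_um = radius_um, truth_type = tt)
  })
}

#' Build per-type expression programs for count simulation
#'
#' Gene-by-type matrix of relative expression. Each type gets
#' `n_markers_per_type` disjoint marker genes upweighted `marker_fold`-fold
#' over a shared lognormal baseline; the first `n_mito` genes are flagged
#' mitochondrial (named `MT-*`) and rescaled so they make up `mito_fraction`
#' of every program.
#'
#' @param n_genes,types,n_markers_per_type,marker_fold,n_mito,mito_fraction
#'   Program shape parameters.
#' @param seed Integer seed.
#' @return List: `programs` (genes x types, columns sum to 1),
#'   `gene_annotations` (data frame: `gene`, `species`, `mito`),
#'   `markers` (list of marker genes per type).
#' @export
simulate_programs <- function(n_genes = 200, types = c("typeA", "typeB"),
                              n_markers_per_type = 10, marker_fold = 20,
                              n_mito = 5, mito_fraction = 0.05, seed = 1L) {
  stopifnot(n_mito + n_markers_per_type * length(types) <= n_genes)
  with_seed(seed, {
    genes <- c(sprintf("MT-G%03d", seq_len(n_mito)),
               sprintf("GENE%04d", seq_len(n_genes - n_mito)))
    mito <- seq_len(n_mito)
    base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    programs <- matrix(base, n_genes, length(types),
                       dimnames = list(genes, types))
    markers <- list()
    nonmito <- setdiff(seq_len(n_genes), mito)
    for (t in seq_along(types)) {
      mk <- nonmito[(t - 1) * n_markers_per_type + seq_len(n_markers_per_type)]
      programs[mk, t] <- programs[mk, t] * marker_fold
      markers[[types[t]]] <- genes[mk]
    }
    # fix the mitochondrial share of every program
    for (t in seq_along(types)) {
      p <- programs[, t]
      p[mito] <- p[mito] / sum(p[mito]) * mito_fraction
      p[-mito] <- p[-mito] / sum(p[-mito]) * (1 - mito_fraction)
      programs[, t] <- p
    }
    list(programs = programs,
         gene_annotations = data.frame(
           gene = genes, species = "human",
           mito = seq_len(n_genes) %in% mito, stringsAsFactors = FALSE),
         markers = markers)
  })
}

#' Simulate a gene x spot count matrix for a set of CCEs
#'
#' Per CCE: a sequencing depth is drawn (lognormal around `depth`), each
#' gene's transcript count is negative-binomial with mean
#' `depth * program fraction` and dispersion `nb_size` (Poisson as
#' `nb_size = Inf`), and each gene's transcripts are distributed over the
#' CCE's capture spots multinomially, proportional to the spot overlap
#' fraction (emulating capture geometry). In two-species mode each type maps
#' to a species; off-species genes receive counts only through the
#' `contamination` rate (fraction of depth drawn from the other species' mean
#' program).
#'
#' @param assignment Data frame `spot_id`, `cce_id`, `overlap_fraction` (as
#'   returned by [assign_spots_to_cces()]), or one synthetic spot per CCE when
#'   `NULL` and `cce_ids` given.
#' @param cce_types Named character: type per CCE id.
#' @param programs Genes x types relative-expression matrix (columns sum
#'   to 1), e.g. from [simulate_programs()].
#' @param gene_annotations Data frame `gene`, `species`, `mito` (required in
#'   two-species mode; defaults to single-species human).
#' @param type_species Optional named character mapping type -> species.
#' @param depth Mean transcripts per CCE.
#' @param depth_sdlog Lognormal spread of per-CCE depth.
#' @param nb_size Negative-binomial size (dispersion) parameter; `Inf` gives
#'   Poisson counts.
#' @param contamination Cross-species contamination rate in `[0, 1)`.
#' @param cce_ids Used with `assignment = NULL` to fabricate one spot per CCE.
#' @param seed Integer seed.
#' @return List: `spot_counts` (a `spot_count_matrix`), `truth` (list with
#'   `cce_types`, `depths`, `assignment`).
#' @export
simulate_counts <- function(assignment = NULL, cce_types, programs,
                            gene_annotations = NULL, type_species = NULL,
                            depth = 5000, depth_sdlog = 0.3, nb_size = 2,
                            contamination = 0, cce_ids = NULL, seed = 1L) {
  if (is.null(assignment)) {
    if (is.null(cce_ids)) cce_ids <- names(cce_types)
    assignment <- data.frame(spot_id = sprintf("spot_%06d", seq_along(cce_ids)),
                             cce_id = cce_ids, overlap_fraction = 1,
                             stringsAsFactors = FALSE)
  }
  genes <- rownames(programs)
  if (is.null(gene_annotations))
    gene_annotations <- data.frame(gene = genes, species = "human",
                                   mito = startsWith(genes, "MT-"),
                                   stringsAsFactors = FALSE)
  stopifnot(all(programs >= 0), all(assignment$cce_id %in% names(cce_types)))
  cces <- unique(assignment$cce_id)
  spots <- unique(assignment$spot_id)
  n_g <- length(genes)

  with_seed(seed, {
    depths <- stats::setNames(
      round(stats::rlnorm(length(cces), log(depth), depth_sdlog)), cces)
    trip_i <- list(); trip_j <- list(); trip_x <- list()
    spot_of <- split(seq_len(nrow(assignment)), assignment$cce_id)
    species_of_gene <- stats::setNames(gene_annotations$species,
                                       gene_annotations$gene)
    for (c_id in cces) {
      type <- cce_types[[c_id]]
      p <- programs[, type]
      if (!is.null(type_species)) {
        own <- type_species[[type]]
        off <- species_of_gene[genes] != own
        p[off] <- 0
        if (sum(p) == 0) stop("program for type ", type,
                              " has no genes of its own species")
        p <- p / sum(p)
        if (contamination > 0) {
          other <- rowMeans(programs[, names(type_species)[
            type_species != own], drop = FALSE])
          other[!off] <- 0
          if (sum(other) > 0)
            p <- (1 - contamination) * p + contamination * other / sum(other)
        }
      }
      mu <- depths[c_id] * p
      cnt <- if (is.infinite(nb_size)) stats::rpois(n_g, mu)
      else stats::rnbinom(n_g, size = nb_size, mu = mu)
      nz <- which(cnt > 0)
      if (!length(nz)) next
      rows <- spot_of[[c_id]]
      w <- assignment$overlap_fraction[rows]
      sp_idx <- match(assignment$spot_id[rows], spots)
      if (length(rows) == 1) {
        trip_i[[c_id]] <- nz
        trip_j[[c_id]] <- rep(sp_idx, length(nz))
        trip_x[[c_id]] <- cnt[nz]
      } else {
        alloc <- vapply(nz, function(g)
          stats::rmultinom(1, cnt[g], prob = w)[, 1],
          numeric(length(rows)))
        nzc <- which(alloc > 0)
        trip_i[[c_id]] <- nz[(nzc - 1) %/% length(rows) + 1]
        trip_j[[c_id]] <- sp_idx[(nzc - 1) %% length(rows) + 1]
        trip_x[[c_id]] <- alloc[nzc]
      }
    }
    counts <- Matrix::sparseMatrix(
      i = unlist(trip_i) %||% integer(0),
      j = unlist(trip_j) %||% integer(0),
      x = unlist(trip_x) %||% numeric(0),
      dims = c(n_g, length(spots)), dimnames = list(genes, spots))
    list(spot_counts = spot_count_matrix(counts, gene_annotations),
         truth = list(cce_types = cce_types, depths = depths,
                      assignment = assignment))
  })
}

#' Simulate longitudinal live/dead trajectories with known phenotype labels
#'
#' Constructs per-CCE (timepoint, live, dead, area) sequences that satisfy the
#' defining conditions of each phenotype class, so the rule classifier's
#' recovery can be scored exactly. Class counts are `round(n_cce * class_mix)`
#' adjusted to sum to `n_cce`.
#'
#' @param n_cce Number of CCEs.
#' @param class_mix Named numeric summing to 1 over a subset of
#'   `c("daughter_cell_resistant", "cell_cycle_arrest", "dead",
#'   "proliferation", "unclassified")`.
#' @param n_timepoints Number of imaging timepoints (default 5).
#' @param area_mean,area_sd Instance area distribution (pixels); kept below
#'   the classifier's default 15000 px threshold.
#' @param seed Integer seed.
#' @return List: `trajectories` (data frame `cce_id`, `timepoint`, `n_live`,
#'   `n_dead`, `mean_instance_area_px`), `truth` (named label per CCE).
#' @export
simulate_trajectories <- function(n_cce,
                                  class_mix = c(daughter_cell_resistant = 0.25,
                                                cell_cycle_arrest = 0.25,
                                                dead = 0.25,
                                                proliferation = 0.25),
                                  n_timepoints = 5, area_mean = 5000,
                                  area_sd = 800, seed = 1L) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8, n_timepoints >= 2)
  counts <- round(n_cce * class_mix)
  counts[1] <- counts[1] + n_cce - sum(counts)
  labels <- rep(names(class_mix), counts)
  tp <- seq_len(n_timepoints)
  with_seed(seed, {
    labels <- sample(labels)
    rows <- lapply(seq_len(n_cce), function(i) {
      lab <- labels[i]
      if (lab == "cell_cycle_arrest") {
        live <- rep(1L, n_timepoints); dead <- rep(0L, n_timepoints)
      } else if (lab == "daughter_cell_resistant") {
        split_at <- sample(2:n_timepoints, 1)
        live <- ifelse(tp < split_at, 1L, 2L)
        dead <- c(rep(0L, n_timepoints - 1), 1L)   # one daughter dies at end
      } else if (lab == "dead") {
        die_at <- sample(2:n_timepoints, 1)
        live <- ifelse(tp < die_at, 1L, 0L)
        dead <- ifelse(tp < die_at, 0L, 1L)
      } else if (lab == "proliferation") {
        live <- pmin(2L^(tp - 1L), 8L); dead <- rep(0L, n_timepoints)
      } else {                                      # unclassified: vanished
        live <- c(1L, rep(0L, n_timepoints - 1))
        dead <- rep(0L, n_timepoints)
      }
      area <- pmax(500, stats::rnorm(n_timepoints, area_mean, area_sd))
      data.frame(cce_id = sprintf("cce_%05d", i), timepoint = tp,
                 n_live = live, n_dead = dead,
                 mean_instance_area_px = area, stringsAsFactors = FALSE)
    })
    traj <- do.call(rbind, rows)
    list(trajectories = traj,
         truth = stats::setNames(labels, sprintf("cce_%05d", seq_len(n_cce))))
  })
}

#' Simulate a paired expression + imaging dataset with planted structure
#'
#' Generates a normalized expression matrix with cluster structure, a sparse
#' planted linear (and multinomial) response, morphotype embeddings, a lane
#' covariate, and module scores with planted cluster-by-phenotype interaction
#' shifts. In `orthogonal = TRUE` mode the planted predictor genes are
#' mean-centred within every expression cluster, so by construction the
#' cluster structure carries no information about the response -- the regime
#' in which supervised models find drivers that clustering misses.
#'
#' @param n_cce,n_genes Dataset dimensions.
#' @param n_planted Number of true predictor genes.
#' @param effect_size Coefficient magnitude of planted predictors (alternating
#'   signs).
#' @param snr Signal-to-noise ratio (sd(signal)/sd(noise)) of the continuous
#'   response.
#' @param n_clusters Expression clusters (each with its own shifted gene set).
#' @param cluster_shift Mean shift of cluster-defining genes.
#' @param n_cluster_genes Cluster-defining genes per cluster.
#' @param orthogonal Demean planted genes within clusters (default `TRUE`).
#' @param phenotypes Character vector of phenotype labels to sample.
#' @param interaction_cells Data frame `cluster`, `phenotype`, `shift`,
#'   `module` of planted interaction effects on module scores (optional).
#' @param modules Names of module scores to generate.
#' @param n_morphotypes,embedding_dim,morph_sd Embedding generator: morphotype
#'   centroids in `embedding_dim` dimensions plus Gaussian noise.
#' @param n_lanes,lane_shift Lane covariate and additive expression batch
#'   shift per lane.
#' @param seed Integer seed.
#' @return A `multimodal_dataset` (list with `cce_ids`, `expression`,
#'   `embeddings`, `phenotype`, `score`, `lane`, `rna_cluster`,
#'   `module_scores`, `truth`).
#' @export
simulate_multimodal_dataset <- function(n_cce = 500, n_genes = 200,
                                        n_planted = 10, effect_size = 1,
                                        snr = 3, n_clusters = 3,
                                        cluster_shift = 1,
                                        n_cluster_genes = 20,
                                        orthogonal = TRUE,
                                        phenotypes = c("arrest", "prolif"),
                                        interaction_cells = NULL,
                                        modules = "module1",
                                        n_morphotypes = 2, embedding_dim = 16,
                                        morph_sd = 0.5, n_lanes = 3,
                                        lane_shift = 0, seed = 1L) {
  stopifnot(n_planted < n_genes)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  cce_ids <- sprintf("cce_%05d", seq_len(n_cce))
  with_seed(seed, {
    X <- matrix(stats::rnorm(n_genes * n_cce), n_genes, n_cce,
                dimnames = list(genes, cce_ids))
    cluster <- sample(seq_len(n_clusters), n_cce, replace = TRUE)
    # cluster-defining genes sit after the planted block
    planted <- genes[seq_len(n_planted)]
    n_cluster_genes <- min(n_cluster_genes,
                           (n_genes - n_planted) %/% n_clusters)
    cl_genes <- lapply(seq_len(n_clusters), function(k)
      genes[n_planted + (k - 1) * n_cluster_genes + seq_len(n_cluster_genes)])
    for (k in seq_len(n_clusters))
      X[cl_genes[[k]], cluster == k] <- X[cl_genes[[k]], cluster == k] +
        cluster_shift
    lane <- factor(sample(seq_len(n_lanes), n_cce, replace = TRUE))
    if (lane_shift != 0)
      for (l in seq_len(n_lanes))
        X[, lane == l] <- X[, lane == l] + lane_shift * (l - 1)
    beta <- stats::setNames(rep(c(1, -1), length.out = n_planted) * effect_size,
                            planted)
    if (orthogonal && n_planted > 0) {
      # decouple planted genes from the cluster structure: the response is
      # built from the exactly cluster-demeaned planted block (so the score
      # carries no cluster component at all), while the observed expression
      # gets fresh cluster-mean draws from the null sampling distribution
      # N(0, 1/n_k), leaving planted genes statistically indistinguishable
      # from null genes with respect to cluster means
      Xd <- X[planted, , drop = FALSE]
      for (k in seq_len(n_clusters)) {
        sel <- cluster == k
        Xd[, sel] <- Xd[, sel] - rowMeans(Xd[, sel, drop = FALSE])
        X[planted, sel] <- Xd[, sel] +
          stats::rnorm(n_planted, 0, 1 / sqrt(sum(sel)))
      }
      signal <- drop(crossprod(Xd, beta))
    } else {
      signal <- if (n_planted > 0)
        drop(crossprod(X[planted, , drop = FALSE], beta)) else numeric(n_cce)
    }
    noise_sd <- if (n_planted > 0 && stats::sd(signal) > 0)
      stats::sd(signal) / snr else 1
    score <- signal + stats::rnorm(n_cce, 0, noise_sd)
    phenotype <- factor(sample(phenotypes, n_cce, replace = TRUE))
    # module scores: baseline noise + planted interaction shifts
    ms <- matrix(stats::rnorm(n_cce * length(modules)), n_cce,
                 dimnames = list(cce_ids, modules))
    if (!is.null(interaction_cells)) {
      for (r in seq_len(nrow(interaction_cells))) {
        sel <- cluster == interaction_cells$cluster[r] &
          phenotype == interaction_cells$phenotype[r]
        ms[sel, interaction_cells$module[r]] <-
          ms[sel, interaction_cells$module[r]] + interaction_cells$shift[r]
      }
    }
    morph <- sample(seq_len(n_morphotypes), n_cce, replace = TRUE)
    centroids <- matrix(stats::rnorm(n_morphotypes * embedding_dim, sd = 2),
                        n_morphotypes, embedding_dim)
    emb <- centroids[morph, , drop = FALSE] +
      matrix(stats::rnorm(n_cce * embedding_dim, 0, morph_sd), n_cce)
    rownames(emb) <- cce_ids
    multimodal_dataset(
      cce_ids = cce_ids, expression = X, embeddings = emb,
      phenotype = phenotype, score = score, lane = lane,
      rna_cluster = factor(cluster), module_scores = ms,
      truth = list(planted = planted, beta = beta, cluster = cluster,
                   cluster_genes = cl_genes, morphotype = morph,
                   interaction_cells = interaction_cells,
                   noise_sd = noise_sd))
  })
}
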