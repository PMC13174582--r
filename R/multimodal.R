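# Paired imaging + transcriptomics statistics: clustering, elastic-net models
# with bootstrap stability selection, signed-rank preranked GSEA, interaction
# linear models, and the model-vs-cluster-marker comparison.

#' Aligned per-CCE multimodal dataset
#'
#' @param cce_ids Character ids; all blocks are aligned on them.
#' @param expression Normalized genes x CCEs matrix.
#' @param embeddings Optional CCEs x d feature matrix.
#' @param phenotype Optional categorical label per CCE.
#' @param score Optional continuous response per CCE.
#' @param lane Lane covariate (factor).
#' @param rna_cluster Expression-cluster label per CCE.
#' @param module_scores Optional CCEs x modules matrix.
#' @param truth Optional list of planted ground truth (synthetic data).
#' @return Object of class `multimodal_dataset`.
#' @export
multimodal_dataset <- function(cce_ids, expression, embeddings = NULL,
                               phenotype = NULL, score = NULL, lane = NULL,
                               rna_cluster = NULL, module_scores = NULL,
                               truth = NULL) {
  n <- length(cce_ids)
  stopifnot(ncol(expression) == n)
  if (!is.null(embeddings)) stopifnot(nrow(embeddings) == n)
  if (!is.null(phenotype)) stopifnot(length(phenotype) == n,
                                     !anyNA(phenotype))
  if (!is.null(score)) stopifnot(length(score) == n, !anyNA(score))
  structure(list(cce_ids = cce_ids, expression = expression,
                 embeddings = embeddings, phenotype = phenotype,
                 score = score, lane = lane, rna_cluster = rna_cluster,
                 module_scores = module_scores, truth = truth),
            class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat(sprintf("<multimodal_dataset> %d CCEs, %d genes%s%s\n",
              length(x$cce_ids), nrow(x$expression),
              if (!is.null(x$embeddings))
                sprintf(", %d embedding dims", ncol(x$embeddings)) else "",
              if (!is.null(x$phenotype)) ", phenotyped" else ""))
  invisible(x)
}

#' Cluster feature vectors via a 2D embedding + k-means
#'
#' Embeds the rows of `features` in two dimensions (UMAP when the `uwot`
#' package is available and `method = "umap"`, otherwise the first two
#' principal components) and runs k-means in that plane. Deterministic given
#' the seed.
#'
#' @param features Numeric matrix (rows = observations).
#' @param k Number of clusters (<= number of rows).
#' @param method `"pca"` (default) or `"umap"`.
#' @param seed Integer seed.
#' @return Integer cluster label per row.
#' @export
cluster_features <- function(features, k, method = c("pca", "umap"),
                             seed = 1L) {
  method <- match.arg(method)
  features <- as.matrix(features)
  if (k > nrow(features)) stop("k exceeds the number of observations")
  if (k == 1) return(rep(1L, nrow(features)))
  keep <- apply(features, 2, stats::sd) > 0
  emb <- if (!any(keep)) {
    matrix(0, nrow(features), 2)
  } else if (method == "umap" && requireNamespace("uwot", quietly = TRUE)) {
    with_seed(seed, uwot::umap(features[, keep, drop = FALSE], n_threads = 1))
  } else {
    p <- stats::prcomp(features[, keep, drop = FALSE], scale. = TRUE)
    cbind(p$x[, 1], if (ncol(p$x) >= 2) p$x[, 2] else 0)
  }
  if (all(apply(emb, 2, stats::sd) == 0))
    return(rep(1L, nrow(features)))
  with_seed(seed, stats::kmeans(emb, centers = k, nstart = 10,
                                iter.max = 50)$cluster)
}

#' Elastic-net model configuration
#'
#' @param alpha Elastic-net mixing parameter (default 0.5, equal L1/L2).
#' @param nfolds_multinomial,nfolds_gaussian Cross-validation folds for
#'   lambda selection (5 for categorical, 10 for continuous responses).
#' @param n_variable_genes Expression features kept, ranked by variance
#'   (default 2000).
#' @param min_expr_fraction Minimum fraction of CCEs with nonzero expression
#'   (default 0.15).
#' @param bootstrap_reps,stability_threshold Stability selection: number of
#'   bootstrap refits and the inclusive selection-frequency threshold
#'   (defaults 100 and 0.5).
#' @param stability_lambda Penalty rule used inside the stability loop:
#'   `"ebic"` (default) re-selects lambda in every bootstrap by the extended
#'   BIC (gamma = 1), a selection-consistent criterion; `"cv_min"` fixes the
#'   full-data minimum-CV-error lambda, which targets prediction and tends to
#'   keep dataset-level spurious correlates that bootstrap resampling cannot
#'   remove.
#' @param test_fraction Held-out fraction for evaluation (default 0.2).
#' @param cv_loss Loss for CV lambda selection (`"deviance"` default).
#' @param seed Integer seed (split, folds, bootstrap).
#' @return List of class `model_config`.
#' @export
model_config <- function(alpha = 0.5, nfolds_multinomial = 5,
                         nfolds_gaussian = 10, n_variable_genes = 2000,
                         min_expr_fraction = 0.15, bootstrap_reps = 100,
                         stability_threshold = 0.5,
                         stability_lambda = c("ebic", "cv_min"),
                         test_fraction = 0.2, cv_loss = "deviance",
                         seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, nfolds_multinomial >= 2,
            nfolds_gaussian >= 2)
  stability_lambda <- match.arg(stability_lambda)
  structure(list(alpha = alpha, nfolds_multinomial = nfolds_multinomial,
                 nfolds_gaussian = nfolds_gaussian,
                 n_variable_genes = n_variable_genes,
                 min_expr_fraction = min_expr_fraction,
                 bootstrap_reps = bootstrap_reps,
                 stability_threshold = stability_threshold,
                 stability_lambda = stability_lambda,
                 test_fraction = test_fraction, cv_loss = cv_loss,
                 seed = seed),
            class = "model_config")
}

# Extended BIC (gamma = 1) over the glmnet path; returns the lambda whose
# support minimizes EBIC. For gaussian fits the deviance term is computed on
# the least-squares REFIT of each candidate support (shrinkage-free, the
# standard practice for BIC-type selection on lasso paths); multinomial fits
# use the penalized path deviance directly.
ebic_lambda <- function(x, y, family, alpha) {
  n <- nrow(x); p <- ncol(x)
  f <- glmnet::glmnet(x, y, family = family, alpha = alpha,
                      standardize = FALSE)
  k <- f$df
  pen <- k * (log(n) + 2 * log(p))
  if (family != "gaussian")
    return(f$lambda[which.min((1 - f$dev.ratio) * f$nulldev + pen)])
  # candidate supports: one path point per distinct df, supports below n/2
  cand <- which(!duplicated(k) & k <= n %/% 2)
  beta <- f$beta
  best <- Inf; best_lambda <- f$lambda[1]
  for (i in cand) {
    supp <- which(beta[, i] != 0)
    rss <- if (length(supp) == 0) sum((y - mean(y))^2)
    else {
      fit <- stats::lm.fit(cbind(1, x[, supp, drop = FALSE]), y)
      sum(fit$residuals^2)
    }
    val <- n * log(rss / n) + pen[i]
    if (val < best) { best <- val; best_lambda <- f$lambda[i] }
  }
  best_lambda
}

# Assemble the standardized design matrix from the requested feature blocks.
build_feature_matrix <- function(data, blocks, config) {
  mats <- list()
  if ("expression" %in% blocks) {
    X <- as.matrix(data$expression)
    expr_frac <- rowMeans(X != 0)
    X <- X[expr_frac >= config$min_expr_fraction, , drop = FALSE]
    if (nrow(X) > config$n_variable_genes) {
      v <- apply(X, 1, stats::var)
      X <- X[order(v, decreasing = TRUE)[seq_len(config$n_variable_genes)], ,
             drop = FALSE]
    }
    mats$expression <- t(X)
  }
  if ("embeddings" %in% blocks) {
    if (is.null(data$embeddings)) stop("dataset has no embeddings block")
    E <- as.matrix(data$embeddings)
    colnames(E) <- colnames(E) %||% sprintf("emb_%03d", seq_len(ncol(E)))
    colnames(E) <- paste0("emb:", colnames(E))
    mats$embeddings <- E
  }
  if (!length(mats)) stop("no feature blocks selected")
  # per-block standardization before concatenation
  mats <- lapply(mats, function(m) {
    mu <- colMeans(m); sdv <- apply(m, 2, stats::sd)
    keep <- sdv > 0
    sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  })
  do.call(cbind, mats)
}

#' Fit an elastic-net model of a phenotype from expression/embedding features
#'
#' Gaussian elastic net for a continuous response, multinomial for a
#' categorical one, at the configured mixing `alpha`; lambda is chosen by
#' minimum mean cross-validated error. Features: expression genes filtered to
#' nonzero expression in at least `min_expr_fraction` of CCEs and then to the
#' `n_variable_genes` most variable; embedding columns used as-is; every block
#' standardized before concatenation. An 80/20 train/test split (seeded,
#' stratified for categorical responses) provides the held-out metric:
#' R-squared, or the confusion matrix and overall accuracy.
#'
#' @param data A `multimodal_dataset`.
#' @param response `"score"` (continuous) or `"phenotype"` (categorical), or
#'   a vector of length `ncol(expression)`.
#' @param blocks Feature blocks, subset of `c("expression", "embeddings")`.
#' @param config A [model_config()].
#' @return List of class `cce_enet`: `fit` (the `cv.glmnet` object),
#'   `lambda`, `coefficients` (named, nonzero rows only; one column per class
#'   for multinomial), `family`, `metric` (list with `r2` or
#'   `accuracy`/`confusion`), `features`, `train_idx`.
#' @export
fit_elastic_net <- function(data, response = "score",
                            blocks = "expression",
                            config = model_config()) {
  y <- if (is.character(response) && length(response) == 1)
    data[[response]] else response
  if (is.null(y)) stop("response not found in dataset")
  x <- build_feature_matrix(data, blocks, config)
  n <- nrow(x)
  stopifnot(length(y) == n)
  categorical <- is.factor(y) || is.character(y)
  if (categorical) {
    y <- factor(y)
    if (nlevels(y) < 2) stop("categorical response needs >= 2 levels")
  } else if (stats::sd(y) == 0) stop("constant response")
  family <- if (categorical) "multinomial" else "gaussian"
  nfolds <- if (categorical) config$nfolds_multinomial else
    config$nfolds_gaussian

  with_seed(config$seed, {
    test_idx <- if (categorical) {
      unlist(lapply(split(seq_len(n), y), function(ii)
        sample(ii, max(1, round(length(ii) * config$test_fraction)))))
    } else sample(n, max(1, round(n * config$test_fraction)))
    train_idx <- setdiff(seq_len(n), test_idx)
    foldid <- sample(rep_len(seq_len(nfolds), length(train_idx)))
    cv <- glmnet::cv.glmnet(x[train_idx, , drop = FALSE],
                            if (categorical) y[train_idx] else y[train_idx],
                            family = family, alpha = config$alpha,
                            foldid = foldid,
                            type.measure = config$cv_loss,
                            standardize = FALSE)
    co <- stats::coef(cv, s = "lambda.min")
    if (categorical) {
      cf <- do.call(cbind, lapply(co, function(m) m[-1, 1]))
      colnames(cf) <- names(co)
      nz <- rowSums(cf != 0) > 0
      coefficients <- cf[nz, , drop = FALSE]
      pred <- stats::predict(cv, x[test_idx, , drop = FALSE],
                             s = "lambda.min", type = "class")
      confusion <- table(truth = y[test_idx],
                         predicted = factor(pred, levels = levels(y)))
      metric <- list(accuracy = mean(pred == as.character(y[test_idx])),
                     confusion = confusion)
    } else {
      cf <- co[-1, 1]
      coefficients <- cf[cf != 0]
      pred <- drop(stats::predict(cv, x[test_idx, , drop = FALSE],
                                  s = "lambda.min"))
      ss_res <- sum((y[test_idx] - pred)^2)
      ss_tot <- sum((y[test_idx] - mean(y[test_idx]))^2)
      metric <- list(r2 = 1 - ss_res / ss_tot)
    }
    structure(list(fit = cv, lambda = cv$lambda.min,
                   coefficients = coefficients, family = family,
                   metric = metric, features = colnames(x),
                   train_idx = train_idx, config = config),
              class = "cce_enet")
  })
}

#' @export
print.cce_enet <- function(x, ...) {
  m <- if (x$family == "gaussian")
    sprintf("held-out R2 = %.3f", x$metric$r2)
  else sprintf("held-out accuracy = %.3f", x$metric$accuracy)
  nz <- if (is.matrix(x$coefficients)) nrow(x$coefficients)
  else length(x$coefficients)
  cat(sprintf("<cce_enet> %s elastic net (alpha = %g): %d nonzero features, %s\n",
              x$family, x$config$alpha, nz, m))
  invisible(x)
}

#' Bootstrap stability selection for elastic-net features
#'
#' The elastic net is refit on `bootstrap_reps` bootstrap resamples; a feature
#' is *stable* when it receives a nonzero coefficient in at least
#' `stability_threshold * bootstrap_reps` fits (inclusive, i.e. exactly 50 of
#' 100 counts as stable at the default threshold). Under the default
#' `stability_lambda = "ebic"` rule each bootstrap refit selects its own
#' penalty by the extended BIC, which targets support recovery;
#' `"cv_min"` instead fixes the full-data minimum-CV-error lambda for all
#' refits (the penalty the predictive fit uses).
#'
#' @inheritParams fit_elastic_net
#' @return Data frame `feature`, `frequency`, `stable`, ordered by decreasing
#'   frequency; for `"cv_min"` the fixed lambda is attached as attribute
#'   `"lambda"`.
#' @export
stability_select <- function(data, response = "score",
                             blocks = "expression",
                             config = model_config()) {
  y <- if (is.character(response) && length(response) == 1)
    data[[response]] else response
  x <- build_feature_matrix(data, blocks, config)
  categorical <- is.factor(y) || is.character(y)
  if (categorical) y <- factor(y)
  family <- if (categorical) "multinomial" else "gaussian"
  nfolds <- if (categorical) config$nfolds_multinomial else
    config$nfolds_gaussian
  n <- nrow(x)
  with_seed(config$seed, {
    lambda <- NA_real_
    if (config$stability_lambda == "cv_min") {
      foldid <- sample(rep_len(seq_len(nfolds), n))
      cv <- glmnet::cv.glmnet(x, y, family = family, alpha = config$alpha,
                              foldid = foldid, type.measure = config$cv_loss,
                              standardize = FALSE)
      lambda <- cv$lambda.min
    }
    hits <- integer(ncol(x))
    for (b in seq_len(config$bootstrap_reps)) {
      ii <- sample(n, n, replace = TRUE)
      if (categorical && nlevels(droplevels(y[ii])) < nlevels(y)) {
        # resample until every class is present (keeps the fit well-posed)
        while (nlevels(droplevels(y[ii])) < nlevels(y))
          ii <- sample(n, n, replace = TRUE)
      }
      lam_b <- if (config$stability_lambda == "ebic")
        ebic_lambda(x[ii, , drop = FALSE], y[ii], family, config$alpha)
      else lambda
      fit <- glmnet::glmnet(x[ii, , drop = FALSE], y[ii], family = family,
                            alpha = config$alpha, lambda = lam_b,
                            standardize = FALSE)
      co <- stats::coef(fit)
      nz <- if (is.list(co))
        Reduce(`|`, lapply(co, function(m) m[-1, 1] != 0))
      else co[-1, 1] != 0
      hits <- hits + nz
    }
    freq <- hits / config$bootstrap_reps
    out <- data.frame(feature = colnames(x), frequency = freq,
                      stable = freq >= config$stability_threshold,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$frequency, out$feature), ]
    rownames(out) <- NULL
    attr(out, "lambda") <- lambda
    out
  })
}

#' Signed rank statistic for preranked GSEA
#'
#' `rank = -log10(p) * sign(log2FC)`; p-values are floored at `p_floor` to
#' keep the statistic finite.
#'
#' @param p P-values.
#' @param log2fc Log2 fold changes.
#' @param p_floor Smallest p-value used (default 1e-300).
#' @return Numeric signed ranks.
#' @export
signed_rank_stat <- function(p, log2fc, p_floor = 1e-300) {
  -log10(pmax(p, p_floor)) * sign(log2fc)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic weighted (exponent 1) running-sum enrichment score: genes sorted by
#' decreasing statistic; hits advance the sum proportionally to |statistic|,
#' misses retreat by 1/(N - Nh); the ES is the extremum of the running sum.
#'
#' @param stats_vec Named numeric vector of per-gene statistics.
#' @param gene_set Character vector of gene ids.
#' @return The enrichment score (signed).
#' @export
gsea_enrichment_score <- function(stats_vec, gene_set) {
  ord <- order(stats_vec, decreasing = TRUE)
  s <- stats_vec[ord]
  hit <- names(s) %in% gene_set
  nh <- sum(hit)
  if (nh == 0 || nh == length(s)) return(0)
  w <- abs(s)
  sw <- sum(w[hit])
  inc <- numeric(length(s))
  inc[hit] <- if (sw > 0) w[hit] / sw else 1 / nh   # flat steps if all zero
  dec <- ifelse(hit, 0, 1 / (length(s) - nh))
  run <- cumsum(inc - dec)
  run[which.max(abs(run))]
}

#' Signed-rank preranked gene-set enrichment with permutation p-values
#'
#' For every group in a differential-expression table, genes are ranked by
#' `-log10(p) * sign(log2FC)` and each gene set receives a weighted KS
#' enrichment score. Significance comes from a gene-permutation null
#' (`n_perm` random sets of the same size, seeded); FDR is Benjamini-Hochberg
#' across all pathways within the grouping strategy. Groups smaller than
#' `min_group_size` CCEs are skipped with a message.
#'
#' @param de_table Data frame `group`, `gene`, `p`, `log2FC` (one row per
#'   gene per group), e.g. from [differential_expression()] with
#'   `min_pct = 0`, `logfc_threshold = 0`.
#' @param gene_sets Named list of gene-id vectors (e.g. [read_gene_sets()]).
#' @param group_sizes Named integer: CCEs per group (for the size filter);
#'   `NULL` disables the filter.
#' @param grouping Label recorded in the output (`"rna"`, `"imaging"` or
#'   `"combined"`).
#' @param min_group_size Minimum CCEs per retained group (default 50).
#' @param n_perm Gene permutations (default 1000).
#' @param seed Integer seed.
#' @return Data frame: `grouping`, `group`, `pathway`, `size`, `es`, `p`,
#'   `fdr`.
#' @export
signed_rank_gsea <- function(de_table, gene_sets, group_sizes = NULL,
                             grouping = "rna", min_group_size = 50,
                             n_perm = 1000, seed = 1L) {
  stopifnot(all(c("group", "gene", "p", "log2FC") %in% names(de_table)))
  out <- list()
  for (g in unique(de_table$group)) {
    if (!is.null(group_sizes) && !is.na(group_sizes[g]) &&
        group_sizes[g] < min_group_size) {
      message("group ", g, " has ", group_sizes[g], " CCEs (< ",
              min_group_size, "): skipped")
      next
    }
    sub <- de_table[de_table$group == g, ]
    stats_vec <- stats::setNames(signed_rank_stat(sub$p, sub$log2FC),
                                 sub$gene)
    for (pw in names(gene_sets)) {
      gs <- intersect(gene_sets[[pw]], names(stats_vec))
      if (length(gs) < 2) next
      es <- gsea_enrichment_score(stats_vec, gs)
      null_es <- with_seed(seed + length(out), vapply(seq_len(n_perm),
        function(i) gsea_enrichment_score(
          stats_vec, sample(names(stats_vec), length(gs))), 0))
      p <- if (es >= 0) (1 + sum(null_es >= es)) / (1 + n_perm)
      else (1 + sum(null_es <= es)) / (1 + n_perm)
      out[[length(out) + 1]] <- data.frame(
        grouping = grouping, group = g, pathway = pw, size = length(gs),
        es = es, p = p, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(grouping = character(0), group = character(0),
               pathway = character(0), size = integer(0), es = numeric(0),
               p = numeric(0))
  res$fdr <- stats::p.adjust(res$p, "BH")
  rownames(res) <- NULL
  res
}

#' Combined RNA-cluster x imaging-phenotype grouping
#'
#' Cartesian-product labels of the two groupings, as used when enrichment is
#' computed on the combined classification.
#'
#' @param rna_cluster,phenotype Aligned label vectors.
#' @return Factor of `cluster.phenotype` labels.
#' @export
combined_grouping <- function(rna_cluster, phenotype) {
  factor(paste(rna_cluster, phenotype, sep = "."))
}

#' Scan module scores for RNA-cluster x imaging-phenotype interactions
#'
#' Per module, fits the ordinary least squares model
#' `module_score ~ rna_cluster * phenotype + lane` (treatment coding, lane as
#' additive covariate) and tests every interaction coefficient with a t-test.
#' Benjamini-Hochberg adjustment runs across all interaction terms of all
#' modules; `significant` marks `p_adj <= 0.05`. Empty cluster-by-phenotype
#' cells are reported; aliasing not explained by empty cells raises an error
#' naming the aliased terms.
#'
#' @param data A `multimodal_dataset` with `rna_cluster`, `phenotype` and
#'   optionally `lane`.
#' @param module_scores Matrix CCEs x modules (default:
#'   `data$module_scores`).
#' @return Data frame: `module`, `term`, `estimate`, `p`, `p_adj`,
#'   `significant`; empty design cells are attached as attribute
#'   `"empty_cells"`.
#' @export
interaction_scan <- function(data, module_scores = NULL) {
  module_scores <- module_scores %||% data$module_scores
  if (is.null(module_scores)) stop("no module scores supplied")
  module_scores <- as.matrix(module_scores)
  cluster <- factor(data$rna_cluster)
  phenotype <- factor(data$phenotype)
  if (nlevels(cluster) < 2 || nlevels(phenotype) < 2)
    stop("need >= 2 clusters and >= 2 phenotypes")
  tab <- table(cluster, phenotype)
  empty <- which(tab == 0, arr.ind = TRUE)
  empty_cells <- if (nrow(empty))
    data.frame(cluster = rownames(tab)[empty[, 1]],
               phenotype = colnames(tab)[empty[, 2]])
  else data.frame(cluster = character(0), phenotype = character(0))
  lane <- if (!is.null(data$lane) && nlevels(factor(data$lane)) > 1)
    factor(data$lane)
  out <- list()
  for (m in colnames(module_scores) %||% seq_len(ncol(module_scores))) {
    y <- module_scores[, m]
    df <- data.frame(y = y, cluster = cluster, phenotype = phenotype)
    form <- y ~ cluster * phenotype
    if (!is.null(lane)) { df$lane <- lane; form <- y ~ cluster * phenotype + lane }
    if (stats::sd(y) == 0) {
      terms <- attr(stats::terms(form), "term.labels")
      nm <- grep("cluster.*:.*phenotype", colnames(
        stats::model.matrix(form, df)), value = TRUE)
      out[[m]] <- data.frame(module = m, term = nm, estimate = 0,
                             p = NA_real_, stringsAsFactors = FALSE)
      next
    }
    fit <- stats::lm(form, data = df)
    cf <- stats::coef(fit)
    inter <- grep(":", names(cf), value = TRUE)
    na_terms <- inter[is.na(cf[inter])]
    if (length(na_terms)) {
      expected_na <- nrow(empty_cells) > 0
      if (!expected_na)
        stop("rank-deficient design; aliased terms: ",
             paste(na_terms, collapse = ", "))
      inter <- setdiff(inter, na_terms)
    }
    sm <- summary(fit)$coefficients
    out[[m]] <- data.frame(module = m, term = inter,
                           estimate = unname(cf[inter]),
                           p = sm[inter, "Pr(>|t|)"],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$p_adj <- stats::p.adjust(res$p, "BH")
  res$significant <- !is.na(res$p_adj) & res$p_adj <= 0.05
  rownames(res) <- NULL
  attr(res, "empty_cells") <- empty_cells
  res
}

#' Overlap between stable model predictors and top cluster markers
#'
#' Compares the gene set selected by a supervised model with the top
#' `top_n` differentially expressed genes per cluster (ordered by log2 fold
#' change), and pairs each model gene's |coefficient| with its mean cluster
#' log2FC to quantify (rank) correlation between the two orderings.
#'
#' @param coefficients Named numeric vector of model coefficients (stable
#'   features).
#' @param markers Marker table from [differential_expression()].
#' @param top_n Markers per cluster (default 20).
#' @return List: `overlap` (data frame per cluster + union row), `pairs`
#'   (gene, abs_coefficient, mean_log2FC), `rank_correlation` (Spearman,
#'   `NA` when fewer than 3 pairs vary).
#' @export
model_vs_cluster_overlap <- function(coefficients, markers, top_n = 20) {
  model_genes <- names(coefficients)
  by_cluster <- split(markers, markers$group)
  top <- lapply(by_cluster, function(mk) {
    mk <- mk[order(-mk$log2FC), ]
    utils::head(mk$gene, top_n)
  })
  overlap <- data.frame(
    cluster = names(top),
    n_markers = vapply(top, length, 0L),
    n_overlap = vapply(top, function(g) length(intersect(g, model_genes)), 0L),
    stringsAsFactors = FALSE)
  union_top <- unique(unlist(top))
  overlap <- rbind(overlap,
                   data.frame(cluster = "union", n_markers = length(union_top),
                              n_overlap = length(intersect(union_top,
                                                           model_genes))))
  mean_l2fc <- tapply(abs(markers$log2FC), markers$gene, mean)
  pairs <- data.frame(gene = model_genes,
                      abs_coefficient = abs(unname(coefficients)),
                      mean_log2FC = as.numeric(mean_l2fc[model_genes]),
                      stringsAsFactors = FALSE)
  pairs$mean_log2FC[is.na(pairs$mean_log2FC)] <- 0
  rc <- if (nrow(pairs) >= 3 && stats::sd(pairs$abs_coefficient) > 0 &&
            stats::sd(pairs$mean_log2FC) > 0)
    stats::cor(pairs$abs_coefficient, pairs$mean_log2FC, method = "spearman")
  else NA_real_
  list(overlap = overlap, pairs = pairs, rank_correlation = rc)
}
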