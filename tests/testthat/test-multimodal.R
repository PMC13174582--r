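# Clustering, elastic-net models, stability selection, signed-rank GSEA and
# interaction models.

test_that("k-means in the 2D embedding recovers planted blobs", {
  set.seed(1)
  blob <- rbind(matrix(rnorm(50 * 5, 0), 50),
                matrix(rnorm(50 * 5, 6), 50))
  cl <- cluster_features(blob, k = 2, seed = 1)
  expect_equal(adjusted_rand_index(cl, rep(1:2, each = 50)), 1)

  # identical rows, k = 1 -> single cluster
  same <- matrix(1, 20, 4)
  expect_equal(unique(cluster_features(same, k = 1, seed = 1)), 1L)

  expect_error(cluster_features(blob, k = 200), "exceeds")
  # deterministic given seed
  expect_identical(cluster_features(blob, 2, seed = 7),
                   cluster_features(blob, 2, seed = 7))
})

test_that("planted morphotypes of shape embeddings cluster cleanly", {
  # four morphotypes: disks/ellipses at two sizes
  masks <- list()
  truth <- integer(0)
  kinds <- expand.grid(r = c(5, 9), ay = c(1, 2.2))
  idx <- 0
  for (k in seq_len(nrow(kinds))) for (rep_ in 1:12) {
    idx <- idx + 1
    masks[[idx]] <- disk_mask(kinds$r[k], ax = 1, ay = kinds$ay[k],
                              dim_px = 45)
    truth[idx] <- k
  }
  emb <- do.call(rbind, lapply(masks, extract_shape_embedding))
  # jitter so replicate rows are not exactly identical
  aris <- vapply(1:10, function(s) {
    set.seed(s)
    adjusted_rand_index(
      cluster_features(emb + matrix(rnorm(length(emb), 0, 1e-3), nrow(emb)),
                       k = 4, seed = s),
      truth)
  }, 0)
  expect_gte(mean(aris >= 0.9), 0.9)
})

test_that("gaussian elastic net recovers a planted linear model", {
  ds <- simulate_multimodal_dataset(n_cce = 500, n_genes = 200,
                                    n_planted = 2, effect_size = c(3, 2),
                                    snr = 3, orthogonal = FALSE, seed = 42)
  # response built as 3*g1 - 2*g2 + noise
  fit <- fit_elastic_net(ds, "score", config = model_config(seed = 42))
  expect_gte(fit$metric$r2, 0.6)
  cf <- fit$coefficients
  expect_true(all(c("GENE0001", "GENE0002") %in% names(cf)))
  expect_gt(cf[["GENE0001"]], 0)
  expect_lt(cf[["GENE0002"]], 0)
})

test_that("pure-noise responses yield no held-out signal", {
  for (s in 1:3) {
    ds <- simulate_multimodal_dataset(n_cce = 200, n_genes = 100,
                                      n_planted = 0, seed = 100 + s)
    fit <- fit_elastic_net(ds, "score", config = model_config(seed = s))
    expect_lte(fit$metric$r2, 0.1)
  }
})

test_that("multinomial elastic net separates planted classes", {
  set.seed(5)
  n <- 800; n_genes <- 150
  cls <- factor(sample(paste0("k", 1:4), n, replace = TRUE))
  X <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("GENE%04d", seq_len(n_genes)),
                              sprintf("cce_%05d", seq_len(n))))
  for (k in 1:4) {
    mk <- (k - 1) * 10 + seq_len(10)
    X[mk, cls == paste0("k", k)] <- X[mk, cls == paste0("k", k)] + 2
  }
  ds <- multimodal_dataset(colnames(X), X, phenotype = cls)
  fit <- fit_elastic_net(ds, "phenotype",
                         config = model_config(seed = 5,
                                               min_expr_fraction = 0))
  expect_gte(fit$metric$accuracy, 0.9)
  expect_equal(fit$family, "multinomial")
  expect_equal(dim(fit$metric$confusion), c(4, 4))
})

test_that("stability selection recovers planted features and is inclusive", {
  ds <- simulate_multimodal_dataset(n_cce = 300, n_genes = 150,
                                    n_planted = 10, effect_size = 1.5,
                                    snr = 3, seed = 12)
  cfg <- model_config(seed = 12, bootstrap_reps = 50)
  ss <- stability_select(ds, "score", config = cfg)
  stable <- ss$feature[ss$stable]
  expect_gte(length(intersect(stable, ds$truth$planted)), 8)
  expect_lte(length(setdiff(stable, ds$truth$planted)), 2)
  # thresholding rule is inclusive (frequency == threshold counts as stable)
  expect_identical(ss$stable, ss$frequency >= cfg$stability_threshold)
  # reproducible given seed
  ss2 <- stability_select(ds, "score", config = cfg)
  expect_identical(ss, ss2)
})

test_that("signed rank statistic follows the quoted formula", {
  expect_equal(signed_rank_stat(0.01, -3), -2)
  expect_equal(signed_rank_stat(0.1, 2), 1)
  expect_equal(signed_rank_stat(1, 5), 0)
})

test_that("enrichment score equals the brute-force cumulative sum", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    stats_vec <- setNames(rnorm(n), sprintf("g%02d", 1:n))
    gs <- sample(names(stats_vec), sample(2:5, 1))
    expect_equal(gsea_enrichment_score(stats_vec, gs),
                 brute_force_es(stats_vec, gs), tolerance = 1e-12)
  }
})

test_that("enrichment score matches the field-standard implementation", {
  set.seed(4)
  stats_vec <- setNames(rnorm(40), sprintf("g%02d", 1:40))
  gs <- sample(names(stats_vec), 6)
  es <- gsea_enrichment_score(stats_vec, gs)
  ranked <- sort(stats_vec, decreasing = TRUE)
  ref <- fgsea::calcGseaStat(ranked,
                             selectedStats = which(names(ranked) %in% gs),
                             gseaParam = 1)
  expect_equal(es, ref, tolerance = 1e-8)
})

test_that("planted gene sets reach FDR < 0.05 and small groups are skipped", {
  set.seed(6)
  n_genes <- 120
  de <- data.frame(group = "g1", gene = sprintf("g%03d", 1:n_genes),
                   p = runif(n_genes, 0.2, 1),
                   log2FC = rnorm(n_genes, 0, 0.3))
  # plant: top 20 genes highly significant and up
  de$p[1:20] <- runif(20, 1e-8, 1e-4)
  de$log2FC[1:20] <- runif(20, 2, 4)
  sets <- list(planted = de$gene[1:20],
               random = sample(de$gene, 20))
  res <- signed_rank_gsea(de, sets, group_sizes = c(g1 = 100),
                          n_perm = 1000, seed = 1)
  planted <- res[res$pathway == "planted", ]
  expect_gt(planted$es, 0)
  expect_lt(planted$fdr, 0.05)

  # group below the size threshold is skipped with a message
  expect_message(
    small <- signed_rank_gsea(de, sets, group_sizes = c(g1 = 49),
                              n_perm = 100, seed = 1),
    "skipped")
  expect_equal(nrow(small), 0)
})

test_that("interaction scan finds a planted cluster-by-phenotype shift", {
  ic <- data.frame(cluster = 2, phenotype = "prolif", shift = 1,
                   module = "module1")
  hits <- 0
  for (s in 1:20) {
    ds <- simulate_multimodal_dataset(n_cce = 400, n_genes = 20,
                                      n_clusters = 2,
                                      phenotypes = c("arrest", "prolif"),
                                      interaction_cells = ic, seed = 600 + s)
    res <- interaction_scan(ds)
    hit <- res$significant[res$term == "cluster2:phenotypeprolif"]
    hits <- hits + as.integer(hit)
  }
  expect_gte(hits, 18)   # >= 90% power
})

test_that("interaction scan is calibrated under the null and handles degenerate input", {
  ps <- c()
  for (s in 1:25) {
    ds <- simulate_multimodal_dataset(n_cce = 360, n_genes = 20,
                                      n_clusters = 3,
                                      phenotypes = c("a", "b", "c"),
                                      seed = 900 + s)
    res <- interaction_scan(ds)
    ps <- c(ps, res$p)
  }
  rate <- mean(ps < 0.05)
  se <- sqrt(0.05 * 0.95 / length(ps))
  expect_lt(abs(rate - 0.05), 3 * se)

  # constant module score: zero estimates, nothing significant
  ds <- simulate_multimodal_dataset(n_cce = 100, n_genes = 20, seed = 1)
  ds$module_scores[, 1] <- 5
  res <- interaction_scan(ds)
  expect_true(all(res$estimate == 0))
  expect_false(any(res$significant))
})

test_that("interaction p-values match a permutation oracle", {
  ds <- simulate_multimodal_dataset(n_cce = 120, n_genes = 20,
                                    n_clusters = 2,
                                    phenotypes = c("a", "b"), seed = 77)
  res <- interaction_scan(ds)
  term <- "cluster2:phenotypeb"
  obs_p <- res$p[res$term == term]
  # permutation null: shuffle phenotype within cluster, collect |t| of the
  # interaction coefficient
  y <- ds$module_scores[, 1]
  cl <- factor(ds$rna_cluster); ph <- factor(ds$phenotype)
  lane <- factor(ds$lane)
  tstat <- function(ph_perm) {
    f <- summary(stats::lm(y ~ cl * ph_perm + lane))
    f$coefficients["cl2:ph_permb", "t value"]
  }
  obs_t <- abs(tstat(ph))
  set.seed(8)
  null_t <- replicate(400, {
    php <- ph
    for (k in levels(cl)) {
      sel <- cl == k
      php[sel] <- sample(ph[sel])
    }
    abs(tstat(php))
  })
  perm_p <- (1 + sum(null_t >= obs_t)) / (1 + 400)
  # agreement within Monte-Carlo error of the permutation estimate
  se <- sqrt(perm_p * (1 - perm_p) / 400)
  expect_lt(abs(obs_p - perm_p), 4 * se + 0.02)
})

test_that("model predictors and cluster markers are compared correctly", {
  co <- setNames(c(2, -1, 0.5), c("g1", "g2", "g3"))
  markers <- data.frame(group = rep("c1", 3), gene = c("g1", "g2", "g3"),
                        log2FC = c(3, 2, 1), pct_in = 1, pct_out = 0,
                        p = 0.01, p_adj = 0.01)
  ov <- model_vs_cluster_overlap(co, markers, top_n = 3)
  expect_equal(ov$overlap$n_overlap[ov$overlap$cluster == "c1"], 3)

  markers2 <- markers; markers2$gene <- c("x1", "x2", "x3")
  ov2 <- model_vs_cluster_overlap(co, markers2, top_n = 3)
  expect_equal(ov2$overlap$n_overlap[ov2$overlap$cluster == "c1"], 0)
})

test_that("orthogonal simulation: model genes disjoint from cluster markers", {
  ds <- simulate_multimodal_dataset(n_cce = 500, n_genes = 300,
                                    n_planted = 25, effect_size = 2,
                                    snr = 2.5, n_clusters = 3,
                                    cluster_shift = 1.5, n_cluster_genes = 25,
                                    orthogonal = TRUE, seed = 31)
  cfg <- model_config(seed = 31, bootstrap_reps = 50)
  ss <- stability_select(ds, "score", config = cfg)
  stable <- ss$feature[ss$stable]
  expect_gte(length(intersect(stable, ds$truth$planted)), 20)
  expect_lte(length(setdiff(stable, ds$truth$planted)), 2)
  markers <- differential_expression(ds$expression, ds$rna_cluster,
                                     min_pct = 0, logfc_threshold = 0)
  fit <- fit_elastic_net(ds, "score", config = cfg)
  co <- fit$coefficients[names(fit$coefficients) %in% stable]
  ov <- model_vs_cluster_overlap(co, markers, top_n = 20)
  expect_lte(ov$overlap$n_overlap[ov$overlap$cluster == "union"], 2)
})

test_that("elastic net at the mixing extremes matches ridge and lasso oracles", {
  set.seed(13)
  n <- 10; p <- 5
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  x <- scale(x)
  y <- as.vector(scale(rnorm(n) + x[, 1]))
  lambda <- 0.5
  # glmnet standardizes y internally by its population SD. The lasso solution
  # is scale-equivariant, so its penalty maps back to lambda unchanged; the
  # ridge solution is not, and maps to lambda / sd_n(y) on the original scale.
  sy <- sqrt(mean((y - mean(y))^2))
  lam <- lambda / sy
  # alpha = 0: closed-form ridge, b = (X'X/n + lam I)^-1 X'y/n
  b_ridge <- solve(crossprod(x) / n + lam * diag(p), crossprod(x, y) / n)
  g_ridge <- glmnet::glmnet(x, y, alpha = 0, lambda = lambda,
                            standardize = FALSE, intercept = FALSE,
                            thresh = 1e-14, maxit = 1e7)
  expect_equal(as.numeric(stats::coef(g_ridge))[-1], as.numeric(b_ridge),
               tolerance = 1e-6)
  # alpha = 1: coordinate-descent lasso oracle (independent implementation)
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  b <- rep(0, p)
  for (it in 1:5000) {
    for (j in 1:p) {
      r <- y - x[, -j, drop = FALSE] %*% b[-j]
      b[j] <- soft(mean(x[, j] * r), lambda) / mean(x[, j]^2)
    }
  }
  g_lasso <- glmnet::glmnet(x, y, alpha = 1, lambda = lambda,
                            standardize = FALSE, intercept = FALSE,
                            thresh = 1e-14, maxit = 1e7)
  expect_equal(as.numeric(stats::coef(g_lasso))[-1], b, tolerance = 1e-6)
})
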