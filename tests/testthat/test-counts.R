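# Spot->CCE assignment, aggregation, QC, barnyard, signatures, DE.

make_spot_counts <- function(counts) {
  spot_count_matrix(counts)
}

test_that("spot assignment follows the overlap geometry", {
  lay <- small_layout()
  cells <- simulate_lane_sample(lay, n_cells = 10, seed = 2)
  res <- place_spot_aware(cells, lay, seed = 2)
  asn <- assign_spots_to_cces(res, lay)
  # mapping keys are exactly the owned spots, verified by independent
  # geometric recomputation against every enclosure
  owned <- unlist(split_ids(res$enclosures$owned_spots))
  expect_setequal(asn$assignment$spot_id, owned)
  for (k in seq_len(nrow(asn$assignment))) {
    row <- asn$assignment[k, ]
    sp <- lay$spots[lay$spots$spot_id == row$spot_id, ]
    enc <- res$enclosures[res$enclosures$cce_id == row$cce_id, ]
    frac <- spot_overlap_fraction(sp, enc)
    expect_equal(frac, row$overlap_fraction, tolerance = 1e-12)
    expect_gte(frac, 0.25)
  }
  expect_setequal(c(asn$assignment$spot_id, asn$unmapped_spots),
                  lay$spots$spot_id)

  # a spot fully under a CCE maps to it; a far spot is unmapped
  one <- structure(list(
    enclosures = enclosure_set(lay$spots$x_um[1], lay$spots$y_um[1],
                               outer_diameter_um = 90),
    uncompartmentalized_cell_ids = character(0), iterations_used = 0L,
    converged = TRUE, mode = "unconstrained"), class = "placement_result")
  a1 <- assign_spots_to_cces(one, lay)
  expect_equal(a1$assignment$spot_id, lay$spots$spot_id[1])
  expect_true(all(lay$spots$spot_id[-1] %in% a1$unmapped_spots))
})

test_that("double-claimed spots raise an exclusivity error", {
  lay <- small_layout()
  enc <- enclosure_set(c(lay$spots$x_um[1] - 10, lay$spots$x_um[1] + 10),
                       rep(lay$spots$y_um[1], 2), outer_diameter_um = 90)
  res <- structure(list(enclosures = enc,
                        uncompartmentalized_cell_ids = character(0),
                        iterations_used = 0L, converged = TRUE,
                        mode = "unconstrained"), class = "placement_result")
  expect_error(assign_spots_to_cces(res, lay), "exclusivity")
})

test_that("aggregation sums assigned spot columns and conserves totals", {
  counts <- matrix(0L, 3, 4,
                   dimnames = list(c("g1", "g2", "MT-g3"),
                                   paste0("s", 1:4)))
  counts["g1", ] <- c(3L, 4L, 5L, 7L)
  counts["g2", ] <- c(1L, 0L, 2L, 0L)
  counts["MT-g3", ] <- c(0L, 1L, 0L, 2L)
  sc <- make_spot_counts(counts)
  asn <- data.frame(spot_id = c("s1", "s2", "s3"),
                    cce_id = c("c1", "c1", "c2"),
                    overlap_fraction = c(0.5, 1, 0.8))
  agg <- aggregate_counts(sc, asn)
  expect_equal(as.numeric(agg$counts["g1", "c1"]), 7)   # 3 + 4
  expect_equal(as.numeric(agg$counts["g1", "c2"]), 5)   # single spot: identity
  expect_equal(as.numeric(agg$counts[, "c2"]),
               as.numeric(counts[, "s3"]))
  # spot s4 is unassigned and excluded; totals conserved over mapped spots
  expect_equal(sum(agg$counts), sum(counts[, c("s1", "s2", "s3")]))
  expect_equal(agg$qc$n_spots, c(2L, 1L))
  expect_equal(agg$qc$spot_overlap_pct, c(75, 80))
  # unknown spot id errors
  bad <- rbind(asn, data.frame(spot_id = "nope", cce_id = "c3",
                               overlap_fraction = 1))
  expect_error(aggregate_counts(sc, bad), "absent")
})

test_that("count conservation holds exactly on random matrices", {
  set.seed(10)
  for (i in 1:25) {
    n_g <- 50; n_s <- 30
    counts <- matrix(rpois(n_g * n_s, 2), n_g, n_s,
                     dimnames = list(sprintf("g%02d", 1:n_g),
                                     sprintf("s%02d", 1:n_s)))
    sc <- make_spot_counts(counts)
    mapped <- sample(n_s, sample(5:n_s, 1))
    asn <- data.frame(spot_id = colnames(counts)[mapped],
                      cce_id = paste0("c", sample(1:8, length(mapped),
                                                  replace = TRUE)),
                      overlap_fraction = runif(length(mapped), 0.25, 1))
    agg <- aggregate_counts(sc, asn)
    expect_identical(as.numeric(sum(agg$counts)),
                     as.numeric(sum(counts[, mapped])))
  }
})

test_that("QC filter applies strict thresholds and is monotone", {
  counts <- matrix(c(100L, 500L), 1, 2,
                   dimnames = list("g1", c("c1", "c2")))
  qc <- data.frame(cce_id = c("c1", "c2"), total_transcripts = c(100, 500),
                   spot_overlap_pct = c(50, 50), mito_pct = c(5, 5),
                   n_spots = c(1L, 1L))
  m <- cce_count_matrix(counts, qc)
  kept <- qc_filter(m, min_total = 200, min_overlap_pct = 0,
                    max_mito_pct = 100)
  expect_equal(kept$cce_ids, "c2")
  # identity when no threshold binds
  ident <- qc_filter(m, min_total = 0, min_overlap_pct = 0,
                     max_mito_pct = 100)
  expect_equal(ident$cce_ids, c("c1", "c2"))

  # monotone in min_total on a random matrix
  set.seed(3)
  n <- 40
  cn <- sprintf("c%02d", 1:n)
  counts2 <- matrix(rpois(10 * n, 20), 10, n,
                    dimnames = list(sprintf("g%02d", 1:10), cn))
  qc2 <- data.frame(cce_id = cn, total_transcripts = colSums(counts2),
                    spot_overlap_pct = runif(n, 0, 100),
                    mito_pct = runif(n, 0, 30), n_spots = 1L)
  m2 <- cce_count_matrix(counts2, qc2)
  survivors <- vapply(seq(0, 300, by = 25), function(thr)
    length(qc_filter(m2, thr, 0, 100)$cce_ids), 0L)
  expect_true(all(diff(survivors) <= 0))
})

test_that("barnyard assignment uses the species log-ratio with margin", {
  genes <- c("HUM1", "HUM2", "MOU1", "MOU2")
  ann <- data.frame(gene = genes, species = c("human", "human", "mouse",
                                              "mouse"),
                    mito = FALSE)
  counts <- matrix(c(495L, 495L, 5L, 5L,     # human-dominated
                     10L, 10L, 10L, 10L),    # equal
                   4, 2, dimnames = list(genes, c("c1", "c2")))
  m <- cce_count_matrix(counts, data.frame(
    cce_id = c("c1", "c2"), total_transcripts = colSums(counts),
    spot_overlap_pct = 100, mito_pct = 0, n_spots = 1L), ann)
  lab <- classify_species_barnyard(m, delta = 1)
  expect_equal(lab$label, c("human", "undetermined"))

  # symmetry: swapping species annotations swaps the labels
  ann2 <- ann; ann2$species <- c("mouse", "mouse", "human", "human")
  m2 <- cce_count_matrix(counts, m$qc, ann2)
  lab2 <- classify_species_barnyard(m2, delta = 1)
  expect_equal(lab2$label, c("mouse", "undetermined"))

  ann3 <- ann; ann3$species <- NA_character_
  m3 <- cce_count_matrix(counts, m$qc, ann3)
  expect_error(classify_species_barnyard(m3), "species")
})

test_that("signature scores scale to [0,1] and assign by argmax", {
  # 10 CCEs expressing only type-A signature genes are assigned A
  prog <- simulate_programs(n_genes = 100, types = c("A", "B"),
                            n_markers_per_type = 8, marker_fold = 50,
                            seed = 3)
  ct <- setNames(rep(c("A", "B"), each = 10), sprintf("cce_%02d", 1:20))
  sim <- simulate_counts(cce_types = ct, programs = prog$programs,
                         cce_ids = names(ct), depth = 3000, seed = 4)
  agg <- aggregate_counts(sim$spot_counts, sim$truth$assignment)
  sc <- score_signatures(agg, prog$markers, seed = 1)
  expect_equal(sc$assigned_type, unname(ct[sc$cce_id]))
  # min-max scaling: each signature column spans exactly [0, 1]
  expect_equal(min(sc$A), 0); expect_equal(max(sc$A), 1)
  expect_equal(min(sc$B), 0); expect_equal(max(sc$B), 1)
  expect_warning(expect_error(score_signatures(agg, list(A = "NOT_A_GENE")),
                              "no genes"),
                 "dropped")
})

test_that("three-type mixture proportions are recovered within binomial error", {
  mix <- c(A = 0.5, B = 0.3, C = 0.2)
  n <- 300
  prog <- simulate_programs(n_genes = 150, types = names(mix),
                            n_markers_per_type = 10, marker_fold = 30,
                            seed = 5)
  set.seed(6)
  ct <- setNames(sample(names(mix), n, replace = TRUE, prob = mix),
                 sprintf("cce_%03d", 1:n))
  sim <- simulate_counts(cce_types = ct, programs = prog$programs,
                         depth = 3000, seed = 7)
  agg <- aggregate_counts(sim$spot_counts, sim$truth$assignment)
  sc <- score_signatures(agg, prog$markers, seed = 1)
  est <- table(factor(sc$assigned_type, levels = names(mix))) / n
  truth <- table(factor(ct, levels = names(mix))) / n
  for (t in names(mix)) {
    se <- sqrt(truth[[t]] * (1 - truth[[t]]) / n)
    expect_lt(abs(est[[t]] - truth[[t]]), 3 * se + 0.02)
  }
})

test_that("differential expression recovers planted markers and filters", {
  # two groups with disjoint high-expression genes (planted log2FC ~ 6)
  set.seed(8)
  n_per <- 30
  genes <- sprintf("g%03d", 1:60)
  base <- matrix(rpois(60 * 2 * n_per, 1), 60, 2 * n_per,
                 dimnames = list(genes, sprintf("c%03d", 1:(2 * n_per))))
  grp <- rep(c("A", "B"), each = n_per)
  base[1:5, grp == "A"] <- rpois(5 * n_per, 200)
  base[6:10, grp == "B"] <- rpois(5 * n_per, 200)
  qc <- data.frame(cce_id = colnames(base),
                   total_transcripts = colSums(base),
                   spot_overlap_pct = 100, mito_pct = 0, n_spots = 1L)
  m <- cce_count_matrix(base, qc)
  de <- differential_expression(m, grp, min_pct = 0.25, logfc_threshold = 0.5)
  planted_a <- de[de$group == "A" & de$gene %in% genes[1:5], ]
  expect_equal(nrow(planted_a), 5)
  expect_true(all(planted_a$p_adj <= 0.01))
  expect_true(all(planted_a$log2FC >= 5))

  # a gene expressed in 10% of the group fails min_pct = 0.25
  pct_gene <- matrix(0L, 1, 2 * n_per,
                     dimnames = list("rare", colnames(base)))
  pct_gene[1, which(grp == "A")[1:3]] <- 50L
  m2 <- cce_count_matrix(rbind(base, pct_gene), qc)
  de2 <- differential_expression(m2, grp, min_pct = 0.25,
                                 logfc_threshold = 0)
  expect_false("rare" %in% de2$gene[de2$group == "A"])

  expect_error(differential_expression(m, rep("A", 2 * n_per)), "2 groups")
})

test_that("identical groups produce no significant genes", {
  hits <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    counts <- matrix(rnbinom(80 * 40, size = 2, mu = 8), 80, 40,
                     dimnames = list(sprintf("g%03d", 1:80),
                                     sprintf("c%03d", 1:40)))
    qc <- data.frame(cce_id = colnames(counts),
                     total_transcripts = colSums(counts),
                     spot_overlap_pct = 100, mito_pct = 0, n_spots = 1L)
    m <- cce_count_matrix(counts, qc)
    de <- differential_expression(m, rep(c("A", "B"), 20), min_pct = 0,
                                  logfc_threshold = 0)
    if (any(de$p_adj < 0.05)) hits <- hits + 1
  }
  expect_lte(hits, 1)   # >= 95% of seeds clean, allowing one false alarm
})

test_that("wilcoxon null type-I error is calibrated", {
  set.seed(11)
  n_genes <- 200
  counts <- matrix(rnbinom(n_genes * 60, size = 2, mu = 10), n_genes, 60,
                   dimnames = list(sprintf("g%03d", 1:n_genes),
                                   sprintf("c%03d", 1:60)))
  qc <- data.frame(cce_id = colnames(counts),
                   total_transcripts = colSums(counts),
                   spot_overlap_pct = 100, mito_pct = 0, n_spots = 1L)
  m <- cce_count_matrix(counts, qc)
  de <- differential_expression(m, rep(c("A", "B"), 30), min_pct = 0,
                                logfc_threshold = 0)
  deA <- de[de$group == "A", ]
  rate <- mean(deA$p < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(deA))
  expect_lt(abs(rate - 0.05), 3 * se + 0.01)
})
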