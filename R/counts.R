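# Spot-level and CCE-level count containers, spot->CCE assignment, count
# aggregation with QC, barnyard species assignment, normalization, signature
# scoring and rank-based differential expression.

#' Gene x spot count matrix
#'
#' @param counts Non-negative integer matrix or `Matrix::sparseMatrix`
#'   (genes x spots) with dimnames.
#' @param gene_annotations Data frame with columns `gene`, `species`, `mito`
#'   covering every gene; defaults to single-species with `MT-` prefix
#'   flagging mitochondrial genes.
#' @return Object of class `spot_count_matrix`.
#' @export
spot_count_matrix <- function(counts, gene_annotations = NULL) {
  counts <- methods::as(methods::as(methods::as(
    Matrix::Matrix(counts, sparse = TRUE),
    "CsparseMatrix"), "generalMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and spot colnames")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be non-negative integers")
  if (is.null(gene_annotations))
    gene_annotations <- data.frame(gene = rownames(counts), species = "human",
                                   mito = startsWith(rownames(counts), "MT-"),
                                   stringsAsFactors = FALSE)
  if (!all(rownames(counts) %in% gene_annotations$gene))
    stop("gene_annotations must cover every gene in the matrix")
  gene_annotations <- gene_annotations[match(rownames(counts),
                                             gene_annotations$gene), ]
  structure(list(counts = counts, genes = rownames(counts),
                 spots = colnames(counts),
                 gene_annotations = gene_annotations),
            class = "spot_count_matrix")
}

#' @export
print.spot_count_matrix <- function(x, ...) {
  cat(sprintf("<spot_count_matrix> %d genes x %d spots, %d nonzeros\n",
              length(x$genes), length(x$spots), length(x$counts@x)))
  invisible(x)
}

#' Gene x CCE count matrix with per-CCE QC metadata
#'
#' @param counts Integer matrix (genes x CCEs).
#' @param qc Data frame with one row per CCE: `cce_id`, `total_transcripts`,
#'   `spot_overlap_pct`, `mito_pct`, `n_spots`.
#' @param gene_annotations As in [spot_count_matrix()].
#' @return Object of class `cce_count_matrix`.
#' @export
cce_count_matrix <- function(counts, qc, gene_annotations = NULL) {
  cn <- colnames(counts)
  counts <- methods::as(methods::as(methods::as(
    Matrix::Matrix(counts, sparse = TRUE),
    "CsparseMatrix"), "generalMatrix"), "dMatrix")
  if (is.null(colnames(counts))) colnames(counts) <- cn %||% character(0)
  stopifnot(identical(as.character(colnames(counts) %||% character(0)),
                      as.character(qc$cce_id)))
  if (is.null(gene_annotations))
    gene_annotations <- data.frame(gene = rownames(counts), species = "human",
                                   mito = startsWith(rownames(counts), "MT-"),
                                   stringsAsFactors = FALSE)
  structure(list(counts = counts, genes = rownames(counts),
                 cce_ids = colnames(counts), qc = qc,
                 gene_annotations = gene_annotations),
            class = "cce_count_matrix")
}

#' @export
print.cce_count_matrix <- function(x, ...) {
  cat(sprintf("<cce_count_matrix> %d genes x %d CCEs (median total %g)\n",
              length(x$genes), length(x$cce_ids),
              stats::median(x$qc$total_transcripts)))
  invisible(x)
}

#' Assign capture spots to CCEs by geometric overlap
#'
#' Recomputes spot/CCE overlap fractions from the placement geometry and maps
#' every spot whose overlap with a CCE outer footprint is at least
#' `min_overlap` to that CCE. Spot exclusivity is asserted: two CCEs above
#' threshold on the same spot is a placement bug and raises an error.
#'
#' @param placement A `placement_result`.
#' @param layout The `lane_layout`.
#' @param min_overlap Minimum overlap fraction (default 0.25).
#' @return List: `assignment` (data frame `spot_id`, `cce_id`,
#'   `overlap_fraction`), `unmapped_spots` (character).
#' @export
assign_spots_to_cces <- function(placement, layout, min_overlap = 0.25) {
  enc <- placement$enclosures
  spots <- layout$spots
  if (nrow(enc) == 0)
    return(list(assignment = data.frame(spot_id = character(0),
                                        cce_id = character(0),
                                        overlap_fraction = numeric(0)),
                unmapped_spots = spots$spot_id))
  reach <- max(enc$outer_diameter_um) / 2 + max(spots$diameter_um) / 2
  gi <- grid_index(spots$x_um, spots$y_um, reach)
  rows <- list()
  for (k in seq_len(nrow(enc))) {
    sp <- grid_query(gi, enc$x_um[k], enc$y_um[k])
    if (!length(sp)) next
    frac <- spot_overlap_fraction_xy(spots$x_um[sp], spots$y_um[sp],
                                     spots$diameter_um[sp] / 2,
                                     enc$x_um[k], enc$y_um[k],
                                     enc$outer_diameter_um[k] / 2)
    sel <- frac >= min_overlap
    if (any(sel))
      rows[[length(rows) + 1]] <- data.frame(
        spot_id = spots$spot_id[sp[sel]], cce_id = enc$cce_id[k],
        overlap_fraction = frac[sel], stringsAsFactors = FALSE)
  }
  assignment <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spot_id = character(0), cce_id = character(0),
               overlap_fraction = numeric(0))
  dup <- unique(assignment$spot_id[duplicated(assignment$spot_id)])
  if (length(dup))
    stop("spot exclusivity violated (placement bug): spots claimed by ",
         "multiple CCEs: ", paste(utils::head(dup, 5), collapse = ", "))
  list(assignment = assignment,
       unmapped_spots = setdiff(spots$spot_id, assignment$spot_id))
}

#' Aggregate spot counts to CCE level
#'
#' Sums, per gene, the transcript counts of all capture spots assigned to the
#' same CCE. Unassigned spots are excluded. QC metadata is computed per CCE:
#' total transcripts, percent spot overlap (mean overlap fraction of its
#' assigned spots x 100), mitochondrial read percentage, and number of spots.
#'
#' @param spot_counts A `spot_count_matrix`.
#' @param assignment Data frame `spot_id`, `cce_id`, `overlap_fraction` (the
#'   `assignment` element of [assign_spots_to_cces()]).
#' @return A `cce_count_matrix`.
#' @export
aggregate_counts <- function(spot_counts, assignment) {
  unknown <- setdiff(assignment$spot_id, spot_counts$spots)
  if (length(unknown))
    stop("assignment refers to spot ids absent from the count matrix: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  cces <- unique(assignment$cce_id)
  # indicator matrix spots x CCEs; aggregation = one sparse multiply
  ind <- Matrix::sparseMatrix(
    i = match(assignment$spot_id, spot_counts$spots),
    j = match(assignment$cce_id, cces),
    x = 1, dims = c(length(spot_counts$spots), length(cces)),
    dimnames = list(spot_counts$spots, cces))
  agg <- spot_counts$counts %*% ind
  total <- Matrix::colSums(agg)
  mito <- spot_counts$gene_annotations$mito
  mito_total <- if (any(mito))
    Matrix::colSums(agg[mito, , drop = FALSE]) else rep(0, length(cces))
  ov <- vapply(split(assignment$overlap_fraction, assignment$cce_id)[cces],
               mean, 0)
  n_spots <- vapply(split(assignment$spot_id, assignment$cce_id)[cces],
                    length, 0L)
  qc <- data.frame(cce_id = cces, total_transcripts = total,
                   spot_overlap_pct = 100 * ov,
                   mito_pct = ifelse(total > 0, 100 * mito_total / total, 0),
                   n_spots = n_spots, stringsAsFactors = FALSE)
  rownames(qc) <- NULL
  cce_count_matrix(agg, qc, spot_counts$gene_annotations)
}

#' Quality-control filter on CCE-level counts
#'
#' Retains CCEs with total transcripts strictly above `min_total`, percent
#' capture-spot overlap strictly above `min_overlap_pct`, and mitochondrial
#' read percentage strictly below `max_mito_pct`. All three thresholds are
#' experiment-dependent and therefore required arguments.
#'
#' @param m A `cce_count_matrix`.
#' @param min_total Minimum total transcripts (exclusive).
#' @param min_overlap_pct Minimum spot overlap percent (exclusive).
#' @param max_mito_pct Maximum mitochondrial percent (exclusive).
#' @return The filtered `cce_count_matrix`; the filter report (counts removed
#'   per criterion) is attached as attribute `"filter_report"`.
#' @export
qc_filter <- function(m, min_total, min_overlap_pct, max_mito_pct) {
  stopifnot(is.finite(min_total), is.finite(min_overlap_pct),
            is.finite(max_mito_pct))
  keep_total <- m$qc$total_transcripts > min_total
  keep_overlap <- m$qc$spot_overlap_pct > min_overlap_pct
  keep_mito <- m$qc$mito_pct < max_mito_pct
  keep <- keep_total & keep_overlap & keep_mito
  out <- cce_count_matrix(m$counts[, keep, drop = FALSE],
                          m$qc[keep, , drop = FALSE], m$gene_annotations)
  attr(out, "filter_report") <- data.frame(
    criterion = c("total_transcripts", "spot_overlap_pct", "mito_pct"),
    threshold = c(min_total, min_overlap_pct, max_mito_pct),
    failed = c(sum(!keep_total), sum(!keep_overlap), sum(!keep_mito)),
    kept = sum(keep))
  out
}

#' Barnyard species assignment from the species read log-ratio
#'
#' Each CCE is assigned to a species when the log10 ratio of its reads from
#' the two species (pseudocount 1 on both) clears the margin `delta`;
#' otherwise it is `"undetermined"`. Species are taken from the gene
#' annotations; exactly two must be present.
#'
#' @param m A `cce_count_matrix` whose `gene_annotations$species` has two
#'   levels.
#' @param delta Log10-ratio margin (default 1, i.e. 10-fold).
#' @return Data frame: `cce_id`, counts per species, `log_ratio`, `label`.
#' @export
classify_species_barnyard <- function(m, delta = 1) {
  sp <- m$gene_annotations$species
  if (anyNA(sp)) stop("every gene needs a species annotation")
  lv <- sort(unique(sp))
  if (length(lv) != 2)
    stop("barnyard classification needs exactly 2 species, got: ",
         paste(lv, collapse = ", "))
  a <- Matrix::colSums(m$counts[sp == lv[1], , drop = FALSE])
  b <- Matrix::colSums(m$counts[sp == lv[2], , drop = FALSE])
  lr <- log10((a + 1) / (b + 1))
  label <- ifelse(lr >= delta, lv[1], ifelse(lr <= -delta, lv[2],
                                             "undetermined"))
  out <- data.frame(cce_id = m$cce_ids, log_ratio = lr, label = label,
                    stringsAsFactors = FALSE)
  out[[lv[1]]] <- a; out[[lv[2]]] <- b
  rownames(out) <- NULL
  out
}

#' Normalize CCE counts
#'
#' Per-CCE library-size scaling to the median total, then `log1p`. A simple
#' deterministic normalization sufficient for the rank-based and linear
#' statistics implemented here.
#'
#' @param m A `cce_count_matrix`.
#' @param log Apply `log1p` after scaling (default `TRUE`; `FALSE` keeps the
#'   linear median-scaled values used for fold changes).
#' @return Sparse genes x CCEs matrix of normalized expression.
#' @export
normalize_cce_counts <- function(m, log = TRUE) {
  totals <- Matrix::colSums(m$counts)
  target <- stats::median(totals[totals > 0])
  sf <- ifelse(totals > 0, target / totals, 0)
  out <- m$counts %*% Matrix::Diagonal(x = sf)
  dimnames(out) <- dimnames(m$counts)
  if (log) out@x <- log1p(out@x)
  out
}

# Expression-matched control genes: bin genes by mean expression into n_bins
# rank bins; sample (seeded) n_control controls per signature gene from its
# bin. The module-score construction used for signatures and modules.
control_gene_sets <- function(mean_expr, signature_idx, n_bins = 25,
                              n_control = 100, seed = 0L) {
  bins <- cut(rank(mean_expr, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  with_seed(seed, {
    unique(unlist(lapply(signature_idx, function(g) {
      pool <- which(bins == bins[g])
      pool[sample.int(length(pool), min(n_control, length(pool)))]
    })))
  })
}

#' Per-CCE signature (module) scores and cell-type assignment
#'
#' For each gene set, the score of a CCE is the mean normalized expression of
#' the signature genes minus the mean over an expression-matched control gene
#' set (genes binned into `n_bins` mean-expression bins; controls sampled from
#' the signature genes' bins with a fixed seed). Scores are min-max scaled to
#' `[0, 1]` across CCEs per signature, and each CCE is assigned to the
#' signature with the largest scaled score.
#'
#' @param m A `cce_count_matrix`, or a pre-normalized genes x CCEs matrix.
#' @param signatures Named list of gene-id vectors.
#' @param n_bins,n_control Control-matching parameters.
#' @param scale_scores Min-max scale to `[0, 1]` (default `TRUE`; raw module
#'   scores when `FALSE`, as used for interaction modelling).
#' @param seed Seed for control sampling.
#' @return Data frame: `cce_id`, one score column per signature,
#'   `assigned_type`.
#' @export
score_signatures <- function(m, signatures, n_bins = 25, n_control = 100,
                             scale_scores = TRUE, seed = 0L) {
  X <- if (inherits(m, "cce_count_matrix")) normalize_cce_counts(m) else m
  if (!length(signatures)) stop("no signatures given")
  genes <- rownames(X)
  sig_idx <- lapply(names(signatures), function(nm) {
    idx <- match(signatures[[nm]], genes)
    if (anyNA(idx))
      warning(sum(is.na(idx)), " signature gene(s) of ", nm,
              " absent from the matrix; dropped")
    idx <- idx[!is.na(idx)]
    if (!length(idx)) stop("signature ", nm, " has no genes in the matrix")
    idx
  })
  names(sig_idx) <- names(signatures)
  mean_expr <- Matrix::rowMeans(X)
  scores <- vapply(names(sig_idx), function(nm) {
    si <- sig_idx[[nm]]
    ctrl <- control_gene_sets(mean_expr, si, n_bins, n_control, seed)
    s <- Matrix::colMeans(X[si, , drop = FALSE]) -
      Matrix::colMeans(X[ctrl, , drop = FALSE])
    if (scale_scores) {
      rng <- range(s)
      s <- if (diff(rng) > 0) (s - rng[1]) / diff(rng) else rep(0, length(s))
    }
    s
  }, numeric(ncol(X)))
  assigned <- names(sig_idx)[max.col(scores, ties.method = "first")]
  out <- data.frame(cce_id = colnames(X), scores, assigned_type = assigned,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank-based differential expression (group vs rest)
#'
#' Per-gene Wilcoxon rank-sum test of normalized expression, each group
#' against all others. Genes are pre-filtered: the fraction of expressing
#' (nonzero) CCEs in the group must reach `min_pct` and |log2 fold change|
#' must reach `logfc_threshold`, where log2FC is computed on mean normalized
#' expression (linear, median-scaled) with pseudocount 1. Benjamini-Hochberg
#' adjustment within group. When `m` is a plain matrix its values are used
#' as-is for both the means and the ranks.
#'
#' @param m A `cce_count_matrix` or a normalized genes x CCEs matrix.
#' @param groups Factor/character of group labels, one per CCE.
#' @param min_pct Minimum expressing fraction in the group (default 0.25).
#' @param logfc_threshold Minimum |log2FC| (default 0.5).
#' @param only_pos Keep only positive-log2FC genes (default `FALSE`).
#' @return Data frame: `group`, `gene`, `log2FC`, `pct_in`, `pct_out`, `p`,
#'   `p_adj`.
#' @export
differential_expression <- function(m, groups, min_pct = 0.25,
                                    logfc_threshold = 0.5,
                                    only_pos = FALSE) {
  X <- if (inherits(m, "cce_count_matrix"))
    normalize_cce_counts(m, log = FALSE) else m
  groups <- as.factor(groups)
  stopifnot(ncol(X) == length(groups))
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 3)) stop("every group needs at least 3 CCEs")
  Xd <- as.matrix(X)
  out <- list()
  for (g in levels(groups)) {
    ing <- groups == g
    mean_in <- rowMeans(Xd[, ing, drop = FALSE])
    mean_out <- rowMeans(Xd[, !ing, drop = FALSE])
    l2fc <- log2((mean_in + 1) / (mean_out + 1))
    pct_in <- rowMeans(Xd[, ing, drop = FALSE] > 0)
    pct_out <- rowMeans(Xd[, !ing, drop = FALSE] > 0)
    keep <- pct_in >= min_pct & abs(l2fc) >= logfc_threshold
    if (only_pos) keep <- keep & l2fc > 0
    ki <- which(keep)
    if (!length(ki)) next
    p <- vapply(ki, function(i)
      stats::wilcox.test(Xd[i, ing], Xd[i, !ing], exact = FALSE)$p.value,
      0)
    out[[g]] <- data.frame(group = g, gene = rownames(Xd)[ki],
                           log2FC = l2fc[ki], pct_in = pct_in[ki],
                           pct_out = pct_out[ki], p = p,
                           p_adj = stats::p.adjust(p, "BH"),
                           stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(group = character(0), gene = character(0), log2FC = numeric(0),
               pct_in = numeric(0), pct_out = numeric(0), p = numeric(0),
               p_adj = numeric(0))
  rownames(res) <- NULL
  res
}
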