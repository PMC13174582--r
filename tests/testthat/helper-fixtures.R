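# Shared fixtures and independent oracles used across the suite.

# Small single-field layout: 600 x 450 um, 12 spots on a 150 um pitch.
small_layout <- function(width_um = 600, height_um = 450, pitch = 150,
                         spot_d = 50) {
  build_lane_layout(width_um = width_um, height_um = height_um, n_fields = 1,
                    spot_pitch_um = pitch, spot_diameter_um = spot_d)
}

# Monte-Carlo oracle for the spot/CCE overlap fraction: uniform points in the
# spot disk, fraction falling inside the CCE outer disk.
mc_overlap_fraction <- function(sx, sy, sr, cx, cy, cr, n = 1e6, seed = 42) {
  set.seed(seed)
  th <- runif(n, 0, 2 * pi)
  rr <- sr * sqrt(runif(n))
  px <- sx + rr * cos(th); py <- sy + rr * sin(th)
  mean((px - cx)^2 + (py - cy)^2 <= cr^2)
}

# Independent truth table for the trajectory phenotype rules (nested ifs coded
# straight from the class definitions, no shared code with the classifier).
truth_table_label <- function(live, dead, mean_area, thr = 15000) {
  last <- length(live)
  if (mean_area >= thr) return("proliferation")
  if (dead[last] >= 1 && live[last] >= 1) return("daughter_cell_resistant")
  if (all(live == 1)) return("cell_cycle_arrest")
  if (live[last] == 0 && dead[last] >= 1) return("dead")
  if (live[last] >= 1) return("proliferation")
  "unclassified"
}

# Adjusted Rand index (independent implementation for clustering checks).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_ind <- sum_a * sum_b / n
  (sum_ij - exp_ind) / ((sum_a + sum_b) / 2 - exp_ind)
}

# Brute-force GSEA enrichment score by explicit cumulative sum (oracle).
brute_force_es <- function(stats_vec, gene_set) {
  s <- sort(stats_vec, decreasing = TRUE)
  running <- 0
  best <- 0
  nh <- sum(names(s) %in% gene_set)
  nm <- length(s) - nh
  denom <- sum(abs(s)[names(s) %in% gene_set])
  for (g in names(s)) {
    if (g %in% gene_set) {
      running <- running + (if (denom > 0) abs(s[[g]]) / denom else 1 / nh)
    } else {
      running <- running - 1 / nm
    }
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# A tiny labelled mask: one rectangular instance on constant background.
toy_mask <- function(obj_val = 50, bg_val = 10) {
  lab <- matrix(0L, 30, 30)
  lab[10:15, 12:20] <- 1L
  ch <- matrix(bg_val, 30, 30)
  ch[lab == 1L] <- obj_val
  instance_mask(lab, list(gfp = ch))
}

# Random multi-instance mask with non-touching rectangles and noisy channels.
random_mask <- function(seed, n_obj = 3, dim_px = 40) {
  set.seed(seed)
  lab <- matrix(0L, dim_px, dim_px)
  slots <- sample(0:(n_obj * 2 - 1), n_obj)   # disjoint vertical bands
  band <- floor(dim_px / (n_obj * 2))
  for (i in seq_len(n_obj)) {
    r0 <- slots[i] * band + 2
    lab[r0:(r0 + band - 3), sample(3:(dim_px - 8), 1) + 0:4] <- i
  }
  ch <- matrix(runif(dim_px^2, 0, 255), dim_px, dim_px)
  instance_mask(lab, list(ch1 = ch))
}

# Disk-shaped single-instance mask (for shape-feature tests).
disk_mask <- function(radius_px, dim_px = 2 * radius_px + 9, intensity = NULL,
                      ax = 1, ay = 1) {
  ctr <- (dim_px + 1) / 2
  xx <- matrix(rep(seq_len(dim_px), each = dim_px), dim_px)
  yy <- matrix(rep(seq_len(dim_px), dim_px), dim_px)
  lab <- matrix(0L, dim_px, dim_px)
  lab[((xx - ctr) / ax)^2 + ((yy - ctr) / ay)^2 <= radius_px^2] <- 1L
  ch <- if (is.null(intensity)) matrix(0, dim_px, dim_px) else intensity
  instance_mask(lab, list(ch1 = ch))
}
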