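# Placement algorithms, overlap resolution, validation, and the small-instance
# baselines.

test_that("an isolated cell gets one CCE centred on it", {
  lay <- small_layout()
  cells <- cell_records(300, 225, radius_um = 8)
  res <- place_unconstrained(cells, lay)
  expect_equal(nrow(res$enclosures), 1)
  expect_equal(res$enclosures$x_um, 300)
  expect_equal(res$enclosures$y_um, 225)
  expect_true(res$converged)

  # empty field
  empty <- place_unconstrained(cells[0, ], lay)
  expect_equal(nrow(empty$enclosures), 0)
  expect_equal(length(empty$uncompartmentalized_cell_ids), 0)
})

test_that("unconstrained placement is feasible and keeps isolated cells", {
  lay <- build_lane_layout(width_um = 500, height_um = 500, n_fields = 1,
                           spot_pitch_um = 150, spot_diameter_um = 50)
  cells <- simulate_lane_sample(lay, n_cells = 50, seed = 21)
  res <- place_unconstrained(cells, lay)
  v <- validate_placement(res, lay, cells)
  expect_equal(nrow(v), 0)
  # exhaustive pairwise-distance check: cells without a neighbour within
  # 2 x outer diameter must all be compartmentalized
  d <- as.matrix(dist(cells[, c("x_um", "y_um")]))
  diag(d) <- Inf
  iso <- cells$cell_id[apply(d, 1, min) > 2 * 90 &
                         cells$x_um >= 45 & cells$x_um <= 455 &
                         cells$y_um >= 45 & cells$y_um <= 455]
  placed <- unlist(split_ids(res$enclosures$member_cells))
  expect_true(all(iso %in% placed))
})

test_that("spot-aware placement owns spots and respects exclusivity", {
  lay <- small_layout()
  # one cell directly over one spot, no neighbours
  sp <- lay$spots[1, ]
  cells <- cell_records(sp$x_um, sp$y_um, radius_um = 8)
  res <- place_spot_aware(cells, lay)
  expect_equal(nrow(res$enclosures), 1)
  expect_true(sp$spot_id %in% split_ids(res$enclosures$owned_spots)[[1]])
  # the centred candidate collides only with the spot itself
  cc <- count_collisions(cells, lay)
  expect_equal(cc$n_collisions, 1L)

  # two cells reachable only from one spot -> exactly one placed
  lay1 <- build_lane_layout(width_um = 400, height_um = 400, n_fields = 1,
                            spot_pitch_um = 399, spot_diameter_um = 50)
  expect_equal(nrow(lay1$spots), 1)
  sp1 <- lay1$spots[1, ]
  cells2 <- cell_records(c(sp1$x_um - 20, sp1$x_um + 20),
                         c(sp1$y_um, sp1$y_um), radius_um = 8)
  res2 <- place_spot_aware(cells2, lay1)
  expect_equal(nrow(res2$enclosures), 1)
  expect_equal(length(res2$uncompartmentalized_cell_ids), 1)
})

test_that("spot-aware placement beats or ties the naive greedy baseline", {
  lay <- build_lane_layout(width_um = 1000, height_um = 1000, n_fields = 1,
                           spot_pitch_um = 170, spot_diameter_um = 50)
  for (s in 1:10) {
    cells <- simulate_lane_sample(lay, n_cells = 20, seed = 300 + s)
    h <- nrow(place_spot_aware(cells, lay, seed = s)$enclosures)
    g <- nrow(greedy_baseline_placement(cells, lay)$enclosures)
    expect_gte(h, g)
  }
})

test_that("placement is deterministic given inputs and seed", {
  lay <- small_layout()
  cells <- simulate_lane_sample(lay, n_cells = 40, seed = 5)
  a <- place_spot_aware(cells, lay, seed = 9)
  b <- place_spot_aware(cells, lay, seed = 9)
  expect_identical(a, b)
  u1 <- place_unconstrained(cells, lay, seed = 9)
  u2 <- place_unconstrained(cells, lay, seed = 9)
  expect_identical(u1, u2)
})

test_that("isolated cells with a free spot in reach are all compartmentalized", {
  # cells pairwise farther than 2 x outer diameter, each sitting on a spot
  lay <- build_lane_layout(width_um = 1200, height_um = 1200, n_fields = 1,
                           spot_pitch_um = 200, spot_diameter_um = 50)
  sp <- lay$spots[c(1, 8, 15, 22, 29, 36), ]
  d <- as.matrix(dist(sp[, c("x_um", "y_um")])); diag(d) <- Inf
  stopifnot(min(d) > 180)
  cells <- cell_records(sp$x_um, sp$y_um, radius_um = 8)
  res <- place_spot_aware(cells, lay)
  expect_equal(nrow(res$enclosures), nrow(cells))
  expect_equal(length(res$uncompartmentalized_cell_ids), 0)
})

test_that("overlap resolution separates two CCEs and fixes non-overlapping input", {
  enc <- enclosure_set(c(100, 180), c(100, 100), outer_diameter_um = 90,
                       wall_thickness_um = 10)
  out <- resolve_overlaps(enc)
  d <- sqrt(diff(out$enclosures$x_um)^2 + diff(out$enclosures$y_um)^2)
  expect_gte(d, 90 - 0.5)
  expect_true(out$converged)

  # closed-form symmetric repulsion: both move half the overlap depth along
  # the centre line in the first iteration, meeting the target exactly
  expect_equal(out$enclosures$x_um, c(95, 185), tolerance = 1e-9)

  # non-overlapping input is a fixed point
  apart <- enclosure_set(c(0, 200), c(0, 0), outer_diameter_um = 90)
  fixed <- resolve_overlaps(apart)
  expect_equal(fixed$enclosures$x_um, c(0, 200))
  expect_equal(fixed$iterations, 0L)
  expect_true(fixed$converged)
})

test_that("immovable mutually overlapping CCEs are dropped until feasible", {
  # member cells fill the whole lumen: any move breaks containment
  xs <- c(100, 150, 125); ys <- c(100, 100, 143)
  cells <- cell_records(xs, ys, radius_um = 35)   # lumen radius exactly 35
  enc <- enclosure_set(xs, ys, outer_diameter_um = 90, wall_thickness_um = 10,
                       member_cells = cells$cell_id)
  out <- resolve_overlaps(enc, cells = cells, max_iter = 20)
  expect_false(out$converged)
  expect_gt(length(out$dropped_cce_ids), 0)
  # remaining set is feasible (exhaustive pairwise check on <= 3 CCEs)
  e <- out$enclosures
  if (nrow(e) > 1) {
    d <- as.matrix(dist(e[, c("x_um", "y_um")])); diag(d) <- Inf
    expect_true(all(d >= 90 - 0.5))
  }
  # members of kept CCEs still inside their lumen
  for (k in seq_len(nrow(e))) {
    ci <- match(split_ids(e$member_cells)[[k]], cells$cell_id)
    dd <- sqrt((cells$x_um[ci] - e$x_um[k])^2 + (cells$y_um[ci] - e$y_um[k])^2)
    expect_true(all(dd + cells$radius_um[ci] <= 35 + 1e-6))
  }
})

test_that("validate_placement reports hand-built violations", {
  lay <- small_layout()
  # two CCEs owning the same spot
  sp <- lay$spots$spot_id[1]
  enc <- enclosure_set(c(100, 300), c(100, 300), outer_diameter_um = 90,
                       owned_spots = c(sp, sp))
  res <- new_res <- structure(list(enclosures = enc,
                                   uncompartmentalized_cell_ids = character(0),
                                   iterations_used = 0L, converged = TRUE,
                                   mode = "unconstrained"),
                              class = "placement_result")
  v <- validate_placement(res, lay)
  expect_true("spot_double_ownership" %in% v$type)
  expect_equal(sum(v$type == "spot_double_ownership"), 1)

  # cell centre 40 um from CCE centre with lumen radius 35 -> containment
  cells <- cell_records(140, 100, radius_um = 5)
  enc2 <- enclosure_set(100, 100, outer_diameter_um = 90,
                        wall_thickness_um = 10,
                        member_cells = cells$cell_id)
  res2 <- structure(list(enclosures = enc2,
                         uncompartmentalized_cell_ids = character(0),
                         iterations_used = 0L, converged = TRUE,
                         mode = "unconstrained"),
                    class = "placement_result")
  v2 <- validate_placement(res2, lay, cells)
  expect_true("cell_outside_lumen" %in% v2$type)
})

test_that("feasibility holds across seeds and densities", {
  lay <- build_lane_layout(width_um = 900, height_um = 600, n_fields = 1,
                           spot_pitch_um = 150, spot_diameter_um = 50)
  for (dens in c(50, 300, 1000)) {
    for (s in 1:5) {
      cells <- simulate_lane_sample(lay, density_per_mm2 = dens,
                                    seed = s * 31 + dens)
      res <- place_spot_aware(cells, lay, seed = s)
      expect_equal(nrow(validate_placement(res, lay, cells)), 0)
    }
  }
})

test_that("group mode encloses nearby cells in one CCE", {
  lay <- small_layout()
  cells <- cell_records(c(300, 310, 100), c(225, 225, 100), radius_um = 6)
  res <- place_spot_aware(cells, lay,
                          cce_params(group_linkage_um = 20), seed = 1)
  members <- split_ids(res$enclosures$member_cells)
  sizes <- vapply(members, length, 0L)
  expect_true(any(sizes == 2))
  v <- validate_placement(res, lay, cells)
  expect_equal(nrow(v), 0)
})

test_that("heuristic count sits between greedy baseline and brute-force max", {
  for (s in 1:12) {
    set.seed(4000 + s)
    lay <- small_layout()
    cells <- simulate_lane_sample(lay, n_cells = sample(2:8, 1),
                                  seed = 5000 + s)
    h <- nrow(place_spot_aware(cells, lay, seed = s)$enclosures)
    g <- nrow(greedy_baseline_placement(cells, lay)$enclosures)
    b <- max_placement_bruteforce(cells, lay)
    expect_gte(h, g)
    expect_lte(h, b)
  }
})
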