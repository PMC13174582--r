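# CCE placement: the two placement algorithms (unconstrained and capture-spot
# aware), iterative overlap resolution, validation, and the small-instance
# baselines/oracles used to bound the heuristic.

#' CCE placement parameters
#'
#' @param outer_diameter_um CCE outer diameter (default 90).
#' @param wall_thickness_um Annular wall thickness (default 10); lumen
#'   diameter is `outer_diameter_um - 2 * wall_thickness_um`.
#' @param min_spot_overlap Minimum fraction of a capture spot's area that must
#'   lie under the CCE footprint for the spot to count as occupied/owned
#'   (default 0.25).
#' @param max_collisions Candidacy bound for unconstrained placement: a cell
#'   is a placement candidate only if some candidate position incurs at most
#'   this many overlaps with other candidate CCEs. `Inf` disables pruning.
#' @param n_offset_radii,n_offset_angles Polar search grid for off-centre CCE
#'   positions (offsets keep every member cell inside the lumen).
#' @param group_linkage_um When non-`NULL`, cells closer than this distance
#'   are merged into one multi-cell CCE (single-linkage grouping).
#' @return A list of class `cce_params`.
#' @export
cce_params <- function(outer_diameter_um = 90, wall_thickness_um = 10,
                       min_spot_overlap = 0.25, max_collisions = 6,
                       n_offset_radii = 3, n_offset_angles = 8,
                       group_linkage_um = NULL) {
  stopifnot(outer_diameter_um > 0, wall_thickness_um > 0,
            outer_diameter_um > 2 * wall_thickness_um,
            min_spot_overlap > 0, min_spot_overlap <= 1)
  structure(list(outer_diameter_um = outer_diameter_um,
                 wall_thickness_um = wall_thickness_um,
                 min_spot_overlap = min_spot_overlap,
                 max_collisions = max_collisions,
                 n_offset_radii = n_offset_radii,
                 n_offset_angles = n_offset_angles,
                 group_linkage_um = group_linkage_um),
            class = "cce_params")
}

# Polar grid of candidate CCE-centre offsets (centre first, then increasing
# radius, then angle): the deterministic search order used everywhere.
candidate_offsets <- function(max_off, n_radii = 3, n_angles = 8) {
  if (max_off <= 0) return(matrix(0, 1, 2))
  r <- max_off * seq_len(n_radii) / n_radii
  a <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  rbind(c(0, 0),
        cbind(rep(r, each = n_angles) * cos(a),
              rep(r, each = n_angles) * sin(a)))
}

# Single-linkage grouping of cells within `linkage_um` (union-find). Returns a
# list of integer index vectors, one per CCE unit, in order of first member.
group_cell_indices <- function(cells, linkage_um) {
  n <- nrow(cells)
  if (is.null(linkage_um) || n == 0) return(as.list(seq_len(n)))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  pr <- pairs_within(cells$x_um, cells$y_um, linkage_um)
  if (nrow(pr)) for (k in seq_len(nrow(pr))) {
    a <- find(pr[k, 1]); b <- find(pr[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, 1L)
  unname(split(seq_len(n), match(roots, unique(roots))))
}

# Build per-unit geometry: centroid and maximum safe centre offset such that
# every member cell stays inside the lumen (triangle-inequality bound).
unit_geometry <- function(cells, units, lumen_r) {
  ux <- vapply(units, function(ii) mean(cells$x_um[ii]), 0)
  uy <- vapply(units, function(ii) mean(cells$y_um[ii]), 0)
  max_off <- vapply(seq_along(units), function(u) {
    ii <- units[[u]]
    d0 <- sqrt((cells$x_um[ii] - ux[u])^2 + (cells$y_um[ii] - uy[u])^2)
    min(lumen_r - cells$radius_um[ii] - d0)
  }, 0)
  list(x = ux, y = uy, max_off = max_off)
}

new_placement_result <- function(enclosures, uncompartmentalized, iterations,
                                 converged, mode) {
  structure(list(enclosures = enclosures,
                 uncompartmentalized_cell_ids = uncompartmentalized,
                 iterations_used = iterations, converged = converged,
                 mode = mode),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat(sprintf("<placement_result> mode=%s: %d CCEs placed, %d cells uncompartmentalized, converged=%s\n",
              x$mode, nrow(x$enclosures),
              length(x$uncompartmentalized_cell_ids), x$converged))
  invisible(x)
}

#' Collision counts for candidate CCEs centred on each cell
#'
#' A collision is an overlap of the candidate CCE footprint with another
#' candidate CCE (one per overlapping candidate) or with a capture spot (one
#' per spot under the footprint, since that spot would no longer be available
#' to another CCE). Candidates are evaluated at the cell-centred position.
#'
#' @param cells Cell records.
#' @param layout Optional `lane_layout`; spot collisions are 0 when absent.
#' @param params A [cce_params()].
#' @return Data frame `cell_id`, `n_collisions`.
#' @export
count_collisions <- function(cells, layout = NULL, params = cce_params()) {
  R <- params$outer_diameter_um / 2
  n <- nrow(cells)
  cc <- integer(n)
  if (n > 1) {
    pr <- pairs_within(cells$x_um, cells$y_um, 2 * R)
    if (nrow(pr)) {
      tb <- tabulate(c(pr[, 1], pr[, 2]), n)
      cc <- cc + tb
    }
  }
  if (!is.null(layout) && nrow(layout$spots)) {
    sp <- layout$spots
    gi <- grid_index(sp$x_um, sp$y_um, R + max(sp$diameter_um) / 2)
    for (i in seq_len(n)) {
      nb <- grid_query(gi, cells$x_um[i], cells$y_um[i])
      if (length(nb)) {
        d <- sqrt((sp$x_um[nb] - cells$x_um[i])^2 +
                    (sp$y_um[nb] - cells$y_um[i])^2)
        cc[i] <- cc[i] + sum(d < R + sp$diameter_um[nb] / 2)
      }
    }
  }
  data.frame(cell_id = cells$cell_id, n_collisions = cc,
             stringsAsFactors = FALSE)
}

#' Unconstrained CCE placement
#'
#' Places one CCE per cell (or per cell group in group mode), centred on the
#' cell, then resolves overlaps by iterative pairwise repulsion. Candidacy is
#' decided by a deterministic analytic density score: a cell is a candidate if
#' some position on the polar offset grid (which keeps the cell inside the
#' lumen) would incur at most `params$max_collisions` overlaps with other
#' candidate CCEs.
#'
#' @param cells Cell records (see [cell_records()]).
#' @param layout Optional `lane_layout`; when given, CCEs must stay inside the
#'   lane rectangle.
#' @param params A [cce_params()] object.
#' @param seed Integer seed (the algorithm is deterministic; retained so all
#'   placement entry points share one signature).
#' @return A `placement_result`.
#' @export
place_unconstrained <- function(cells, layout = NULL, params = cce_params(),
                                seed = 1L) {
  if (is.null(cells) || nrow(cells) == 0)
    return(new_placement_result(enclosure_set(numeric(0), numeric(0)),
                                character(0), 0L, TRUE, "unconstrained"))
  if (!is.null(layout)) validate_cells(cells, layout)
  R <- params$outer_diameter_um / 2
  lumen_r <- R - params$wall_thickness_um

  units <- group_cell_indices(cells, params$group_linkage_um)
  ug <- unit_geometry(cells, units, lumen_r)
  feasible <- ug$max_off >= 0           # members fit inside the lumen at all
  if (!is.null(layout)) {
    # CCEs are centred on the cell, so the centred footprint must fit the lane
    feasible <- feasible &
      ug$x >= R & ug$x <= layout$width_um - R &
      ug$y >= R & ug$y <= layout$height_um - R
  }

  # collision score at the centred position: candidate CCEs within one outer
  # diameter; pruned when above the bound even at the best offset (offsets can
  # reduce the count by at most the neighbours just at the boundary, so the
  # centred count minus none is used as the analytic score).
  idx <- which(feasible)
  ncoll <- rep(Inf, length(units))
  if (length(idx)) {
    gi <- grid_index(ug$x[idx], ug$y[idx], 2 * R)
    for (m in seq_along(idx)) {
      nb <- grid_query(gi, ug$x[idx[m]], ug$y[idx[m]])
      d2 <- (ug$x[idx[nb]] - ug$x[idx[m]])^2 + (ug$y[idx[nb]] - ug$y[idx[m]])^2
      ncoll[idx[m]] <- sum(d2 < (2 * R)^2) - 1L   # exclude self
    }
  }
  cand <- feasible & ncoll <= params$max_collisions

  member_ids <- vapply(units, function(ii) paste(cells$cell_id[ii], collapse = ";"), "")
  enc <- enclosure_set(ug$x[cand], ug$y[cand],
                       outer_diameter_um = params$outer_diameter_um,
                       wall_thickness_um = params$wall_thickness_um,
                       member_cells = member_ids[cand])
  res <- resolve_overlaps(enc, cells = cells, layout = layout,
                          min_spot_overlap = params$min_spot_overlap)
  placed_members <- unlist(split_ids(res$enclosures$member_cells))
  new_placement_result(res$enclosures,
                       setdiff(cells$cell_id, placed_members),
                       res$iterations, res$converged, "unconstrained")
}

#' Capture-spot-aware CCE placement
#'
#' Heuristic placement under the spot-exclusivity constraint: no capture spot
#' may be occupied by more than one CCE. For every cell the number of
#' "collisions" a CCE centred on it would incur is counted (one per other
#' candidate CCE whose footprint it would overlap, plus one per capture spot
#' under the footprint). Cells are then processed in ascending collision count
#' (ties broken by cell id); each is placed at the first position on its polar
#' offset grid that keeps the cell in the lumen, stays inside the lane, does
#' not overlap an already-placed CCE, and occupies at least one free capture
#' spot (overlap fraction >= `params$min_spot_overlap`) without touching an
#' occupied one above that threshold. Spots so occupied are owned by the CCE.
#'
#' @inheritParams place_unconstrained
#' @param layout A `lane_layout` with at least one capture spot.
#' @return A `placement_result` whose enclosures each own >= 1 spot.
#' @export
place_spot_aware <- function(cells, layout, params = cce_params(), seed = 1L) {
  stopifnot(inherits(layout, "lane_layout"), nrow(layout$spots) >= 1)
  if (is.null(cells) || nrow(cells) == 0)
    return(new_placement_result(enclosure_set(numeric(0), numeric(0)),
                                character(0), 0L, TRUE, "spot_aware"))
  validate_cells(cells, layout)
  R <- params$outer_diameter_um / 2
  lumen_r <- R - params$wall_thickness_um
  spots <- layout$spots
  sr <- spots$diameter_um / 2
  spot_area <- pi * sr^2

  units <- group_cell_indices(cells, params$group_linkage_um)
  ug <- unit_geometry(cells, units, lumen_r)
  nu <- length(units)

  # spatial indexes: unit centroids (for CCE-CCE collisions), spots (reach =
  # outer radius + spot radius + max offset, covered by the 3x3 query window)
  reach <- R + max(sr) + pmax(0, max(ug$max_off))
  gi_units <- grid_index(ug$x, ug$y, 2 * R)
  gi_spots <- grid_index(spots$x_um, spots$y_um, reach)

  ncoll <- integer(nu)
  near_spots <- vector("list", nu)
  for (u in seq_len(nu)) {
    nb <- grid_query(gi_units, ug$x[u], ug$y[u])
    d2 <- (ug$x[nb] - ug$x[u])^2 + (ug$y[nb] - ug$y[u])^2
    cc <- sum(d2 < (2 * R)^2) - 1L
    sp <- grid_query(gi_spots, ug$x[u], ug$y[u])
    if (length(sp)) {
      ds <- sqrt((spots$x_um[sp] - ug$x[u])^2 + (spots$y_um[sp] - ug$y[u])^2)
      near_spots[[u]] <- sp[ds < reach]
      cs <- sum(ds < R + sr[sp])        # spots under the centred footprint
    } else cs <- 0L
    ncoll[u] <- cc + cs
  }

  # deterministic processing order: ascending collisions, then first member id
  first_id <- vapply(units, function(ii) min(cells$cell_id[ii]), "")
  ord <- order(ncoll, first_id)

  occupied <- logical(nrow(spots))
  placed_x <- numeric(0); placed_y <- numeric(0)
  gi_placed <- grid_index(numeric(0), numeric(0), 2 * R + max(0, max(ug$max_off)))
  keep <- logical(nu)
  pos_x <- numeric(nu); pos_y <- numeric(nu)
  owned <- vector("list", nu)

  for (u in ord) {
    if (ug$max_off[u] < 0) next           # members cannot fit in the lumen
    offs <- candidate_offsets(ug$max_off[u], params$n_offset_radii,
                              params$n_offset_angles)
    cx <- ug$x[u] + offs[, 1]; cy <- ug$y[u] + offs[, 2]
    ok <- cx >= R & cx <= layout$width_um - R &
      cy >= R & cy <= layout$height_um - R
    if (!any(ok)) next
    # non-overlap against already-placed CCEs (equal radii: distance >= 2R)
    nbp <- grid_query(gi_placed, ug$x[u], ug$y[u])
    if (length(nbp)) {
      for (ci in which(ok)) {
        d2 <- (placed_x[nbp] - cx[ci])^2 + (placed_y[nbp] - cy[ci])^2
        if (any(d2 < (2 * R)^2 - 1e-9)) ok[ci] <- FALSE
      }
      if (!any(ok)) next
    }
    sp <- near_spots[[u]]
    if (!length(sp)) next
    placed_here <- FALSE
    for (ci in which(ok)) {
      frac <- spot_overlap_fraction_xy(spots$x_um[sp], spots$y_um[sp], sr[sp],
                                       cx[ci], cy[ci], R)
      occ <- frac >= params$min_spot_overlap
      if (any(occ) && !any(occ & occupied[sp])) {
        keep[u] <- TRUE
        pos_x[u] <- cx[ci]; pos_y[u] <- cy[ci]
        owned[[u]] <- spots$spot_id[sp[occ]]
        occupied[sp[occ]] <- TRUE
        placed_x <- c(placed_x, cx[ci]); placed_y <- c(placed_y, cy[ci])
        grid_add(gi_placed, cx[ci], cy[ci], length(placed_x))
        placed_here <- TRUE
        break
      }
    }
  }

  ki <- which(keep)[order(match(which(keep), ord))]   # assignment order
  member_ids <- vapply(units[ki], function(ii)
    paste(cells$cell_id[ii], collapse = ";"), "")
  enc <- enclosure_set(pos_x[ki], pos_y[ki],
                       outer_diameter_um = params$outer_diameter_um,
                       wall_thickness_um = params$wall_thickness_um,
                       member_cells = member_ids,
                       owned_spots = vapply(owned[ki], paste, "", collapse = ";"))
  res <- resolve_overlaps(enc, cells = cells, layout = layout,
                          min_spot_overlap = params$min_spot_overlap)
  placed_members <- unlist(split_ids(res$enclosures$member_cells))
  new_placement_result(res$enclosures,
                       setdiff(cells$cell_id, placed_members),
                       res$iterations, res$converged, "spot_aware")
}

#' Resolve CCE-CCE overlaps by iterative pairwise repulsion
#'
#' Overlapping CCEs are moved apart along their centre lines: each member of an
#' overlapping pair is displaced by half the overlap depth, damped by
#' `damping^(iteration - 1)`. After every iteration, moves that would push a
#' member cell out of the lumen, lose an owned capture spot (overlap below
#' `min_spot_overlap`), or leave the lane are rolled back. If the overlap has
#' not fallen below `tolerance` after `max_iter` iterations, the later-assigned
#' CCE of each persistently overlapping pair is dropped until the remaining
#' set is feasible.
#'
#' @param enclosures An `enclosure_set`, in assignment order.
#' @param cells Cell records for the member-containment constraint (optional).
#' @param layout `lane_layout` for lane-bounds and owned-spot constraints
#'   (optional).
#' @param min_spot_overlap Ownership threshold for owned spots.
#' @param max_iter Maximum repulsion iterations (default 100).
#' @param tolerance Residual overlap depth considered resolved, in um
#'   (default 0.5).
#' @param damping Per-iteration step damping factor (default 0.9).
#' @return List with `enclosures` (kept, constraints intact), `dropped_cce_ids`,
#'   `iterations`, and `converged` (`TRUE` iff resolved within `max_iter`
#'   without dropping any CCE).
#' @export
resolve_overlaps <- function(enclosures, cells = NULL, layout = NULL,
                             min_spot_overlap = 0.25, max_iter = 100,
                             tolerance = 0.5, damping = 0.9) {
  n <- nrow(enclosures)
  if (n == 0)
    return(list(enclosures = enclosures, dropped_cce_ids = character(0),
                iterations = 0L, converged = TRUE))
  x <- enclosures$x_um; y <- enclosures$y_um
  r <- enclosures$outer_diameter_um / 2
  lumen_r <- r - enclosures$wall_thickness_um
  members <- split_ids(enclosures$member_cells)
  owned <- split_ids(enclosures$owned_spots)
  cell_lookup <- if (!is.null(cells)) {
    stats::setNames(seq_len(nrow(cells)), cells$cell_id)
  }
  spot_lookup <- if (!is.null(layout)) {
    stats::setNames(seq_len(nrow(layout$spots)), layout$spots$spot_id)
  }

  move_ok <- function(i, nx, ny) {
    if (!is.null(layout)) {
      if (nx < r[i] || nx > layout$width_um - r[i] ||
          ny < r[i] || ny > layout$height_um - r[i]) return(FALSE)
    }
    if (!is.null(cell_lookup) && length(members[[i]])) {
      ii <- cell_lookup[members[[i]]]
      d <- sqrt((cells$x_um[ii] - nx)^2 + (cells$y_um[ii] - ny)^2)
      if (any(d + cells$radius_um[ii] > lumen_r[i] + 1e-9)) return(FALSE)
    }
    if (!is.null(spot_lookup) && length(owned[[i]])) {
      si <- spot_lookup[owned[[i]]]
      frac <- spot_overlap_fraction_xy(layout$spots$x_um[si],
                                       layout$spots$y_um[si],
                                       layout$spots$diameter_um[si] / 2,
                                       nx, ny, r[i])
      if (any(frac < min_spot_overlap - 1e-12)) return(FALSE)
    }
    TRUE
  }

  overlap_pairs <- function(x, y, alive) {
    ai <- which(alive)
    if (length(ai) < 2) return(NULL)
    pr <- pairs_within(x[ai], y[ai], 2 * max(r))
    if (!nrow(pr)) return(NULL)
    i <- ai[pr[, 1]]; j <- ai[pr[, 2]]
    d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    depth <- r[i] + r[j] - d
    sel <- depth > tolerance
    if (!any(sel)) return(NULL)
    cbind(i = i[sel], j = j[sel], depth = depth[sel], d = d[sel])
  }

  alive <- rep(TRUE, n)
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    op <- overlap_pairs(x, y, alive)
    if (is.null(op)) { converged <- TRUE; iterations <- it - 1L; break }
    iterations <- it
    step <- 0.5 * op[, "depth"] * damping^(it - 1)
    dx <- numeric(n); dy <- numeric(n)
    for (k in seq_len(nrow(op))) {
      i <- op[k, "i"]; j <- op[k, "j"]; d <- op[k, "d"]
      if (d > 1e-9) {
        ux <- (x[i] - x[j]) / d; uy <- (y[i] - y[j]) / d
      } else {                       # coincident centres: deterministic angle
        a <- 2 * pi * i / (n + 1)
        ux <- cos(a); uy <- sin(a)
      }
      dx[i] <- dx[i] + ux * step[k]; dy[i] <- dy[i] + uy * step[k]
      dx[j] <- dx[j] - ux * step[k]; dy[j] <- dy[j] - uy * step[k]
    }
    moved <- which(dx != 0 | dy != 0)
    for (i in moved) {
      if (move_ok(i, x[i] + dx[i], y[i] + dy[i])) {
        x[i] <- x[i] + dx[i]; y[i] <- y[i] + dy[i]
      }                               # else roll back (keep position)
    }
  }
  if (!converged) {
    # persistent infeasibility: drop the later-assigned CCE of each pair
    repeat {
      op <- overlap_pairs(x, y, alive)
      if (is.null(op)) break
      alive[max(op[1, c("i", "j")])] <- FALSE
    }
  }

  enc <- enclosures[alive, , drop = FALSE]
  enc$x_um <- x[alive]; enc$y_um <- y[alive]
  rownames(enc) <- NULL
  class(enc) <- c("enclosure_set", "data.frame")
  list(enclosures = enc,
       dropped_cce_ids = enclosures$cce_id[!alive],
       iterations = iterations, converged = converged)
}

#' Validate a placement against all feasibility invariants
#'
#' Checks CCE-CCE overlap, capture-spot double ownership, owned-spot minimum
#' overlap, member-cell containment in the lumen, CCEs outside the lane, and
#' (in spot-aware mode) CCEs owning no spot.
#'
#' @param result A `placement_result`.
#' @param layout The `lane_layout` the placement was computed on.
#' @param cells Cell records (required for containment checks when enclosures
#'   have members).
#' @param min_spot_overlap Ownership threshold used at placement time.
#' @param tolerance Residual overlap depth tolerated (um, default 0.5).
#' @return A data frame of violations (`type`, `cce_id`, `detail`); zero rows
#'   iff the placement is feasible.
#' @export
validate_placement <- function(result, layout, cells = NULL,
                               min_spot_overlap = 0.25, tolerance = 0.5) {
  enc <- result$enclosures
  v <- list()
  add <- function(type, cce_id, detail)
    v[[length(v) + 1]] <<- data.frame(type = type, cce_id = cce_id,
                                      detail = detail)
  n <- nrow(enc)
  if (n >= 2) {
    r <- enc$outer_diameter_um / 2
    pr <- pairs_within(enc$x_um, enc$y_um, 2 * max(r))
    if (nrow(pr)) {
      d <- sqrt((enc$x_um[pr[, 1]] - enc$x_um[pr[, 2]])^2 +
                  (enc$y_um[pr[, 1]] - enc$y_um[pr[, 2]])^2)
      bad <- which(r[pr[, 1]] + r[pr[, 2]] - d > tolerance)
      for (k in bad)
        add("cce_overlap", enc$cce_id[pr[k, 1]],
            paste0("overlaps ", enc$cce_id[pr[k, 2]]))
    }
  }
  if (n >= 1) {
    r <- enc$outer_diameter_um / 2
    out <- enc$x_um - r < -1e-9 | enc$x_um + r > layout$width_um + 1e-9 |
      enc$y_um - r < -1e-9 | enc$y_um + r > layout$height_um + 1e-9
    for (k in which(out)) add("outside_lane", enc$cce_id[k], "")
    owned <- split_ids(enc$owned_spots)
    all_owned <- unlist(owned)
    dup <- unique(all_owned[duplicated(all_owned)])
    for (s in dup) add("spot_double_ownership", NA_character_, s)
    spot_lookup <- stats::setNames(seq_len(nrow(layout$spots)),
                                   layout$spots$spot_id)
    for (k in seq_len(n)) {
      if (length(owned[[k]])) {
        si <- spot_lookup[owned[[k]]]
        if (anyNA(si)) { add("unknown_spot", enc$cce_id[k],
                             paste(owned[[k]][is.na(si)], collapse = ";")); next }
        frac <- spot_overlap_fraction_xy(
          layout$spots$x_um[si], layout$spots$y_um[si],
          layout$spots$diameter_um[si] / 2, enc$x_um[k], enc$y_um[k], r[k])
        for (m in which(frac < min_spot_overlap - 1e-9))
          add("owned_spot_underlap", enc$cce_id[k], owned[[k]][m])
      } else if (identical(result$mode, "spot_aware")) {
        add("spotless_cce", enc$cce_id[k], "")
      }
    }
    if (!is.null(cells)) {
      lumen_r <- r - enc$wall_thickness_um
      cl <- stats::setNames(seq_len(nrow(cells)), cells$cell_id)
      members <- split_ids(enc$member_cells)
      for (k in seq_len(n)) {
        if (!length(members[[k]])) next
        ii <- cl[members[[k]]]
        if (anyNA(ii)) { add("unknown_cell", enc$cce_id[k], ""); next }
        d <- sqrt((cells$x_um[ii] - enc$x_um[k])^2 +
                    (cells$y_um[ii] - enc$y_um[k])^2)
        for (m in which(d + cells$radius_um[ii] > lumen_r[k] + 1e-6))
          add("cell_outside_lumen", enc$cce_id[k], members[[k]][m])
      }
    }
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(type = character(0), cce_id = character(0),
                  detail = character(0))
}

#' Naive first-come greedy placement baseline
#'
#' Independent baseline for benchmarking the spot-aware heuristic: cells are
#' processed in input order and a CCE is placed centred on the cell whenever
#' that single position is feasible (inside lane, no overlap with a placed
#' CCE, occupies >= 1 free spot at the ownership threshold and no occupied
#' one). No collision ordering and no off-centre search. Quadratic scan: meant
#' for small instances only.
#'
#' @inheritParams place_spot_aware
#' @return A `placement_result`.
#' @export
greedy_baseline_placement <- function(cells, layout, params = cce_params()) {
  R <- params$outer_diameter_um / 2
  spots <- layout$spots
  sr <- spots$diameter_um / 2
  px <- numeric(0); py <- numeric(0)
  keep <- logical(nrow(cells)); owned <- vector("list", nrow(cells))
  occupied <- logical(nrow(spots))
  for (i in seq_len(nrow(cells))) {
    cx <- cells$x_um[i]; cy <- cells$y_um[i]
    if (cells$radius_um[i] > R - params$wall_thickness_um) next
    if (cx < R || cx > layout$width_um - R ||
        cy < R || cy > layout$height_um - R) next
    if (length(px) && any((px - cx)^2 + (py - cy)^2 < (2 * R)^2 - 1e-9)) next
    frac <- spot_overlap_fraction_xy(spots$x_um, spots$y_um, sr, cx, cy, R)
    occ <- frac >= params$min_spot_overlap
    if (!any(occ) || any(occ & occupied)) next
    keep[i] <- TRUE; owned[[i]] <- spots$spot_id[occ]
    occupied[occ] <- TRUE
    px <- c(px, cx); py <- c(py, cy)
  }
  ki <- which(keep)
  enc <- enclosure_set(cells$x_um[ki], cells$y_um[ki],
                       outer_diameter_um = params$outer_diameter_um,
                       wall_thickness_um = params$wall_thickness_um,
                       member_cells = cells$cell_id[ki],
                       owned_spots = vapply(owned[ki], paste, "", collapse = ";"))
  new_placement_result(enc, cells$cell_id[!keep], 0L, TRUE, "spot_aware")
}

#' Exhaustive maximum placement on tiny instances
#'
#' Brute-force upper bound for the spot-aware heuristic: backtracking search
#' over every cell's polar-grid candidate positions (the same discrete
#' position set the heuristic draws from), maximizing the number of placed
#' CCEs under pairwise non-overlap and spot exclusivity. Exponential: intended
#' for <= 8 cells and <= 12 spots.
#'
#' @inheritParams place_spot_aware
#' @return Integer: the maximum achievable number of CCEs.
#' @export
max_placement_bruteforce <- function(cells, layout, params = cce_params()) {
  R <- params$outer_diameter_um / 2
  lumen_r <- R - params$wall_thickness_um
  spots <- layout$spots
  sr <- spots$diameter_um / 2
  n <- nrow(cells)
  if (n == 0) return(0L)
  # per-cell feasible (position, owned-spot-set) options
  options <- lapply(seq_len(n), function(i) {
    mo <- lumen_r - cells$radius_um[i]
    if (mo < 0) return(list())
    offs <- candidate_offsets(mo, params$n_offset_radii, params$n_offset_angles)
    out <- list()
    for (ci in seq_len(nrow(offs))) {
      cx <- cells$x_um[i] + offs[ci, 1]; cy <- cells$y_um[i] + offs[ci, 2]
      if (cx < R || cx > layout$width_um - R ||
          cy < R || cy > layout$height_um - R) next
      frac <- spot_overlap_fraction_xy(spots$x_um, spots$y_um, sr, cx, cy, R)
      occ <- which(frac >= params$min_spot_overlap)
      if (length(occ)) out[[length(out) + 1]] <- list(x = cx, y = cy, spots = occ)
    }
    out
  })
  best <- 0L
  recurse <- function(i, placed_xy, used_spots, count) {
    if (count + (n - i + 1) <= best) return()       # bound
    if (i > n) { best <<- max(best, count); return() }
    for (opt in options[[i]]) {
      if (any(used_spots[opt$spots])) next
      if (nrow(placed_xy) &&
          any((placed_xy[, 1] - opt$x)^2 + (placed_xy[, 2] - opt$y)^2 <
                (2 * R)^2 - 1e-9)) next
      us <- used_spots; us[opt$spots] <- TRUE
      recurse(i + 1, rbind(placed_xy, c(opt$x, opt$y)), us, count + 1L)
    }
    recurse(i + 1, placed_xy, used_spots, count)     # skip cell i
    best <<- max(best, count)
  }
  recurse(1L, matrix(numeric(0), 0, 2), logical(nrow(spots)), 0L)
  best
}
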