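# Coordinate convention used throughout the package: continuous 2D micrometres,
# origin at the lane top-left corner, x increasing rightward, y increasing
# downward. Rasters share the same orientation (row = y, column = x).

#' Construct a flow-cell lane layout with a regular capture-spot grid
#'
#' Models one lane of an eight-lane flow cell. Capture spots (disks of
#' identical mRNA-capture oligonucleotides) are laid out on a regular square
#' grid partitioned into `n_fields` equally wide fields along the lane. The
#' defaults reproduce a 9 cm x 6 mm lane carrying ~23,000 spots in 15 fields.
#'
#' @param width_um,height_um Lane rectangle dimensions in micrometres.
#' @param n_fields Number of fields of view the spot grid is partitioned into
#'   (fields tile the lane along x).
#' @param spot_pitch_um Centre-to-centre spot spacing. Must exceed
#'   `spot_diameter_um` so spot footprints are pairwise disjoint.
#' @param spot_diameter_um Capture-spot diameter (disk model).
#' @param spot_surface Which glass surface carries the spots (`"bottom"` for
#'   suspension cells, `"top"` for adherent cells on coated bottoms). Metadata
#'   only; the geometry is two-dimensional.
#' @param lane_id Identifier string.
#' @return An object of class `lane_layout`: a list with `width_um`,
#'   `height_um`, `fields` (data frame of rectangles) and `spots` (data frame
#'   with `spot_id`, `x_um`, `y_um`, `diameter_um`, `field_id`).
#' @examples
#' lay <- build_lane_layout(width_um = 200, height_um = 200, n_fields = 1,
#'                          spot_pitch_um = 100, spot_diameter_um = 50)
#' nrow(lay$spots) # 4
#' @export
build_lane_layout <- function(width_um = 90000, height_um = 6000,
                              n_fields = 15, spot_pitch_um = 153,
                              spot_diameter_um = 50,
                              spot_surface = c("bottom", "top"),
                              lane_id = "lane1") {
  spot_surface <- match.arg(spot_surface)
  stopifnot(width_um > 0, height_um > 0, n_fields >= 1, spot_pitch_um > 0,
            spot_diameter_um > 0)
  if (spot_pitch_um <= spot_diameter_um)
    stop("spot pitch (", spot_pitch_um, " um) must exceed spot diameter (",
         spot_diameter_um, " um): spot footprints would overlap")

  field_w <- width_um / n_fields
  nx <- floor(field_w / spot_pitch_um)
  ny <- floor(height_um / spot_pitch_um)
  if (nx < 1 || ny < 1)
    stop("lane too small for even one spot at this pitch")

  fields <- data.frame(
    field_id = seq_len(n_fields),
    x0 = (seq_len(n_fields) - 1) * field_w, y0 = 0,
    x1 = seq_len(n_fields) * field_w, y1 = height_um
  )

  # grid centred within each field
  off_x <- (field_w - nx * spot_pitch_um) / 2 + spot_pitch_um / 2
  off_y <- (height_um - ny * spot_pitch_um) / 2 + spot_pitch_um / 2
  per_field <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  spots <- do.call(rbind, lapply(seq_len(n_fields), function(f) {
    data.frame(
      x_um = fields$x0[f] + off_x + (per_field$ix - 1) * spot_pitch_um,
      y_um = off_y + (per_field$iy - 1) * spot_pitch_um,
      field_id = f
    )
  }))
  spots$diameter_um <- spot_diameter_um
  spots$spot_id <- sprintf("spot_%06d", seq_len(nrow(spots)))
  spots <- spots[, c("spot_id", "x_um", "y_um", "diameter_um", "field_id")]
  rownames(spots) <- NULL

  structure(
    list(lane_id = lane_id, width_um = width_um, height_um = height_um,
         spot_pitch_um = spot_pitch_um, spot_surface = spot_surface,
         fields = fields, spots = spots),
    class = "lane_layout"
  )
}

#' @export
print.lane_layout <- function(x, ...) {
  cat(sprintf("<lane_layout> %s: %g x %g um, %d fields, %d capture spots (d = %g um)\n",
              x$lane_id, x$width_um, x$height_um, nrow(x$fields),
              nrow(x$spots), x$spots$diameter_um[1]))
  invisible(x)
}

#' Construct a table of cell records
#'
#' @param x_um,y_um Cell centre coordinates in lane micrometres.
#' @param radius_um Cell radii (recycled).
#' @param cell_id Identifiers; generated when `NULL`.
#' @param truth_type Optional ground-truth type labels (synthetic data).
#' @return A data frame with columns `cell_id`, `x_um`, `y_um`, `radius_um`
#'   and optionally `truth_type`.
#' @export
cell_records <- function(x_um, y_um, radius_um = 8, cell_id = NULL,
                         truth_type = NULL) {
  n <- length(x_um)
  stopifnot(length(y_um) == n, all(radius_um > 0))
  if (is.null(cell_id)) cell_id <- sprintf("cell_%06d", seq_len(n))
  out <- data.frame(cell_id = as.character(cell_id), x_um = x_um, y_um = y_um,
                    radius_um = rep_len(radius_um, n),
                    stringsAsFactors = FALSE)
  if (!is.null(truth_type)) out$truth_type <- as.character(truth_type)
  out
}

#' Construct a set of CCE (CellCage Enclosure) specifications
#'
#' A CCE is a circular hollow hydrogel compartment: an annular wall of
#' thickness `wall_thickness_um` whose outer diameter is `outer_diameter_um`;
#' the open interior (lumen) has diameter `outer - 2 * wall`.
#'
#' @param x_um,y_um CCE centres (micrometres).
#' @param outer_diameter_um,wall_thickness_um Geometry (defaults 90 and 10).
#' @param cce_id Identifiers; generated when `NULL`.
#' @param member_cells,owned_spots Character vectors of `;`-joined ids
#'   (or list columns coerced to that form).
#' @return A data frame of class `enclosure_set`.
#' @export
enclosure_set <- function(x_um, y_um, outer_diameter_um = 90,
                          wall_thickness_um = 10, cce_id = NULL,
                          member_cells = "", owned_spots = "") {
  n <- length(x_um)
  stopifnot(length(y_um) == n)
  outer_diameter_um <- rep_len(outer_diameter_um, n)
  wall_thickness_um <- rep_len(wall_thickness_um, n)
  if (any(outer_diameter_um - 2 * wall_thickness_um <= 0))
    stop("lumen diameter must be positive (outer diameter > 2 * wall thickness)")
  if (is.null(cce_id)) cce_id <- sprintf("cce_%05d", seq_len(n))
  join <- function(v) {
    if (is.list(v)) vapply(v, paste, "", collapse = ";") else as.character(v)
  }
  out <- data.frame(cce_id = as.character(cce_id), x_um = x_um, y_um = y_um,
                    outer_diameter_um = outer_diameter_um,
                    wall_thickness_um = wall_thickness_um,
                    member_cells = rep_len(join(member_cells), n),
                    owned_spots = rep_len(join(owned_spots), n),
                    stringsAsFactors = FALSE)
  class(out) <- c("enclosure_set", "data.frame")
  out
}

#' Split `;`-joined id strings into a list
#' @param x Character vector of `;`-joined ids (as stored in an
#'   `enclosure_set`).
#' @return List of character vectors (empty strings give empty vectors).
#' @export
split_ids <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(v) v[nzchar(v)])
}

# ---- circle geometry -------------------------------------------------------

#' Area of intersection of two disks
#'
#' Standard lens formula; vectorized over all arguments.
#'
#' @param d Centre distances.
#' @param r1,r2 Radii.
#' @return Intersection areas (same length as the longest argument).
#' @export
circle_intersection_area <- function(d, r1, r2) {
  n <- max(length(d), length(r1), length(r2))
  d <- rep_len(d, n); r1 <- rep_len(r1, n); r2 <- rep_len(r2, n)
  out <- numeric(n)
  disjoint <- d >= r1 + r2
  contained <- d <= abs(r1 - r2)
  out[contained] <- (pi * pmin(r1, r2)^2)[contained]
  lens <- !disjoint & !contained
  if (any(lens)) {
    dd <- d[lens]; a <- r1[lens]; b <- r2[lens]
    # clamp acos arguments against rounding
    ca <- pmin(1, pmax(-1, (dd^2 + a^2 - b^2) / (2 * dd * a)))
    cb <- pmin(1, pmax(-1, (dd^2 + b^2 - a^2) / (2 * dd * b)))
    out[lens] <- a^2 * acos(ca) + b^2 * acos(cb) -
      0.5 * sqrt(pmax(0, (-dd + a + b) * (dd + a - b) * (dd - a + b) * (dd + a + b)))
  }
  out
}

#' Fraction of a capture spot covered by a CCE footprint
#'
#' Overlap is computed against the CCE *outer* footprint (the full disk of
#' `outer_diameter_um`), since capture happens anywhere under the compartment.
#'
#' @param spot One-row data frame (or list) with `x_um`, `y_um`,
#'   `diameter_um`; or vectors via `spot_overlap_fraction_xy`.
#' @param enclosure One-row data frame with `x_um`, `y_um`,
#'   `outer_diameter_um`.
#' @return Fraction in \[0, 1\]: `area(spot intersect CCE) / area(spot)`.
#' @export
spot_overlap_fraction <- function(spot, enclosure) {
  spot_overlap_fraction_xy(spot$x_um, spot$y_um, spot$diameter_um / 2,
                           enclosure$x_um, enclosure$y_um,
                           enclosure$outer_diameter_um / 2)
}

#' @rdname spot_overlap_fraction
#' @param sx,sy,sr Spot centres and radii.
#' @param cx,cy,cr CCE centres and outer radii.
#' @export
spot_overlap_fraction_xy <- function(sx, sy, sr, cx, cy, cr) {
  d <- sqrt((sx - cx)^2 + (sy - cy)^2)
  circle_intersection_area(d, sr, cr) / (pi * sr^2)
}

# ---- photomask rasterization -----------------------------------------------

#' Rasterize the photomask for a set of CCE walls
#'
#' The photomask is the binary pattern projected by the light engine: pixels
#' are set where polymerizing light must hit, i.e. on the annular wall of each
#' CCE (distance from a CCE centre between the lumen radius and the outer
#' radius). Pixels are tested at their centres.
#'
#' @param enclosures An `enclosure_set` (may be empty).
#' @param um_per_pixel Raster resolution (> 0).
#' @param origin Lane coordinate of the top-left corner of pixel (1,1);
#'   defaults to `c(0, 0)`.
#' @param width_um,height_um Raster extent; derived from the enclosure
#'   bounding box when `NULL`.
#' @return An object of class `photomask`: list with a logical `raster`
#'   matrix (rows = y), `um_per_pixel` and `origin`.
#' @export
rasterize_photomask <- function(enclosures, um_per_pixel = 1,
                                origin = c(0, 0), width_um = NULL,
                                height_um = NULL) {
  stopifnot(um_per_pixel > 0)
  n <- if (is.null(enclosures)) 0L else nrow(enclosures)
  if (is.null(width_um)) {
    width_um <- if (n == 0) um_per_pixel else
      max(enclosures$x_um + enclosures$outer_diameter_um / 2) - origin[1] +
        um_per_pixel
  }
  if (is.null(height_um)) {
    height_um <- if (n == 0) um_per_pixel else
      max(enclosures$y_um + enclosures$outer_diameter_um / 2) - origin[2] +
        um_per_pixel
  }
  ncol_px <- max(1L, ceiling(width_um / um_per_pixel))
  nrow_px <- max(1L, ceiling(height_um / um_per_pixel))
  raster <- matrix(FALSE, nrow_px, ncol_px)
  if (n > 0) {
    for (i in seq_len(n)) {
      r_out <- enclosures$outer_diameter_um[i] / 2
      r_in <- r_out - enclosures$wall_thickness_um[i]
      cx <- enclosures$x_um[i] - origin[1]
      cy <- enclosures$y_um[i] - origin[2]
      jx <- max(1L, floor((cx - r_out) / um_per_pixel)):
        min(ncol_px, ceiling((cx + r_out) / um_per_pixel) + 1L)
      jy <- max(1L, floor((cy - r_out) / um_per_pixel)):
        min(nrow_px, ceiling((cy + r_out) / um_per_pixel) + 1L)
      jx <- jx[jx >= 1 & jx <= ncol_px]
      jy <- jy[jy >= 1 & jy <= nrow_px]
      if (!length(jx) || !length(jy)) next
      px <- (jx - 0.5) * um_per_pixel
      py <- (jy - 0.5) * um_per_pixel
      d2 <- outer((py - cy)^2, (px - cx)^2, `+`)
      raster[jy, jx] <- raster[jy, jx] | (d2 >= r_in^2 & d2 <= r_out^2)
    }
  }
  structure(list(raster = raster, um_per_pixel = um_per_pixel,
                 origin = origin),
            class = "photomask")
}

#' @export
print.photomask <- function(x, ...) {
  cat(sprintf("<photomask> %d x %d px at %g um/px, %d set pixels\n",
              nrow(x$raster), ncol(x$raster), x$um_per_pixel, sum(x$raster)))
  invisible(x)
}

# ---- validation helpers ----------------------------------------------------

#' Validate cell records against a lane layout
#'
#' Checks that every cell footprint lies inside the lane rectangle and radii
#' are positive.
#'
#' @param cells Cell record data frame.
#' @param layout A `lane_layout`.
#' @return Invisibly `TRUE`; errors on violation.
#' @export
validate_cells <- function(cells, layout) {
  stopifnot(all(cells$radius_um > 0))
  bad <- cells$x_um - cells$radius_um < 0 |
    cells$x_um + cells$radius_um > layout$width_um |
    cells$y_um - cells$radius_um < 0 |
    cells$y_um + cells$radius_um > layout$height_um
  if (any(bad))
    stop(sum(bad), " cell(s) outside the lane rectangle: ",
         paste(utils::head(cells$cell_id[bad], 5), collapse = ", "))
  invisible(TRUE)
}

# ---- CSV interfaces --------------------------------------------------------

#' Read and write cell tables and spot layouts as CSV
#'
#' Cells: columns `cell_id`(or `id`), `x_um`, `y_um`, `radius_um`
#' (or `diameter_um`). Spots: `spot_id`(or `id`), `x_um`, `y_um`,
#' `diameter_um`.
#'
#' @param path File path.
#' @return `read_cells` returns a cell record data frame; `read_spots` a spot
#'   data frame.
#' @export
read_cells <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(df) && "id" %in% names(df))
    names(df)[names(df) == "id"] <- "cell_id"
  if (!"radius_um" %in% names(df) && "diameter_um" %in% names(df))
    df$radius_um <- df$diameter_um / 2
  need <- c("cell_id", "x_um", "y_um", "radius_um")
  if (!all(need %in% names(df)))
    stop("cells CSV must have columns: ", paste(need, collapse = ", "))
  df$cell_id <- as.character(df$cell_id)
  df
}

#' @rdname read_cells
#' @param cells Cell record data frame.
#' @export
write_cells <- function(cells, path) {
  write_csv_atomic(cells, path)
}

#' @rdname read_cells
#' @export
read_spots <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"spot_id" %in% names(df) && "id" %in% names(df))
    names(df)[names(df) == "id"] <- "spot_id"
  need <- c("spot_id", "x_um", "y_um", "diameter_um")
  if (!all(need %in% names(df)))
    stop("spots CSV must have columns: ", paste(need, collapse = ", "))
  df$spot_id <- as.character(df$spot_id)
  df
}

#' @rdname read_cells
#' @param spots Spot data frame (e.g. `layout$spots`).
#' @export
write_spots <- function(spots, path) {
  write_csv_atomic(spots, path)
}
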