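# Format readers/writers (Matrix Market count matrices with TSV sidecars, GMT
# gene sets, PNG/TIFF masks), YAML pipeline configuration, and the end-to-end
# pipeline runner. All writes are atomic (temp file + rename).

#' Read / write a count matrix in Matrix Market format with TSV sidecars
#'
#' The on-disk layout is a directory with `matrix.mtx` (coordinate format),
#' `genes.tsv` (columns `gene`, optionally `species`, `mito`) and one of
#' `spots.tsv` / `cces.tsv` naming the matrix columns. Round-trips integer
#' matrices exactly.
#'
#' @param dir Directory path.
#' @return `read_count_matrix` returns a `spot_count_matrix` (or a
#'   `cce_count_matrix` when `cces.tsv` plus `qc.csv` are present).
#' @export
read_count_matrix <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx under ", dir)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  if (nrow(genes) != nrow(m))
    stop("genes.tsv has ", nrow(genes), " rows for a ", nrow(m),
         "-row matrix")
  col_file <- if (file.exists(file.path(dir, "cces.tsv"))) "cces.tsv"
  else "spots.tsv"
  cols <- utils::read.delim(file.path(dir, col_file),
                            stringsAsFactors = FALSE)
  if (nrow(cols) != ncol(m))
    stop(col_file, " has ", nrow(cols), " rows for a ", ncol(m),
         "-column matrix")
  rownames(m) <- genes$gene
  colnames(m) <- cols[[1]]
  ann <- if (all(c("species", "mito") %in% names(genes)))
    data.frame(gene = genes$gene, species = genes$species,
               mito = as.logical(genes$mito), stringsAsFactors = FALSE)
  qc_file <- file.path(dir, "qc.csv")
  if (col_file == "cces.tsv" && file.exists(qc_file)) {
    qc <- utils::read.csv(qc_file, stringsAsFactors = FALSE)
    cce_count_matrix(m, qc[match(colnames(m), qc$cce_id), ], ann)
  } else {
    spot_count_matrix(m, ann)
  }
}

#' @rdname read_count_matrix
#' @param m A `spot_count_matrix` or `cce_count_matrix`.
#' @export
write_count_matrix <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atomic(file.path(dir, "matrix.mtx"), function(tmp)
    Matrix::writeMM(m$counts, tmp))
  ga <- m$gene_annotations
  write_atomic(file.path(dir, "genes.tsv"), function(tmp)
    utils::write.table(ga, tmp, sep = "\t", row.names = FALSE,
                       quote = FALSE))
  if (inherits(m, "cce_count_matrix")) {
    write_atomic(file.path(dir, "cces.tsv"), function(tmp)
      utils::write.table(data.frame(cce_id = m$cce_ids), tmp, sep = "\t",
                         row.names = FALSE, quote = FALSE))
    write_csv_atomic(m$qc, file.path(dir, "qc.csv"))
  } else {
    write_atomic(file.path(dir, "spots.tsv"), function(tmp)
      utils::write.table(data.frame(spot_id = m$spots), tmp, sep = "\t",
                         row.names = FALSE, quote = FALSE))
  }
  invisible(dir)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then gene ids. Names must be unique,
#' every set must contain at least one gene, and gene ids are
#' whitespace-trimmed.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("malformed GMT line (need name, description, >= 1 gene): ",
           substr(ln, 1, 50))
    nm <- trimws(fields[1])
    genes <- trimws(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("gene set ", nm, " is empty")
    if (nm %in% names(sets)) stop("duplicate gene set name: ", nm)
    sets[[nm]] <- genes
  }
  sets
}

#' @rdname read_gene_sets
#' @param gene_sets Named list of character vectors.
#' @param descriptions Optional descriptions (recycled).
#' @export
write_gene_sets <- function(gene_sets, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(gene_sets))
  write_atomic(path, function(tmp)
    writeLines(vapply(seq_along(gene_sets), function(i)
      paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
            collapse = "\t"), ""), tmp))
}

#' Write / read a photomask as 8-bit PNG with a JSON geometry sidecar
#'
#' @param mask A `photomask`.
#' @param path PNG path; the sidecar is `<path>.json` (fields `um_per_pixel`,
#'   `origin`).
#' @return `read_photomask` returns a `photomask`.
#' @export
write_photomask <- function(mask, path) {
  write_atomic(path, function(tmp)
    png::writePNG(mask$raster * 1, tmp))
  write_atomic(paste0(path, ".json"), function(tmp)
    jsonlite::write_json(list(um_per_pixel = mask$um_per_pixel,
                              origin = mask$origin),
                         tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' @rdname write_photomask
#' @export
read_photomask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(raster = img > 0.5, um_per_pixel = meta$um_per_pixel,
                 origin = meta$origin),
            class = "photomask")
}

# Known configuration schema: section -> allowed keys.
pipeline_schema <- list(
  seed = NULL,
  layout = c("width_um", "height_um", "n_fields", "spot_pitch_um",
             "spot_diameter_um", "spot_surface"),
  cells = c("n_cells", "density_per_mm2", "spatial_mode", "radius_um",
            "cell_types", "type_probs"),
  placement = c("mode", "outer_diameter_um", "wall_thickness_um",
                "min_spot_overlap", "max_collisions", "group_linkage_um"),
  photomask = c("um_per_pixel", "enabled"),
  counts = c("depth", "nb_size", "mito_fraction", "n_genes",
             "n_markers_per_type", "marker_fold"),
  qc = c("min_total", "min_overlap_pct", "max_mito_pct")
)

#' Read and validate a pipeline configuration
#'
#' YAML with sections `layout`, `cells`, `placement`, `photomask`, `counts`,
#' `qc` and a mandatory top-level `seed`. Unknown sections or keys are
#' rejected. The global seed fans out to per-stage seeds by fixed additive
#' offsets (cells +1, placement +2, counts +3).
#'
#' @param path YAML file path.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg Configuration list (as from `yaml::read_yaml`).
#' @export
validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(pipeline_schema))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed))
    stop("config must set an explicit top-level seed")
  for (sec in setdiff(names(cfg), "seed")) {
    bad <- setdiff(names(cfg[[sec]]), pipeline_schema[[sec]])
    if (length(bad))
      stop("unknown key(s) in section ", sec, ": ",
           paste(bad, collapse = ", "))
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the end-to-end simulation + analysis pipeline
#'
#' Stages, in dependency order: lane layout, cell loading simulation, CCE
#' placement, photomask rasterization, spot count simulation, spot-to-CCE
#' assignment, aggregation, and QC filtering. Every artifact is written
#' atomically under `out_dir` together with a `manifest.json` recording the
#' configuration, per-stage seeds, artifact list and package version. Reruns
#' with the same configuration are bit-identical for all deterministic
#' stages.
#'
#' @param config A `pipeline_config` (see [read_pipeline_config()]).
#' @param out_dir Output directory (created; partial outputs are preserved on
#'   failure).
#' @return Invisibly, a list with the main in-memory objects and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_pipeline_config(unclass(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  seeds <- list(cells = seed + 1, placement = seed + 2, counts = seed + 3)
  artifacts <- character(0)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log_lines <<- c(log_lines, msg)
  }

  layout <- do.call(build_lane_layout, config$layout %||% list())
  write_spots(layout$spots, file.path(out_dir, "layout_spots.csv"))
  artifacts <- c(artifacts, "layout_spots.csv")
  note("layout: ", nrow(layout$spots), " spots")

  cell_args <- config$cells %||% list()
  cell_args$layout <- layout
  cell_args$seed <- seeds$cells
  cells <- do.call(simulate_lane_sample, cell_args)
  write_cells(cells, file.path(out_dir, "cells.csv"))
  artifacts <- c(artifacts, "cells.csv")
  note("cells: ", nrow(cells))

  pl_cfg <- config$placement %||% list()
  mode <- pl_cfg$mode %||% "spot_aware"
  params <- do.call(cce_params, pl_cfg[setdiff(names(pl_cfg), "mode")])
  placement <- if (mode == "spot_aware")
    place_spot_aware(cells, layout, params, seed = seeds$placement)
  else place_unconstrained(cells, layout, params, seed = seeds$placement)
  write_csv_atomic(placement$enclosures,
                   file.path(out_dir, "placement.csv"))
  artifacts <- c(artifacts, "placement.csv")
  viol <- validate_placement(placement, layout, cells,
                             min_spot_overlap = params$min_spot_overlap)
  if (nrow(viol)) stop("placement validation failed with ", nrow(viol),
                       " violation(s)")
  note("placement (", mode, "): ", nrow(placement$enclosures), " CCEs, ",
       length(placement$uncompartmentalized_cell_ids), " uncompartmentalized")

  pm_cfg <- config$photomask %||% list()
  if (pm_cfg$enabled %||% TRUE) {
    mask <- rasterize_photomask(placement$enclosures,
                                um_per_pixel = pm_cfg$um_per_pixel %||% 5,
                                width_um = layout$width_um,
                                height_um = layout$height_um)
    write_photomask(mask, file.path(out_dir, "photomask.png"))
    artifacts <- c(artifacts, "photomask.png", "photomask.png.json")
    note("photomask: ", sum(mask$raster), " set pixels")
  }

  asn <- assign_spots_to_cces(placement, layout,
                              min_overlap = params$min_spot_overlap)
  cn_cfg <- config$counts %||% list()
  types <- unique(cells$truth_type) %||% "typeA"
  if (all(is.na(types)) || is.null(cells$truth_type)) types <- "typeA"
  prog <- simulate_programs(n_genes = cn_cfg$n_genes %||% 100, types = types,
                            n_markers_per_type = cn_cfg$n_markers_per_type %||% 5,
                            marker_fold = cn_cfg$marker_fold %||% 20,
                            mito_fraction = cn_cfg$mito_fraction %||% 0.05,
                            seed = seeds$counts)
  members <- split_ids(placement$enclosures$member_cells)
  first_member <- vapply(members, function(v) v[1], "")
  cce_types <- stats::setNames(
    if (is.null(cells$truth_type)) rep("typeA", nrow(placement$enclosures))
    else cells$truth_type[match(first_member, cells$cell_id)],
    placement$enclosures$cce_id)
  sim <- simulate_counts(asn$assignment, cce_types, prog$programs,
                         prog$gene_annotations,
                         depth = cn_cfg$depth %||% 5000,
                         nb_size = cn_cfg$nb_size %||% 2,
                         seed = seeds$counts)
  write_count_matrix(sim$spot_counts, file.path(out_dir, "spot_counts"))
  artifacts <- c(artifacts, "spot_counts/matrix.mtx", "spot_counts/genes.tsv",
                 "spot_counts/spots.tsv")
  agg <- aggregate_counts(sim$spot_counts, asn$assignment)
  write_count_matrix(agg, file.path(out_dir, "cce_counts"))
  artifacts <- c(artifacts, "cce_counts/matrix.mtx", "cce_counts/genes.tsv",
                 "cce_counts/cces.tsv", "cce_counts/qc.csv")
  note("counts: ", sum(agg$counts), " transcripts over ",
       length(agg$cce_ids), " CCEs")

  qc_cfg <- config$qc %||% list()
  filtered <- qc_filter(agg, min_total = qc_cfg$min_total %||% 0,
                        min_overlap_pct = qc_cfg$min_overlap_pct %||% 0,
                        max_mito_pct = qc_cfg$max_mito_pct %||% 100)
  write_count_matrix(filtered, file.path(out_dir, "cce_counts_filtered"))
  artifacts <- c(artifacts, "cce_counts_filtered/matrix.mtx")
  rep_ <- attr(filtered, "filter_report")
  note("qc: kept ", length(filtered$cce_ids), " of ", length(agg$cce_ids),
       " CCEs (thresholds: total > ", qc_cfg$min_total %||% 0,
       ", overlap > ", qc_cfg$min_overlap_pct %||% 0,
       ", mito < ", qc_cfg$max_mito_pct %||% 100, ")")
  write_csv_atomic(rep_, file.path(out_dir, "qc_report.csv"))
  artifacts <- c(artifacts, "qc_report.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("cellcage")),
    config = unclass(config), stage_seeds = seeds, artifacts = artifacts)
  write_atomic(file.path(out_dir, "manifest.json"), function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
  write_atomic(file.path(out_dir, "pipeline.log"), function(tmp)
    writeLines(log_lines, tmp))
  invisible(list(layout = layout, cells = cells, placement = placement,
                 cce_counts = agg, filtered = filtered, manifest = manifest))
}
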