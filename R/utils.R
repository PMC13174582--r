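#' @keywords internal
#' @import methods
"_PACKAGE"

# Run an expression under a local RNG state: seeds the generator, restores the
# caller's .Random.seed afterwards so package functions never clobber the
# session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Spatial hash: assign points to square bins of side `h`, stored in a hashed
# environment mapping "ix_iy" -> integer indices. Environments give O(1)
# lookups, which matters for full-lane runs with tens of thousands of points.
grid_index <- function(x, y, h) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (length(x)) {
    key <- paste0(floor(x / h), "_", floor(y / h))
    sp <- split(seq_along(x), key)
    for (k in names(sp)) assign(k, sp[[k]], envir = env)
  }
  list(env = env, h = h)
}

grid_add <- function(gi, x, y, i) {
  k <- paste0(floor(x / gi$h), "_", floor(y / gi$h))
  assign(k, c(gi$env[[k]], i), envir = gi$env)
  invisible(gi)
}

# Indices of stored points whose bin is within the 3x3 neighbourhood of
# (x, y); guarantees coverage of all points within distance h of (x, y).
grid_query <- function(gi, x, y) {
  ix <- floor(x / gi$h); iy <- floor(y / gi$h)
  out <- vector("list", 9L); n <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    v <- gi$env[[paste0(ix + dx, "_", iy + dy)]]
    if (!is.null(v)) { n <- n + 1L; out[[n]] <- v }
  }
  if (n == 0L) integer(0) else unlist(out[seq_len(n)], use.names = FALSE)
}

# All unordered pairs (i, j), i < j, with distance < d, via grid binning.
pairs_within <- function(x, y, d) {
  n <- length(x)
  if (n < 2) return(cbind(i = integer(0), j = integer(0)))
  gi <- grid_index(x, y, d)
  keys <- ls(gi$env)
  res_i <- vector("list", length(keys)); res_j <- res_i
  for (m in seq_along(keys)) {
    k <- keys[m]
    ij <- as.integer(strsplit(k, "_", fixed = TRUE)[[1]])
    here <- gi$env[[k]]
    # forward half-neighbourhood avoids double counting across bins
    nb <- c(gi$env[[paste0(ij[1] + 1, "_", ij[2] - 1)]],
            gi$env[[paste0(ij[1] + 1, "_", ij[2])]],
            gi$env[[paste0(ij[1] + 1, "_", ij[2] + 1)]],
            gi$env[[paste0(ij[1], "_", ij[2] + 1)]])
    nh <- length(here)
    ci <- rep(here, each = nh); cj <- rep(here, times = nh)
    keep <- ci < cj
    ci <- ci[keep]; cj <- cj[keep]
    if (length(nb)) {
      ci <- c(ci, rep(here, each = length(nb)))
      cj <- c(cj, rep(nb, times = nh))
    }
    if (length(ci)) {
      sel <- (x[ci] - x[cj])^2 + (y[ci] - y[cj])^2 < d^2
      res_i[[m]] <- ci[sel]; res_j[[m]] <- cj[sel]
    }
  }
  oi <- unlist(res_i, use.names = FALSE); oj <- unlist(res_j, use.names = FALSE)
  if (is.null(oi)) return(cbind(i = integer(0), j = integer(0)))
  cbind(i = pmin(oi, oj), j = pmax(oi, oj))
}

# Atomic file writes: write to a temp file in the same directory, then rename.
write_atomic <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}

write_csv_atomic <- function(df, path) {
  write_atomic(path, function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
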