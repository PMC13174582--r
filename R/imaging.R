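# Per-instance image quantification with in-CCE background subtraction, a
# rotation-invariant shape-feature embedding, the image-impairment suite with
# its linear-classifier robustness evaluation, and the longitudinal phenotype
# rule classifier.

#' Labelled instance mask with intensity channels
#'
#' @param labels Integer matrix; 0 = no object, positive ids label object
#'   instances.
#' @param channels Named list of numeric matrices (same shape as `labels`).
#' @param cce_footprint Logical matrix marking the CCE interior; defaults to
#'   the full frame. Must cover every labelled pixel.
#' @return Object of class `instance_mask`.
#' @export
instance_mask <- function(labels, channels = list(), cce_footprint = NULL) {
  stopifnot(is.matrix(labels))
  if (is.null(cce_footprint))
    cce_footprint <- matrix(TRUE, nrow(labels), ncol(labels))
  stopifnot(identical(dim(labels), dim(cce_footprint)))
  for (ch in channels) stopifnot(identical(dim(ch), dim(labels)))
  if (any(labels < 0)) stop("label ids must be non-negative")
  if (any(labels > 0 & !cce_footprint))
    stop("cce_footprint must cover all labelled instance pixels")
  structure(list(labels = labels, channels = channels,
                 cce_footprint = cce_footprint),
            class = "instance_mask")
}

#' Quantify object instances: mean intensity and in-CCE background subtraction
#'
#' For every instance and channel, the mean pixel intensity across the
#' instance's pixels is computed; the background is the mean intensity of all
#' pixels inside the CCE footprint that belong to no object, and
#' `bg_subtracted = mean_intensity - background`. Exact arithmetic, no
#' smoothing.
#'
#' @param mask An `instance_mask` with at least one channel.
#' @return Data frame: `instance_id`, `channel`, `mean_intensity`,
#'   `background`, `bg_subtracted`, `area_px`, `bg_defined`. When the
#'   footprint contains no object-free pixel the background is undefined and
#'   flagged (`bg_defined = FALSE`, background `NA`).
#' @export
quantify_instances <- function(mask) {
  ids <- sort(unique(mask$labels[mask$labels > 0]))
  if (!length(ids)) stop("mask contains no object instance")
  if (!length(mask$channels)) stop("mask has no intensity channels")
  bg_px <- mask$cce_footprint & mask$labels == 0
  bg_defined <- any(bg_px)
  out <- list()
  for (ch_name in names(mask$channels)) {
    ch <- mask$channels[[ch_name]]
    bg <- if (bg_defined) mean(ch[bg_px]) else NA_real_
    for (id in ids) {
      px <- mask$labels == id
      area <- sum(px)
      if (area == 0) stop("instance ", id, " has zero pixels")
      mi <- mean(ch[px])
      out[[length(out) + 1]] <- data.frame(
        instance_id = id, channel = ch_name, mean_intensity = mi,
        background = bg,
        bg_subtracted = if (bg_defined) mi - bg else NA_real_,
        area_px = area, bg_defined = bg_defined)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Hu's seven moment invariants of a point set (optionally weighted),
# rotation-invariant by construction.
hu_moments <- function(xs, ys, w = NULL) {
  if (is.null(w)) w <- rep(1, length(xs))
  m00 <- sum(w)
  xb <- sum(w * xs) / m00; yb <- sum(w * ys) / m00
  mu <- function(p, q) sum(w * (xs - xb)^p * (ys - yb)^q)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  c(n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2))
}

# Area of the convex hull of a point set (shoelace on grDevices::chull).
hull_area <- function(xs, ys) {
  if (length(xs) < 3) return(0)
  h <- grDevices::chull(xs, ys)
  x <- xs[h]; y <- ys[h]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Rotation-invariant shape-feature embedding of mask instances
#'
#' A fixed 64-dimensional descriptor per object instance, built entirely from
#' rotation-invariant quantities: area, boundary-pixel perimeter, circularity,
#' eccentricity (from second central moments), solidity (area / convex hull
#' area), four intensity moments (mean, SD, skewness, kurtosis; zero when the
#' mask has no channels), a 24-bin radial occupancy profile and a 24-bin
#' radial mean-intensity profile about the centroid (radii normalized by the
#' maximum pixel radius), and Hu's seven moment invariants of the binary
#' shape. All quantities are functions of the unordered pixel point set, so a
#' 90-degree image rotation leaves the embedding unchanged to machine
#' precision. This descriptor plays the role of an external pretrained image
#' embedding (the statistics downstream are embedding-agnostic); any matrix of
#' per-instance feature vectors can be substituted.
#'
#' @param mask An `instance_mask`.
#' @param channel Channel used for intensity features (default: first channel
#'   if any).
#' @param n_radial_bins Bins per radial profile (default 24; two profiles).
#' @return Numeric matrix, one row per instance (rownames = instance ids),
#'   `4 + 1 + 4 + 2 * n_radial_bins + 7` = 64 columns.
#' @export
extract_shape_embedding <- function(mask, channel = NULL,
                                    n_radial_bins = 24) {
  ids <- sort(unique(mask$labels[mask$labels > 0]))
  if (!length(ids)) stop("mask contains no object instance")
  if (is.null(channel) && length(mask$channels))
    channel <- names(mask$channels)[1]
  ch <- if (!is.null(channel)) mask$channels[[channel]]
  lab <- mask$labels
  nr <- nrow(lab); nc <- ncol(lab)
  emb <- matrix(0, length(ids), 16 + 2 * n_radial_bins,
                dimnames = list(ids, NULL))
  for (k in seq_along(ids)) {
    id <- ids[k]
    px <- which(lab == id, arr.ind = TRUE)
    xs <- px[, 2]; ys <- px[, 1]
    area <- nrow(px)
    # boundary pixels: any 4-neighbour outside the instance (or image edge)
    inside <- matrix(FALSE, nr + 2, nc + 2)
    inside[cbind(ys + 1, xs + 1)] <- TRUE
    boundary <- !(inside[cbind(ys, xs + 1)] & inside[cbind(ys + 2, xs + 1)] &
                    inside[cbind(ys + 1, xs)] & inside[cbind(ys + 1, xs + 2)])
    perimeter <- sum(boundary)
    xb <- mean(xs); yb <- mean(ys)
    mu20 <- mean((xs - xb)^2); mu02 <- mean((ys - yb)^2)
    mu11 <- mean((xs - xb) * (ys - yb))
    tr <- mu20 + mu02
    det_ <- mu20 * mu02 - mu11^2
    disc <- sqrt(max(0, tr^2 / 4 - det_))
    l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
    ecc <- if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0
    sol <- if (area >= 3) area / max(hull_area(xs, ys), area) else 1
    circ <- if (perimeter > 0) 4 * pi * area / perimeter^2 else 0
    ints <- if (!is.null(ch)) ch[cbind(ys, xs)] else rep(0, area)
    im <- mean(ints); isd <- stats::sd(ints)
    if (is.na(isd)) isd <- 0
    isk <- if (isd > 0) mean(((ints - im) / isd)^3) else 0
    iku <- if (isd > 0) mean(((ints - im) / isd)^4) - 3 else 0
    d <- sqrt((xs - xb)^2 + (ys - yb)^2)
    dmax <- max(d, 1e-9)
    bin <- pmin(n_radial_bins, floor(d / dmax * n_radial_bins) + 1)
    occ <- tabulate(bin, n_radial_bins) / area
    rint <- vapply(seq_len(n_radial_bins), function(b) {
      sel <- bin == b
      if (any(sel)) mean(ints[sel]) else 0
    }, 0)
    hu <- hu_moments(xs, ys)
    # log-compress Hu invariants (signed) for numeric comparability
    hu <- sign(hu) * log1p(abs(hu) * 1e6)
    emb[k, ] <- c(area, perimeter, circ, ecc, sol, im, isd, isk, iku,
                  occ, rint, hu)
  }
  colnames(emb) <- c("area_px", "perimeter_px", "circularity", "eccentricity",
                     "solidity", "int_mean", "int_sd", "int_skew", "int_kurt",
                     sprintf("radial_occ_%02d", seq_len(n_radial_bins)),
                     sprintf("radial_int_%02d", seq_len(n_radial_bins)),
                     sprintf("hu_%d", 1:7))
  emb
}

#' Average instance embeddings to CCE level
#'
#' CCE-level feature vectors are the element-wise mean of the member-cell
#' rows (as used when one compartment holds several cells).
#'
#' @param embeddings Matrix with one row per instance.
#' @param membership Grouping vector (CCE id per row).
#' @return Matrix with one row per group.
#' @export
average_embeddings <- function(embeddings, membership) {
  stopifnot(nrow(embeddings) == length(membership))
  rs <- rowsum(embeddings, membership)
  rs / as.vector(table(membership)[rownames(rs)])
}

# Separable Gaussian convolution with edge replication.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
    stats::filter(vp, k, sides = 2)[(half + 1):(half + length(v))]
  }
  out <- apply(img, 2, pad_conv)
  t(apply(t(out), 2, pad_conv))
}

rotate90 <- function(img, times = 1) {
  times <- ((times %% 4) + 4) %% 4
  for (i in seq_len(times)) img <- t(img[nrow(img):1, , drop = FALSE])
  img
}

#' Apply a seeded image impairment
#'
#' The impairment suite used to probe embedding robustness: random rotations
#' of +/-90 or 180 degrees; uniform brightness or contrast shifts of up to
#' +/-20%; Gaussian blur with kernel SD drawn from \[0, 2\] px; additive
#' Gaussian noise with SD drawn from \[0, 10\] (8-bit units); and random 5%
#' pixel dropout. Intensities are clipped to \[0, 255\]. `"identity"` returns
#' the input unchanged.
#'
#' @param image Numeric matrix, 8-bit scale (values in \[0, 255\]).
#' @param kind One of `"identity"`, `"rotation"`, `"brightness"`,
#'   `"contrast"`, `"gaussian_blur"`, `"gaussian_noise"`, `"dropout"`.
#' @param seed Integer seed for the random draw.
#' @param shift Fixed brightness/contrast shift (e.g. `0.2` for +20%);
#'   sampled uniformly from \[-0.2, 0.2\] when `NULL`.
#' @param sigma Fixed blur / noise SD; sampled from the kind's range when
#'   `NULL`.
#' @param dropout_prob Pixel dropout probability (default 0.05).
#' @return The perturbed image matrix. The applied rotation (quarter turns) is
#'   attached as attribute `"turns"` for `kind = "rotation"`.
#' @export
perturb_image <- function(image, kind, seed = 1L, shift = NULL, sigma = NULL,
                          dropout_prob = 0.05) {
  kinds <- c("identity", "rotation", "brightness", "contrast",
             "gaussian_blur", "gaussian_noise", "dropout")
  if (!kind %in% kinds)
    stop("unknown impairment kind: ", kind, " (expected one of ",
         paste(kinds, collapse = ", "), ")")
  clip <- function(x) { x[] <- pmin(255, pmax(0, x)); x }
  with_seed(seed, switch(
    kind,
    identity = image,
    rotation = {
      turns <- sample(c(1L, 2L, 3L), 1)     # +90, 180, -90
      structure(rotate90(image, turns), turns = turns)
    },
    brightness = {
      s <- shift %||% stats::runif(1, -0.2, 0.2)
      clip(image * (1 + s))
    },
    contrast = {
      s <- shift %||% stats::runif(1, -0.2, 0.2)
      clip((image - mean(image)) * (1 + s) + mean(image))
    },
    gaussian_blur = {
      s <- sigma %||% stats::runif(1, 0, 2)
      clip(gaussian_blur(image, s))
    },
    gaussian_noise = {
      s <- sigma %||% stats::runif(1, 0, 10)
      clip(image + matrix(stats::rnorm(length(image), 0, s), nrow(image)))
    },
    dropout = {
      drop <- matrix(stats::runif(length(image)) < dropout_prob, nrow(image))
      image * !drop
    }))
}

# Apply an impairment to a full instance_mask: geometric impairments rotate
# the labels and footprint along with the channels; intensity impairments
# touch the channels only.
perturb_instance_mask <- function(mask, kind, seed = 1L, ...) {
  if (kind == "rotation") {
    ch1 <- perturb_image(mask$channels[[1]] %||%
                           matrix(0, nrow(mask$labels), ncol(mask$labels)),
                         "rotation", seed = seed)
    turns <- attr(ch1, "turns")
    chans <- lapply(mask$channels, rotate90, times = turns)
    instance_mask(rotate90(mask$labels, turns), chans,
                  rotate90(mask$cce_footprint * 1, turns) > 0)
  } else {
    chans <- lapply(seq_along(mask$channels), function(i)
      perturb_image(mask$channels[[i]], kind, seed = seed + i - 1L, ...))
    names(chans) <- names(mask$channels)
    instance_mask(mask$labels, chans, mask$cce_footprint)
  }
}

#' Per-class accuracy drop of a linear classifier under image impairments
#'
#' Fits a multinomial linear classifier on clean training embeddings, then
#' compares its per-class accuracy on clean versus impaired versions of the
#' held-out test images (each re-embedded after the impairment). The reported
#' drop is `clean accuracy - perturbed accuracy` per class and impairment.
#'
#' @param train_embeddings Matrix of clean training feature vectors.
#' @param train_labels Class labels for the training rows (>= 2 classes).
#' @param test_masks List of single-instance `instance_mask` objects.
#' @param test_labels Class labels for the test masks.
#' @param perturbations Character vector of impairment kinds (see
#'   [perturb_image()]).
#' @param embed_fun Embedding extractor applied to each mask (default
#'   [extract_shape_embedding()]).
#' @param seed Integer seed (classifier fit and impairment draws).
#' @return Data frame: `perturbation`, `class`, `clean_accuracy`,
#'   `perturbed_accuracy`, `accuracy_drop`.
#' @export
embedding_robustness_eval <- function(train_embeddings, train_labels,
                                      test_masks, test_labels,
                                      perturbations = c("rotation",
                                                        "brightness",
                                                        "contrast",
                                                        "gaussian_blur",
                                                        "gaussian_noise",
                                                        "dropout"),
                                      embed_fun = extract_shape_embedding,
                                      seed = 1L) {
  train_labels <- factor(train_labels)
  if (nlevels(train_labels) < 2)
    stop("need at least 2 classes to train the classifier")
  stopifnot(length(test_masks) == length(test_labels))
  test_labels <- factor(test_labels, levels = levels(train_labels))
  mu <- colMeans(train_embeddings)
  sdv <- apply(train_embeddings, 2, stats::sd)
  sdv[sdv == 0] <- 1
  scale_emb <- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
  df_train <- data.frame(y = train_labels, scale_emb(train_embeddings))
  fit <- with_seed(seed, nnet::multinom(y ~ ., data = df_train, trace = FALSE,
                                        MaxNWts = 1e6))
  predict_masks <- function(masks) {
    emb <- do.call(rbind, lapply(masks, embed_fun))
    stats::predict(fit, newdata = data.frame(scale_emb(emb)))
  }
  clean_pred <- predict_masks(test_masks)
  acc_by_class <- function(pred) {
    vapply(levels(train_labels), function(cl) {
      sel <- test_labels == cl
      if (!any(sel)) NA_real_ else mean(pred[sel] == cl)
    }, 0)
  }
  clean_acc <- acc_by_class(clean_pred)
  out <- list()
  for (p in perturbations) {
    pm <- lapply(seq_along(test_masks), function(i)
      perturb_instance_mask(test_masks[[i]], p, seed = seed + 7L * i))
    pacc <- acc_by_class(predict_masks(pm))
    out[[p]] <- data.frame(perturbation = p, class = levels(train_labels),
                           clean_accuracy = clean_acc,
                           perturbed_accuracy = pacc,
                           accuracy_drop = clean_acc - pacc,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify CCEs into longitudinal phenotypes by trajectory rules
#'
#' Rules applied to CCEs whose mean instance area is below
#' `area_threshold_px`, in priority order: *daughter cell resistant* (>= 1
#' dead and >= 1 live cell at the last timepoint), *cell cycle arrest*
#' (exactly 1 live cell at every timepoint), *dead* (0 live and >= 1 dead at
#' the last timepoint). CCEs at or above the area threshold, or remaining CCEs
#' with >= 1 live cell at the last timepoint, are *proliferation*; anything
#' left is *unclassified* (excluded downstream). The mean area is taken over
#' all instances across all timepoints of the CCE.
#'
#' @param trajectories Data frame `cce_id`, `timepoint`, `n_live`, `n_dead`,
#'   `mean_instance_area_px`; every CCE must cover the same complete set of
#'   timepoints.
#' @param area_threshold_px Segmentation-merge guard (default 15000 px).
#' @return Data frame `cce_id`, `label` with one row per CCE.
#' @export
classify_trajectory_phenotypes <- function(trajectories,
                                           area_threshold_px = 15000) {
  need <- c("cce_id", "timepoint", "n_live", "n_dead",
            "mean_instance_area_px")
  stopifnot(all(need %in% names(trajectories)))
  if (any(trajectories$n_live < 0) || any(trajectories$n_dead < 0))
    stop("counts must be non-negative")
  all_tp <- sort(unique(trajectories$timepoint))
  by_cce <- split(trajectories, trajectories$cce_id)
  labels <- vapply(by_cce, function(tr) {
    if (!identical(sort(tr$timepoint), all_tp))
      stop("CCE ", tr$cce_id[1], " is missing timepoints")
    tr <- tr[order(tr$timepoint), ]
    last <- nrow(tr)
    if (mean(tr$mean_instance_area_px) >= area_threshold_px)
      return("proliferation")
    if (tr$n_dead[last] >= 1 && tr$n_live[last] >= 1)
      return("daughter_cell_resistant")
    if (all(tr$n_live == 1))
      return("cell_cycle_arrest")
    if (tr$n_live[last] == 0 && tr$n_dead[last] >= 1)
      return("dead")
    if (tr$n_live[last] >= 1)
      return("proliferation")
    "unclassified"
  }, "")
  data.frame(cce_id = names(labels), label = unname(labels),
             stringsAsFactors = FALSE)
}
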