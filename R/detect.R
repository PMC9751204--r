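#' Preprocessing configuration
#'
#' Parameters of the detection chain's image-conditioning stage. The chain
#' is: (i) low-pass Gaussian filter of the raw grid; (ii) per-column
#' rolling-ball baseline (1-D grayscale opening with a semicircular element
#' of radius `ball_radius` sampled at spacing `dx`), which tracks the slow
#' Gaussian illumination profile along each column while staying under the
#' narrow vesicle peaks; (iii) 3x3 median filter of the assembled
#' background; (iv) subtraction, clipped at zero; (v) final Gaussian
#' filter.
#'
#' @param lowpass_sigma sigma (px) of the initial low-pass filter.
#' @param ball_radius rolling-ball radius, px; must be positive and smaller
#'   than the column length of the images analyzed.
#' @param dx sample-point spacing of the ball, px.
#' @param post_gauss_sigma sigma (px) of the final Gaussian filter.
#' @param sfr signal-to-fluctuation ratio: the detection threshold is
#'   `sfr` times the per-pixel fluctuation level, twice the
#'   (column median - column minimum) of the corrected image. The SFR is
#'   the user's operating point, reviewed on the first image of a batch;
#'   the default 3 sits on the wide plateau between noise clusters and
#'   diffraction-limited spots for shot-noise-limited sCMOS data.
#' @param min_core_px minimum pixels for a connected component to count as
#'   a spot (suppresses single-pixel noise).
#' @param connectivity 4 or 8 (default) for connected components.
#' @param bg_samples number of vesicle-free pseudo-spots for the
#'   background-vs-size fit.
#' @param bg_size_range pixel-count range of the pseudo-spots.
#' @return a validated `vq_preprocess_config` list.
#' @export
preprocess_config <- function(lowpass_sigma = 1, ball_radius = 25, dx = 1,
                              post_gauss_sigma = 1, sfr = 3,
                              min_core_px = 2L, connectivity = 8L,
                              bg_samples = 100L, bg_size_range = c(10L, 100L)) {
  if (ball_radius <= 0) stop("ball_radius must be > 0")
  if (sfr <= 0) stop("sfr must be > 0")
  if (dx <= 0) stop("dx must be > 0")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (length(bg_size_range) != 2 || bg_size_range[1] < 1 ||
      diff(bg_size_range) < 0)
    stop("bg_size_range must be an increasing pair of positive sizes")
  structure(list(lowpass_sigma = lowpass_sigma, ball_radius = ball_radius,
                 dx = dx, post_gauss_sigma = post_gauss_sigma, sfr = sfr,
                 min_core_px = as.integer(min_core_px),
                 connectivity = as.integer(connectivity),
                 bg_samples = as.integer(bg_samples),
                 bg_size_range = as.integer(bg_size_range)),
            class = "vq_preprocess_config")
}

#' Background subtraction by per-column rolling ball
#'
#' @param grid intensity grid (numeric matrix).
#' @param cfg a [preprocess_config()].
#' @return list with `corrected` (low-passed, background-subtracted,
#'   zero-clipped, re-smoothed grid) and `background` (the median-filtered
#'   rolling-ball baseline).
#' @export
preprocess <- function(grid, cfg = preprocess_config()) {
  g <- as_grid_matrix(grid)
  if (any(!is.finite(g))) stop("grid contains non-finite values")
  if (cfg$ball_radius >= nrow(g))
    stop("ball_radius must be smaller than the column length")
  if (nrow(g) < 3 || ncol(g) < 3)
    stop("image smaller than the filter windows")
  low <- gaussian_blur(g, cfg$lowpass_sigma)
  bg <- .rolling_ball_cols(low, cfg$ball_radius, cfg$dx)
  bg <- .median_filter3(bg)
  corr <- pmax(low - bg, 0)
  corr <- gaussian_blur(corr, cfg$post_gauss_sigma)
  list(corrected = corr, background = bg)
}

#' Pixel-specific detection threshold
#'
#' The fluctuation level of each pixel is twice the difference between the
#' median and the minimum of its image column (two row vectors of
#' column statistics, broadcast down the columns); the threshold is `sfr`
#' times that. A threshold that follows the per-column fluctuation level
#' makes detection robust to residual uneven background across the field.
#'
#' @param corrected background-subtracted grid from [preprocess()].
#' @param sfr signal-to-fluctuation ratio.
#' @return list of class `vq_threshold_map`: `threshold` (matrix),
#'   `fluctuation` (matrix), `sfr`.
#' @export
threshold_map <- function(corrected, sfr) {
  g <- as_grid_matrix(corrected)
  med <- apply(g, 2, median)
  mn <- apply(g, 2, min)
  fluct <- matrix(2 * (med - mn), nrow(g), ncol(g), byrow = TRUE)
  structure(list(threshold = sfr * fluct, fluctuation = fluct, sfr = sfr),
            class = "vq_threshold_map")
}

new_spot_set <- function(table, core, enlarged = NULL, channel = NA_character_,
                         shape = NULL) {
  structure(list(table = table, core = core, enlarged = enlarged,
                 channel = channel, shape = shape),
            class = "vq_spots")
}

#' @export
print.vq_spots <- function(x, ...) {
  cat("<vq_spots>", nrow(x$table), "spots, channel:", x$channel, "\n")
  if (nrow(x$table)) print(head(x$table, 5))
  invisible(x)
}

#' @export
as.data.frame.vq_spots <- function(x, ...) x$table

n_spots <- function(spots) nrow(spots$table)

#' Detect spots above the pixel-specific threshold
#'
#' Builds the binary mask `corrected > threshold`, labels its connected
#' components, discards components below `min_core_px`, and records each
#' component's pixel set ("core") and intensity-weighted centroid. Spots
#' whose core touches the image border are flagged (`border = TRUE`):
#' their clipped size biases the normalized intensity.
#'
#' @param corrected background-subtracted grid.
#' @param th a [threshold_map()] (or a matrix of per-pixel thresholds).
#' @param min_core_px,connectivity see [preprocess_config()].
#' @param channel channel tag stored with the spots.
#' @return a `vq_spots` object; centroids in the table are 0-based image
#'   coordinates.
#' @export
detect_spots <- function(corrected, th, min_core_px = 2L, connectivity = 8L,
                         channel = NA_character_) {
  g <- as_grid_matrix(corrected)
  thm <- if (inherits(th, "vq_threshold_map")) th$threshold else th
  if (!identical(dim(g), dim(thm))) stop("threshold map shape mismatch")
  mask <- g > thm
  lab <- .label_components(mask, as.integer(connectivity))
  idx <- which(lab > 0)
  keep_tab <- NULL
  core <- list()
  if (length(idx)) {
    comp <- lab[idx]
    sizes <- tabulate(comp)
    keep <- which(sizes >= min_core_px)
    core <- vector("list", length(keep))
    rows <- (idx - 1L) %% nrow(g) + 1L
    cols <- (idx - 1L) %/% nrow(g) + 1L
    ord <- split(seq_along(idx), comp)
    cen <- matrix(NA_real_, length(keep), 2)
    bord <- logical(length(keep))
    for (j in seq_along(keep)) {
      sel <- ord[[keep[j]]]
      px <- cbind(row = rows[sel], col = cols[sel])
      core[[j]] <- px
      wts <- g[idx[sel]]
      if (sum(wts) <= 0) wts <- rep(1, length(sel))
      cen[j, ] <- c(sum(px[, 1] * wts), sum(px[, 2] * wts)) / sum(wts) - 1
      bord[j] <- any(px[, 1] %in% c(1L, nrow(g))) ||
                 any(px[, 2] %in% c(1L, ncol(g)))
    }
    if (length(keep))
      keep_tab <- data.frame(id = seq_along(keep),
                           channel = channel,
                           centroid_row = cen[, 1], centroid_col = cen[, 2],
                           core_px = sizes[keep], sigma_px = NA_integer_,
                           I_int = NA_real_, I_max = NA_real_,
                           I_tot = NA_real_, I_peak = NA_real_,
                           border = bord,
                           colocalized = FALSE, partner_id = NA_integer_)
  }
  if (is.null(keep_tab))
    keep_tab <- data.frame(id = integer(0), channel = character(0),
                           centroid_row = numeric(0), centroid_col = numeric(0),
                           core_px = integer(0), sigma_px = integer(0),
                           I_int = numeric(0), I_max = numeric(0),
                           I_tot = numeric(0), I_peak = numeric(0),
                           border = logical(0), colocalized = logical(0),
                           partner_id = integer(0))
  new_spot_set(keep_tab, core, channel = channel, shape = dim(g))
}

# Dilate one pixel set (1-based (row, col) matrix) by a (2h+1)^2 square,
# clipped to the image; returns the unique enlarged set.
enlarge_pixels <- function(px, shape, h = 2L) {
  offs <- expand.grid(dr = -h:h, dc = -h:h)
  rr <- rep(px[, 1], each = nrow(offs)) + offs$dr
  cc <- rep(px[, 2], each = nrow(offs)) + offs$dc
  ok <- rr >= 1 & rr <= shape[1] & cc >= 1 & cc <= shape[2]
  unique(cbind(row = rr[ok], col = cc[ok]))
}

#' Enlarge spot cores by a 5x5 window
#'
#' Morphological dilation of each core with a 5x5 square element (2 px in
#' every direction), clipped to the image bounds. The enlargement captures
#' spot edge pixels that fall below the threshold, so the same additive
#' area is included for every spot. The enlarged pixel count is the spot
#' size sigma used by the background model.
#'
#' @param spots a `vq_spots` object with core masks.
#' @return the spots with `enlarged` pixel sets and `sigma_px` filled in.
#' @export
enlarge_spots <- function(spots) {
  stopifnot(inherits(spots, "vq_spots"))
  spots$enlarged <- lapply(spots$core, enlarge_pixels, shape = spots$shape)
  spots$table$sigma_px <- vapply(spots$enlarged, nrow, integer(1))
  spots
}

#' Integrate spot intensities
#'
#' `I_int` is the sum of grid values over the enlarged pixel set; `I_max`
#' is the maximum over the core. Intensities are taken from the
#' background-subtracted grid the threshold was applied to.
#'
#' @param spots a `vq_spots` object with enlarged masks.
#' @param grid the grid to integrate (typically `corrected`).
#' @return the spots with `I_int` and `I_max` filled in.
#' @export
integrate_spots <- function(spots, grid) {
  stopifnot(inherits(spots, "vq_spots"))
  if (is.null(spots$enlarged)) stop("call enlarge_spots() first")
  g <- as_grid_matrix(grid)
  spots$table$I_int <- vapply(spots$enlarged, function(px)
    sum(g[px]), numeric(1))
  spots$table$I_max <- vapply(spots$core, function(px)
    max(g[px]), numeric(1))
  spots
}

#' Sample vesicle-free background pseudo-spots
#'
#' Draws `n_samples` compact pseudo-spots (discs grown around random seed
#' pixels) of sizes uniform on `size_range`, placed wholly outside every
#' detected spot's enlarged mask plus a 2-px guard band, and integrates the
#' grid over each. Only the (size, integrated intensity) pairs enter the
#' background fit, so the disc shape is immaterial.
#'
#' @param grid grid to integrate (same one used for `I_int`).
#' @param spots detected spots (enlarged), or `NULL` for none.
#' @param n_samples number of pseudo-spots.
#' @param size_range inclusive pixel-count range.
#' @param seed RNG seed for reproducible placement.
#' @param guard guard band (px) around occupied masks.
#' @return data frame with columns `sigma` and `I_bg`.
#' @export
sample_background <- function(grid, spots = NULL, n_samples = 100L,
                              size_range = c(10L, 100L), seed = 1L,
                              guard = 2L) {
  g <- as_grid_matrix(grid)
  occupied <- matrix(FALSE, nrow(g), ncol(g))
  if (!is.null(spots) && n_spots(spots) > 0) {
    if (is.null(spots$enlarged)) stop("spots must carry enlarged masks")
    for (px in spots$enlarged) occupied[px] <- TRUE
    occupied <- dilate_square(occupied, guard)
  }
  free_idx <- which(!occupied)
  if (!length(free_idx)) stop("no vesicle-free area to sample")
  set.seed(seed)
  sizes <- sample(seq(size_range[1], size_range[2]), n_samples, replace = TRUE)
  out_sigma <- integer(n_samples)
  out_sum <- numeric(n_samples)
  max_tries <- 200L * n_samples
  tries <- 0L
  for (i in seq_len(n_samples)) {
    repeat {
      tries <- tries + 1L
      if (tries > max_tries)
        stop(sprintf("could not place background samples; %.1f%% of the image is occupied",
                     100 * mean(occupied)))
      seed_px <- free_idx[sample.int(length(free_idx), 1L)]
      r0 <- (seed_px - 1L) %% nrow(g) + 1L
      c0 <- (seed_px - 1L) %/% nrow(g) + 1L
      # nearest pixels by distance form an approximate disc of sizes[i] px
      h <- ceiling(sqrt(sizes[i] / pi)) + 2L
      rr <- (r0 - h):(r0 + h)
      cc <- (c0 - h):(c0 + h)
      if (rr[1] < 1 || cc[1] < 1 || rr[length(rr)] > nrow(g) ||
          cc[length(cc)] > ncol(g)) next
      cand <- expand.grid(row = rr, col = cc)
      d2 <- (cand$row - r0)^2 + (cand$col - c0)^2
      cand <- cand[order(d2), , drop = FALSE][seq_len(sizes[i]), ]
      px <- cbind(row = cand$row, col = cand$col)
      if (any(occupied[px])) next
      out_sigma[i] <- sizes[i]
      out_sum[i] <- sum(g[px])
      break
    }
  }
  data.frame(sigma = out_sigma, I_bg = out_sum)
}

#' Fit the background-vs-size model
#'
#' Ordinary least squares of integrated background intensity on pseudo-spot
#' size: `I_BG(sigma) = a0 + a1 * sigma`. The fit is evaluable at any
#' `sigma >= 1`, in particular at sigma = 1 for the peak normalization.
#' Because a zero-size spot collects zero background, a negative fitted
#' intercept can only be sampling noise; in that case the line is refitted
#' through the origin (`a0 = 0`), which keeps the extrapolation to
#' sigma = 1 below the sampled size range physical.
#'
#' @param samples data frame from [sample_background()].
#' @param channel channel tag.
#' @return object of class `vq_background_model` with coefficients `a0`,
#'   `a1` and the samples.
#' @export
fit_background_model <- function(samples, channel = NA_character_) {
  if (nrow(samples) < 10) stop("need at least 10 background samples")
  if (length(unique(samples$sigma)) < 2)
    stop("degenerate background samples: all sizes equal")
  fit <- lm(I_bg ~ sigma, data = samples)
  if (coef(fit)[1] < 0) fit <- lm(I_bg ~ sigma - 1, data = samples)
  cf <- coef(fit)
  a0 <- if ("(Intercept)" %in% names(cf)) unname(cf["(Intercept)"]) else 0
  structure(list(a0 = a0, a1 = unname(cf[["sigma"]]),
                 samples = samples, channel = channel),
            class = "vq_background_model")
}

#' Predict background intensity for a spot size
#' @param model a `vq_background_model`.
#' @param sigma spot size(s), pixels.
#' @return predicted integrated background intensity.
#' @export
predict_background <- function(model, sigma) {
  stopifnot(inherits(model, "vq_background_model"))
  model$a0 + model$a1 * sigma
}

#' @export
print.vq_background_model <- function(x, ...) {
  cat(sprintf("<vq_background_model> I_BG(sigma) = %.4g + %.4g * sigma (n = %d, channel %s)\n",
              x$a0, x$a1, nrow(x$samples), x$channel))
  invisible(x)
}

#' Background-normalized spot intensities
#'
#' `I_tot = (I_int - I_BG(sigma)) / I_BG(sigma)` with sigma the spot's
#' enlarged size, and `I_peak = (I_max - I_BG(1)) / I_BG(1)`. A spot whose
#' integrated intensity equals the expected background of its size scores
#' `I_tot = 0`; twice the background scores 1.
#'
#' @param spots integrated spots.
#' @param model the channel's [fit_background_model()].
#' @return the spots with `I_tot` and `I_peak` filled in.
#' @export
normalize_spots <- function(spots, model) {
  stopifnot(inherits(spots, "vq_spots"),
            inherits(model, "vq_background_model"))
  if (n_spots(spots) == 0) return(spots)
  if (any(is.na(spots$table$I_int))) stop("call integrate_spots() first")
  ibg <- predict_background(model, spots$table$sigma_px)
  ibg1 <- predict_background(model, 1)
  if (any(ibg <= 0) || ibg1 <= 0)
    stop("background model predicts non-positive intensity; model invalid for this image")
  spots$table$I_tot <- (spots$table$I_int - ibg) / ibg
  spots$table$I_peak <- (spots$table$I_max - ibg1) / ibg1
  spots
}

#' Full single-channel detection chain
#'
#' Convenience wrapper: [preprocess()], [threshold_map()],
#' [detect_spots()], [enlarge_spots()], [integrate_spots()],
#' [sample_background()], [fit_background_model()], [normalize_spots()].
#'
#' @param grid raw intensity grid of one channel.
#' @param cfg a [preprocess_config()].
#' @param channel channel tag.
#' @param seed seed for the background sampling.
#' @return list: `spots`, `model`, `corrected`, `background`, `threshold`.
#' @export
detect_vesicles <- function(grid, cfg = preprocess_config(),
                            channel = NA_character_, seed = 1L) {
  pp <- preprocess(grid, cfg)
  th <- threshold_map(pp$corrected, cfg$sfr)
  spots <- detect_spots(pp$corrected, th, cfg$min_core_px, cfg$connectivity,
                        channel = channel)
  spots <- enlarge_spots(spots)
  spots <- integrate_spots(spots, pp$corrected)
  samples <- sample_background(pp$corrected, spots, cfg$bg_samples,
                               cfg$bg_size_range, seed = seed)
  model <- fit_background_model(samples, channel = channel)
  spots <- normalize_spots(spots, model)
  list(spots = spots, model = model, corrected = pp$corrected,
       background = pp$background, threshold = th)
}
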