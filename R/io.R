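#' Read a two-channel image stack
#'
#' Reads a multi-page grayscale TIFF and splits every page into the two
#' wavelength sub-images according to `layout`: `"split_lr"` (blue left,
#' red right — the dual-view camera layout), `"split_tb"` (blue top), or
#' `"single"` for one-channel data (the blue slot is populated). For data
#' acquired as two separate stacks use [read_stack_pair()].
#'
#' @param path TIFF file.
#' @param layout page layout, see above.
#' @return list of [channel_frame()]s in page order.
#' @export
read_stack <- function(path, layout = c("split_lr", "split_tb", "single")) {
  layout <- match.arg(layout)
  pages <- read_tiff_stack(path)
  lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (layout == "split_lr") {
      if (ncol(p) %% 2 != 0)
        stop("page ", i, ": odd width ", ncol(p), " cannot be split left/right")
      h <- ncol(p) / 2
      channel_frame(blue = p[, seq_len(h), drop = FALSE],
                    red = p[, h + seq_len(h), drop = FALSE],
                    frame_index = i, source = path, layout = "split_lr")
    } else if (layout == "split_tb") {
      if (nrow(p) %% 2 != 0)
        stop("page ", i, ": odd height ", nrow(p), " cannot be split top/bottom")
      h <- nrow(p) / 2
      channel_frame(blue = p[seq_len(h), , drop = FALSE],
                    red = p[h + seq_len(h), , drop = FALSE],
                    frame_index = i, source = path, layout = "split_tb")
    } else {
      channel_frame(blue = p, red = NULL, frame_index = i, source = path,
                    layout = "two_files")
    }
  })
}

#' @rdname read_stack
#' @param blue_path,red_path per-channel TIFF stacks of equal length.
#' @export
read_stack_pair <- function(blue_path, red_path) {
  b <- read_tiff_stack(blue_path)
  r <- read_tiff_stack(red_path)
  if (length(b) != length(r))
    stop("channel stacks differ in page count")
  lapply(seq_along(b), function(i)
    channel_frame(blue = b[[i]], red = r[[i]], frame_index = i,
                  source = blue_path, layout = "two_files"))
}

#' Re-join a split frame into one dual-view page
#'
#' Inverse of the [read_stack()] split; used to verify that splitting is
#' lossless.
#'
#' @param frame a [channel_frame()].
#' @return the re-assembled page matrix.
#' @export
join_frame <- function(frame) {
  b <- as_grid_matrix(frame$blue)
  r <- as_grid_matrix(frame$red)
  switch(frame$layout,
         split_lr = cbind(b, r),
         split_tb = rbind(b, r),
         stop("frame was not produced by splitting one page"))
}

#' Write a spot table as CSV
#'
#' One row per spot with 0-based centroid coordinates:
#' id, channel, centroid_row, centroid_col, sigma_px, I_int, I_max, I_tot,
#' I_peak, colocalized_flag, partner_id. Numeric fields are written at full
#' precision (15 significant digits) so a parse-back reproduces them.
#'
#' @param spots a `vq_spots` object or a list of them (concatenated).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  tabs <- if (inherits(spots, "vq_spots")) list(spots$table)
          else lapply(spots, function(s) s$table)
  tab <- do.call(rbind, tabs)
  cols <- c("id", "channel", "centroid_row", "centroid_col", "sigma_px",
            "I_int", "I_max", "I_tot", "I_peak", "colocalized", "partner_id")
  tab <- tab[, cols]
  names(tab)[names(tab) == "colocalized"] <- "colocalized_flag"
  for (nm in c("centroid_row", "centroid_col", "I_int", "I_max", "I_tot", "I_peak"))
    tab[[nm]] <- formatC(tab[[nm]], digits = 15, format = "g")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a detection/colocalization overlay image
#'
#' Renders the two corrected channel grids as a magenta/green composite
#' PNG with detected spots circled in their channel color and colocalized
#' pairs ringed in white — the non-interactive replacement for the on-screen
#' review of the first analyzed image.
#'
#' @param blue_grid,red_grid corrected channel grids.
#' @param blue_spots,red_spots detected spots (may be `NULL`).
#' @param coloc optional `vq_coloc` whose pairs are ringed in white.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(blue_grid, red_grid, blue_spots = NULL,
                              red_spots = NULL, coloc = NULL, path) {
  b <- as_grid_matrix(blue_grid)
  r <- as_grid_matrix(red_grid)
  sc <- function(m) {
    hi <- stats::quantile(m, 0.999)
    if (hi <= 0) hi <- 1
    pmin(m / hi, 1)
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  grDevices::png(path, width = ncol(b), height = nrow(b))
  op <- par(mar = c(0, 0, 0, 0))
  on.exit({ par(op); dev.off() })
  # raster composite: blue channel -> green, red channel -> magenta
  img <- grDevices::rgb(sc(r), sc(b), sc(r))
  dim(img) <- dim(b)
  plot.new()
  graphics::rasterImage(grDevices::as.raster(img), 0, 0, 1, 1,
                        interpolate = FALSE)
  nr <- nrow(b); nc <- ncol(b)
  ring <- function(tab, col, radius = 6) {
    if (is.null(tab) || !nrow(tab)) return(invisible())
    symbols(x = (tab$centroid_col + 0.5) / nc,
            y = 1 - (tab$centroid_row + 0.5) / nr,
            circles = rep(radius / nc, nrow(tab)),
            inches = FALSE, add = TRUE, fg = col)
  }
  if (!is.null(blue_spots)) ring(blue_spots$table, "cyan")
  if (!is.null(red_spots)) ring(red_spots$table, "red")
  if (!is.null(coloc) && nrow(coloc$pairs) && !is.null(blue_spots)) {
    sel <- blue_spots$table[match(coloc$pairs$blue_id, blue_spots$table$id), ]
    ring(sel, "white", radius = 9)
  }
  invisible(path)
}
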