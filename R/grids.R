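#' Intensity grids
#'
#' An intensity grid is one wavelength channel's image: a rectangular
#' numeric matrix of finite, non-negative camera counts. Pixel (1,1) of the
#' matrix is the top-left corner of the image; all exported tables use
#' 0-based row/column coordinates so that positions are unambiguous across
#' languages.
#'
#' @param values numeric matrix of pixel intensities.
#' @return `intensity_grid()` returns the validated matrix with class
#'   `vq_grid`.
#' @examples
#' g <- intensity_grid(matrix(0, 16, 16))
#' dim(g)
#' @export
intensity_grid <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("an intensity grid must be a numeric matrix")
  if (any(!is.finite(values)))
    stop("intensity grid contains non-finite values")
  if (any(values < 0))
    stop("intensity grid contains negative values")
  class(values) <- c("vq_grid", class(values))
  values
}

as_grid_matrix <- function(x) {
  if (inherits(x, "vq_grid")) return(unclass(x))
  if (is.matrix(x) && is.logical(x)) return(x * 1)
  if (!is.matrix(x) || !is.numeric(x)) stop("expected a numeric matrix")
  x
}

#' Two-channel frame
#'
#' Couples the blue (AF488-type, left sub-image) and red (Cy5-type, right
#' sub-image) channel grids of one camera frame, as produced by a dual-view
#' image splitter. Either channel may be `NULL` for single-channel data.
#'
#' @param blue,red intensity grids (matrices) or `NULL`.
#' @param frame_index 1-based page index in the source stack.
#' @param source path of the source file, or `""`.
#' @param layout how the two channels were stored: `"split_lr"` (left/right
#'   halves of one page), `"split_tb"` (top/bottom), or `"two_files"`.
#' @return an object of class `vq_frame`.
#' @export
channel_frame <- function(blue = NULL, red = NULL, frame_index = 1L,
                          source = "", layout = "split_lr") {
  layout <- match.arg(layout, c("split_lr", "split_tb", "two_files"))
  if (!is.null(blue)) blue <- intensity_grid(as_grid_matrix(blue))
  if (!is.null(red)) red <- intensity_grid(as_grid_matrix(red))
  if (!is.null(blue) && !is.null(red) && !identical(dim(blue), dim(red)))
    stop("blue and red grids must have identical shape")
  structure(list(blue = blue, red = red,
                 frame_index = as.integer(frame_index),
                 source = source, layout = layout),
            class = "vq_frame")
}

#' @export
print.vq_frame <- function(x, ...) {
  sh <- function(g) if (is.null(g)) "absent" else paste(dim(g), collapse = "x")
  cat("<vq_frame> page", x$frame_index,
      " blue:", sh(x$blue), " red:", sh(x$red),
      " layout:", x$layout, "\n")
  invisible(x)
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1, 1 + dr):min(nr, nr + dr)
  sc <- max(1, 1 + dc):min(nc, nc + dc)
  if (dr >= nr || -dr >= nr || dc >= nc || -dc >= nc) return(out)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

# Separable Gaussian blur with replicate edge padding. sigma = 0 is identity.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) c(rep(1L, h), seq_len(n), rep(n, h))
  conv_cols <- function(x) {
    xp <- x[pad_idx(nrow(x)), , drop = FALSE]
    out <- matrix(0, nrow(x), ncol(x))
    for (j in seq_along(k))
      out <- out + k[j] * xp[(j - 1L) + seq_len(nrow(x)), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(m))))
}

# Binary dilation with a (2h+1)x(2h+1) square element, via shifted masks.
dilate_square <- function(mask, h) {
  out <- mask
  for (dr in -h:h) for (dc in -h:h) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_matrix(mask, dr, dc, FALSE)
  }
  out
}
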