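# Stage 2: morphological contrast enhancement.
#
# Grayscale erosion/dilation are min/max filters over a structuring
# element; opening/closing compose them.  The bottom-hat (closing minus
# image) extracts dark structures smaller than the element, the top-hat
# (image minus opening) extracts bright ones, and the enhancement adds
# the bright residue and subtracts the dark one, evening out the
# contrast.  Borders are handled by replicate (edge) padding so no
# spurious residuals appear at the frame.  Arithmetic is carried in
# doubles and clipped to 8 bits only at the very end.

#' Build a structuring element
#'
#' @param shape "disk" or "square".
#' @param radius radius (disk) or half-width (square), in pixels; the
#'   element is a (2*radius+1)^2 boolean grid with origin at its centre.
#' @return logical matrix of class `structuring_element` with the member
#'   offsets stored in attribute `offsets`.
#' @export
structuring_element <- function(shape = c("disk", "square"), radius = 15L) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (radius < 0L) stop("radius must be >= 0", call. = FALSE)
  d <- 2L * radius + 1L
  dy <- matrix(-radius:radius, d, d)
  dx <- matrix(-radius:radius, d, d, byrow = TRUE)
  se <- if (shape == "disk") dy^2 + dx^2 <= radius^2 else matrix(TRUE, d, d)
  if (!any(se)) stop("empty structuring element", call. = FALSE)
  attr(se, "offsets") <- cbind(dy = dy[se], dx = dx[se])
  class(se) <- c("structuring_element", class(se))
  se
}

se_offsets <- function(se) {
  if (!is.null(attr(se, "offsets"))) return(attr(se, "offsets"))
  if (!is.matrix(se) || !is.logical(se) || !any(se))
    stop("invalid structuring element", call. = FALSE)
  if (nrow(se) %% 2L == 0L || ncol(se) %% 2L == 0L)
    stop("structuring element must have odd dimensions", call. = FALSE)
  ry <- (nrow(se) - 1L) %/% 2L; rx <- (ncol(se) - 1L) %/% 2L
  idx <- which(se, arr.ind = TRUE)
  cbind(dy = idx[, 1L] - ry - 1L, dx = idx[, 2L] - rx - 1L)
}

minmax_filter <- function(img, se, op) {
  offs <- se_offsets(se)
  out <- NULL
  for (i in seq_len(nrow(offs))) {
    shifted <- shift_replicate(img, offs[i, 1L], offs[i, 2L])
    out <- if (is.null(out)) shifted else op(out, shifted)
  }
  out
}

#' Grayscale morphological primitives
#'
#' Min/max filters over the structuring-element neighbourhood with
#' replicate border padding; `opening` = dilate(erode(.)), `closing` =
#' erode(dilate(.)).
#'
#' @param img integer matrix in [0, 255].
#' @param se a [structuring_element()].
#' @return integer matrix of the same shape.
#' @export
erode <- function(img, se) { assert_gray(img); minmax_filter(img, se, pmin) }

#' @rdname erode
#' @export
dilate <- function(img, se) { assert_gray(img); minmax_filter(img, se, pmax) }

#' @rdname erode
#' @export
opening <- function(img, se) dilate(erode(img, se), se)

#' @rdname erode
#' @export
closing <- function(img, se) erode(dilate(img, se), se)

#' Bottom-hat transform: closing(f) - f
#'
#' Non-negative residual highlighting dark structures smaller than the
#' structuring element.
#'
#' @inheritParams erode
#' @return non-negative integer matrix (not clipped to 255).
#' @export
bottom_hat <- function(img, se) closing(img, se) - img

#' Top-hat transform: f - opening(f)
#'
#' Non-negative residual highlighting bright structures smaller than the
#' structuring element.
#'
#' @inheritParams erode
#' @return non-negative integer matrix (not clipped to 255).
#' @export
top_hat <- function(img, se) img - opening(img, se)

#' Morphological contrast enhancement
#'
#' `clip(f + top_hat(f) - bottom_hat(f), 0, 255)`: bright detail is
#' amplified and dark detail suppressed, evening the contrast across the
#' breast.  The sum is formed in a wide range and clipped once.
#'
#' @inheritParams erode
#' @return integer matrix in [0, 255].
#' @export
enhance_contrast <- function(img, se) {
  assert_gray(img)
  as_gray(as.numeric(img) + top_hat(img, se) - bottom_hat(img, se))
}

#' Default structuring element scaled to the image
#'
#' A disk of radius 15 at side 256, scaled proportionally with the
#' larger image dimension: large enough to exceed lesion-texture scale,
#' small enough to stay below the pectoral scale.
#'
#' @param img integer matrix.
#' @return a [structuring_element()].
#' @export
default_se <- function(img) {
  structuring_element("disk", max(1L, as.integer(round(15 * max(dim(img)) / 256))))
}

#' Intensity histogram
#'
#' @param img integer matrix in [0, 255].
#' @return integer vector of 256 counts; bin i+1 counts pixels of value
#'   i, and the bins sum to the pixel count.
#' @export
intensity_histogram <- function(img) {
  assert_gray(img)
  tabulate(as.integer(img) + 1L, nbins = 256L)
}
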