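# Stage 1: breast isolation and pectoral-muscle removal.
#
# The pectoral muscle appears in MLO views as a bright triangular wedge
# in the upper chest-wall corner.  It is removed by seeded region
# growing: a seed is planted near that corner (on the side detected as
# the chest wall) and the region absorbs connected neighbours whose
# intensity stays within a tolerance of the region's running mean.

#' Detect breast laterality from intensity mass
#'
#' The chest wall (and hence the breast) is taken to be on the vertical
#' image half with the greater total intensity.
#'
#' @param img integer matrix in [0, 255]; must not be constant.
#' @return "left" or "right".
#' @export
detect_orientation <- function(img) {
  assert_gray(img)
  N <- ncol(img)
  half <- N %/% 2L
  left <- sum(img[, seq_len(half)])
  right <- sum(img[, (N - half + 1L):N])
  if (left == right) {
    if (min(img) == max(img))
      stop("orientation undecidable: constant image", call. = FALSE)
    # fall back to the full-column split including the middle column
    left <- sum(img[, seq_len(ceiling(N / 2))])
    right <- sum(img) - left
    if (left == right)
      stop("orientation undecidable: symmetric intensity mass", call. = FALSE)
  }
  if (left > right) "left" else "right"
}

#' Extract the breast region by thresholding
#'
#' Keeps the largest 8-connected component of pixels strictly above the
#' threshold, which discards scanner labels and small artifacts.
#'
#' @param img integer matrix in [0, 255].
#' @param threshold intensity in [0, 255].
#' @return logical matrix.
#' @export
extract_breast_mask <- function(img, threshold) {
  assert_gray(img)
  if (threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]", call. = FALSE)
  fg <- img > threshold
  if (!any(fg)) stop("no pixel above threshold", call. = FALSE)
  largest_component(fg, 8L)
}

#' Place the pectoral seed near the chest-wall top corner
#'
#' @param img integer matrix.
#' @param laterality "left" or "right" (chest-wall side).
#' @param offset inset from the corner, pixels; must be < min(M, N)/2.
#' @return list(row, col), 0-based.
#' @export
select_pectoral_seed <- function(img, laterality, offset = 5L) {
  assert_gray(img)
  offset <- as.integer(offset)
  if (offset < 0L || offset >= min(nrow(img), ncol(img)) / 2)
    stop("seed offset out of range", call. = FALSE)
  col <- if (laterality == "left") offset else ncol(img) - 1L - offset
  list(row = offset, col = col)
}

#' Seeded region growing
#'
#' Grows a connected region from `seed`, admitting neighbouring pixels
#' whose intensity differs from a reference by at most `tolerance`.  Two
#' membership predicates are provided:
#' \describe{
#'   \item{"running_mean"}{the reference is the mean intensity of the
#'     region grown so far (adaptive; tolerates gradual intensity drift).
#'     Growth proceeds in breadth-first waves; within a wave candidates
#'     are tested in (row, col) order against the mean frozen at the
#'     start of the wave, and the mean is updated after the wave.  A
#'     candidate rejected in one wave is re-tested while it stays
#'     adjacent to the region.}
#'   \item{"fixed_seed"}{the reference is the seed pixel's intensity;
#'     membership is then order-independent — exactly the connected
#'     component of the level set |I - I(seed)| <= tolerance containing
#'     the seed — and monotone in the tolerance.}
#' }
#' Both are deterministic.
#'
#' @param img integer matrix in [0, 255].
#' @param seed list(row, col), 0-based, in bounds.
#' @param tolerance non-negative intensity delta.
#' @param connectivity 4 or 8.
#' @param predicate "running_mean" (default) or "fixed_seed".
#' @return logical matrix containing the seed.
#' @export
region_grow <- function(img, seed, tolerance, connectivity = 8L,
                        predicate = c("running_mean", "fixed_seed")) {
  assert_gray(img)
  predicate <- match.arg(predicate)
  M <- nrow(img); N <- ncol(img)
  r0 <- as.integer(seed$row) + 1L; c0 <- as.integer(seed$col) + 1L
  if (r0 < 1L || r0 > M || c0 < 1L || c0 > N)
    stop("seed out of bounds", call. = FALSE)
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  offs <- neighbour_offsets(as.integer(connectivity))

  if (predicate == "fixed_seed") {
    allowed <- abs(img - img[r0, c0]) <= tolerance
    region <- matrix(FALSE, M, N)
    region[r0, c0] <- TRUE
    repeat {
      frontier <- matrix(FALSE, M, N)
      for (o in offs) frontier <- frontier | shift_fill(region, o[1L], o[2L], FALSE)
      grown <- region | (frontier & allowed)
      if (identical(grown, region)) break
      region <- grown
    }
    return(region)
  }

  region <- matrix(FALSE, M, N)
  region[r0, c0] <- TRUE
  total <- as.numeric(img[r0, c0]); count <- 1L
  repeat {
    frontier <- matrix(FALSE, M, N)
    for (o in offs) frontier <- frontier | shift_fill(region, o[1L], o[2L], FALSE)
    cand <- frontier & !region
    if (!any(cand)) break
    admit <- cand & (abs(img - total / count) <= tolerance)
    if (!any(admit)) break
    region <- region | admit
    total <- total + sum(as.numeric(img[admit]))
    count <- count + sum(admit)
  }
  region
}

#' Remove the pectoral muscle from an MLO mammogram
#'
#' Composes orientation detection, breast-mask extraction, seed
#' placement and seeded region growing, then zeroes the pectoral pixels.
#' For CC-view images (where the pectoral muscle hugs the chest wall as
#' a thin semi-ellipse rather than a wedge) removal is skipped with a
#' message and an empty pectoral mask is returned.
#'
#' @param img integer matrix in [0, 255]; must not be constant.
#' @param tolerance region-growing tolerance (default 16 of 255).
#' @param connectivity 4 or 8 (default 8).
#' @param seed_offset corner inset of the pectoral seed, pixels.
#' @param breast_threshold threshold for breast-mask extraction.
#' @param view "MLO" (default) or "CC".
#' @param laterality optional "left"/"right"; detected when NULL.
#' @return list with `breast_mask`, `pectoral_mask`, `cleaned` (pectoral
#'   pixels set to 0), and `laterality`.
#' @export
remove_pectoral <- function(img, tolerance = 16, connectivity = 8L,
                            seed_offset = 5L, breast_threshold = 40,
                            view = "MLO", laterality = NULL) {
  assert_gray(img)
  if (min(img) == max(img)) stop("constant image", call. = FALSE)
  if (is.null(laterality)) laterality <- detect_orientation(img)
  breast_mask <- extract_breast_mask(img, breast_threshold)
  if (identical(view, "CC")) {
    message("CC view: pectoral removal skipped")
    return(list(breast_mask = breast_mask,
                pectoral_mask = matrix(FALSE, nrow(img), ncol(img)),
                cleaned = img, laterality = laterality))
  }
  seed <- select_pectoral_seed(img, laterality, seed_offset)
  pectoral <- region_grow(img, seed, tolerance, connectivity,
                          predicate = "running_mean")
  pectoral <- pectoral & breast_mask
  cleaned <- img
  cleaned[pectoral] <- 0L
  list(breast_mask = breast_mask, pectoral_mask = pectoral,
       cleaned = cleaned, laterality = laterality)
}
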