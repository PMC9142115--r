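# Shared internal helpers: image validation, shifting with replicate
# padding, connected-component labelling, Dice overlap.

L_LEVELS <- 256L

assert_gray <- function(img, arg = deparse(substitute(img))) {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(sprintf("'%s' must have at least one row and column", arg), call. = FALSE)
  if (anyNA(img))
    stop(sprintf("'%s' contains NA values", arg), call. = FALSE)
  if (min(img) < 0 || max(img) > L_LEVELS - 1L)
    stop(sprintf("'%s' has values outside [0, 255]", arg), call. = FALSE)
  if (any(img != round(img)))
    stop(sprintf("'%s' has non-integer intensities", arg), call. = FALSE)
  invisible(TRUE)
}

assert_mask <- function(mask, arg = deparse(substitute(mask))) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("'%s' must be a logical matrix", arg), call. = FALSE)
  if (anyNA(mask))
    stop(sprintf("'%s' contains NA values", arg), call. = FALSE)
  invisible(TRUE)
}

assert_same_shape <- function(a, b) {
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b))
    stop("shape mismatch between inputs", call. = FALSE)
  invisible(TRUE)
}

clip8 <- function(x) pmin(pmax(x, 0), L_LEVELS - 1L)

as_gray <- function(x) {
  m <- matrix(as.integer(round(clip8(x))), nrow(x), ncol(x))
  m
}

# Shift an image by (dy, dx) with replicate (edge) padding: the output at
# (r, c) is img[clamp(r + dy), clamp(c + dx)].
shift_replicate <- function(img, dy, dx) {
  M <- nrow(img); N <- ncol(img)
  ri <- pmin(pmax(seq_len(M) + dy, 1L), M)
  ci <- pmin(pmax(seq_len(N) + dx, 1L), N)
  img[ri, ci, drop = FALSE]
}

# Shift a matrix filling out-of-bounds positions with `fill`.
shift_fill <- function(m, dy, dx, fill) {
  M <- nrow(m); N <- ncol(m)
  out <- matrix(fill, M, N)
  rs <- max(1L, 1L + dy):min(M, M + dy)
  cs <- max(1L, 1L + dx):min(N, N + dx)
  if (length(rs) > 0L && length(cs) > 0L)
    out[rs - dy, cs - dx] <- m[rs, cs, drop = FALSE]
  out
}

neighbour_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else if (connectivity == 8L) {
    list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
         c(0L, -1L),              c(0L, 1L),
         c(1L, -1L), c(1L, 0L), c(1L, 1L))
  } else stop("connectivity must be 4 or 8", call. = FALSE)
}

#' Label connected components of a binary mask
#'
#' Assigns a positive integer label to each connected foreground component
#' (background pixels get 0).  Labelling is by iterative minimum-label
#' propagation, so the result is deterministic; labels are re-numbered
#' 1..n_components in order of first (column-major) appearance.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8, the convention used throughout
#'   the pipeline).
#' @return integer matrix of the same shape; 0 = background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  assert_mask(mask)
  offs <- neighbour_offsets(as.integer(connectivity))
  M <- nrow(mask); N <- ncol(mask)
  lab <- matrix(Inf, M, N)
  lab[mask] <- which(mask)  # column-major linear index as provisional label
  repeat {
    nb <- lab
    for (o in offs) nb <- pmin(nb, shift_fill(lab, o[1L], o[2L], Inf))
    nb[!mask] <- Inf
    if (identical(nb, lab)) break
    lab <- nb
  }
  out <- matrix(0L, M, N)
  if (any(mask)) {
    ids <- lab[mask]
    uid <- sort(unique(ids))
    out[mask] <- match(ids, uid)
  }
  out
}

# Largest connected component of a mask (by pixel count); ties broken by
# smaller label id (earlier column-major appearance). Empty mask -> empty.
largest_component <- function(mask, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  if (!any(mask)) return(mask)
  tab <- tabulate(lab[lab > 0L])
  keep <- which.max(tab)
  lab == keep
}

#' Dice overlap coefficient between two binary masks
#'
#' 2|A∩B| / (|A| + |B|); returns 1 when both masks are empty.
#'
#' @param a,b logical matrices of the same shape.
#' @return numeric in [0, 1].
#' @export
dice <- function(a, b) {
  assert_mask(a); assert_mask(b); assert_same_shape(a, b)
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(1)
  2 * sum(a & b) / denom
}
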