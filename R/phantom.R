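# Synthetic mammogram phantoms.
#
# A phantom emulates the structures an MLO-view mammogram presents to the
# pipeline: a breast region shaped as a half-ellipse attached to the
# chest-wall side of the frame, a brighter right-triangle pectoral wedge
# in the upper chest-wall corner, an even brighter Gaussian lesion blob
# inside the breast, a linear illumination ramp, and additive Gaussian
# noise.  Ground-truth breast/pectoral/lesion masks are derived from the
# noiseless composition, so every downstream stage can be scored without
# clinical data.

#' Specify a synthetic mammogram phantom
#'
#' All geometry is given in the canonical left-laterality frame (chest
#' wall at the left image border); `laterality = "right"` mirrors the
#' rendered image and masks horizontally.  Intensities are 8-bit levels
#' and must satisfy background < breast < pectoral.  The lesion centre
#' must lie inside the breast half-ellipse and outside the pectoral
#' wedge.
#'
#' @param side image side length in pixels.
#' @param laterality "left" or "right".
#' @param breast_axes c(vertical, horizontal) semi-axes of the breast
#'   half-ellipse, in pixels; the ellipse is centred on the chest wall at
#'   mid-height.
#' @param pectoral_legs c(vertical, horizontal) leg lengths of the
#'   right-triangle pectoral wedge anchored in the top chest-wall corner.
#' @param background_intensity,breast_intensity,pectoral_intensity flat
#'   8-bit levels of the three compartments.
#' @param lesion_center c(row, col) of the Gaussian lesion blob (0-based,
#'   canonical frame).
#' @param lesion_sigma Gaussian standard deviation of the blob, pixels.
#' @param lesion_amplitude peak added intensity of the blob; 0 disables
#'   the lesion.
#' @param gradient_amplitude peak of a linear top-to-bottom illumination
#'   ramp added to the whole frame.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param seed RNG seed used for the noise.
#' @return a validated `phantom_spec` list.
#' @export
phantom_spec <- function(side = 256L,
                         laterality = "left",
                         breast_axes = c(100, 115),
                         pectoral_legs = c(110, 70),
                         background_intensity = 8,
                         breast_intensity = 90,
                         pectoral_intensity = 190,
                         lesion_center = c(150, 60),
                         lesion_sigma = 14,
                         lesion_amplitude = 70,
                         gradient_amplitude = 10,
                         noise_sigma = 5,
                         seed = 1L) {
  spec <- list(side = as.integer(side), laterality = laterality,
               breast_axes = as.numeric(breast_axes),
               pectoral_legs = as.numeric(pectoral_legs),
               background_intensity = background_intensity,
               breast_intensity = breast_intensity,
               pectoral_intensity = pectoral_intensity,
               lesion_center = as.numeric(lesion_center),
               lesion_sigma = lesion_sigma,
               lesion_amplitude = lesion_amplitude,
               gradient_amplitude = gradient_amplitude,
               noise_sigma = noise_sigma,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  class(spec) <- "phantom_spec"
  spec
}

validate_phantom_spec <- function(s) {
  if (s$side < 16L) stop("side must be at least 16 pixels", call. = FALSE)
  if (!s$laterality %in% LATERALITIES)
    stop("laterality must be 'left' or 'right'", call. = FALSE)
  ints <- c(s$background_intensity, s$breast_intensity, s$pectoral_intensity)
  if (any(ints < 0) || any(ints > 255))
    stop("compartment intensities must lie in [0, 255]", call. = FALSE)
  if (!(s$background_intensity < s$breast_intensity &&
        s$breast_intensity < s$pectoral_intensity))
    stop("intensity ordering violated: need background < breast < pectoral",
         call. = FALSE)
  if (s$lesion_amplitude < 0) stop("lesion_amplitude must be >= 0", call. = FALSE)
  if (s$noise_sigma < 0 || s$gradient_amplitude < 0)
    stop("noise_sigma and gradient_amplitude must be >= 0", call. = FALSE)
  if (s$lesion_amplitude > 0) {
    r0 <- s$lesion_center[1L]; c0 <- s$lesion_center[2L]
    cy <- (s$side - 1) / 2
    inside <- (((r0 - cy) / s$breast_axes[1L])^2 +
               (c0 / s$breast_axes[2L])^2) <= 1 && c0 >= 0
    if (!inside)
      stop("lesion placed outside breast half-ellipse", call. = FALSE)
    in_wedge <- r0 / s$pectoral_legs[1L] + c0 / s$pectoral_legs[2L] <= 1
    if (in_wedge)
      stop("lesion placed inside pectoral wedge", call. = FALSE)
  }
  invisible(TRUE)
}

# Noiseless composition + masks in the canonical (left) frame.
render_noiseless <- function(s) {
  n <- s$side
  r <- matrix(0:(n - 1L), n, n)          # row coordinate, 0-based
  cc <- matrix(0:(n - 1L), n, n, byrow = TRUE)
  cy <- (n - 1) / 2
  ellipse <- ((r - cy) / s$breast_axes[1L])^2 + (cc / s$breast_axes[2L])^2 <= 1
  wedge <- r / s$pectoral_legs[1L] + cc / s$pectoral_legs[2L] <= 1
  breast <- ellipse | wedge
  img <- matrix(s$background_intensity, n, n)
  img[breast] <- s$breast_intensity
  img[wedge] <- s$pectoral_intensity
  lesion_mask <- matrix(FALSE, n, n)
  if (s$lesion_amplitude > 0) {
    d2 <- (r - s$lesion_center[1L])^2 + (cc - s$lesion_center[2L])^2
    blob <- s$lesion_amplitude * exp(-d2 / (2 * s$lesion_sigma^2))
    img <- img + blob
    lesion_mask <- blob >= s$lesion_amplitude / 2
  }
  if (s$gradient_amplitude > 0)
    img <- img + s$gradient_amplitude * r / (n - 1)
  list(img = img, breast_mask = breast, pectoral_mask = wedge,
       lesion_mask = lesion_mask)
}

mirror_h <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

#' Generate one synthetic mammogram phantom
#'
#' Deterministic given `spec$seed`.  The returned truth masks are derived
#' from the noiseless composition; the lesion mask is the set of pixels
#' receiving at least half the blob's peak amplitude.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (integer matrix) and `truth` (list of
#'   `breast_mask`, `pectoral_mask`, `lesion_mask`, `spec`).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  validate_phantom_spec(spec)
  comp <- render_noiseless(spec)
  img <- comp$img
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    img <- img + matrix(stats::rnorm(spec$side^2, 0, spec$noise_sigma),
                        spec$side, spec$side)
  }
  img <- as_gray(img)
  truth <- comp[c("breast_mask", "pectoral_mask", "lesion_mask")]
  if (spec$laterality == "right") {
    img <- mirror_h(img)
    truth <- lapply(truth, mirror_h)
  }
  truth$spec <- spec
  list(image = img, truth = truth)
}

#' Default per-field jitter ranges for phantom cohorts
#'
#' Absolute uniform ranges for the fields a cohort varies; everything not
#' listed stays at the base value.  Geometric ranges are expressed at
#' side 256 and scale proportionally with the base spec's side.
#'
#' @param base the [phantom_spec()] the ranges apply to.
#' @return named list of c(min, max) ranges.
#' @export
default_jitter <- function(base = phantom_spec()) {
  f <- base$side / 256
  list(breast_intensity = c(80, 100),
       pectoral_intensity = c(175, 205),
       lesion_amplitude = c(55, 85),
       lesion_sigma = c(11, 17) * f,
       lesion_center_row = c(130, 180) * f,
       lesion_center_col = c(45, 85) * f,
       pectoral_leg_v = c(95, 125) * f,
       pectoral_leg_h = c(60, 85) * f,
       gradient_amplitude = c(5, 15))
}

#' Generate a cohort of jittered phantoms
#'
#' Parameters are drawn uniformly within the `jitter` ranges from one
#' RNG stream seeded by `seed`; each phantom then renders its noise from
#' a per-phantom sub-seed derived from the same stream, so the cohort is
#' reproducible and independent of evaluation order.
#'
#' @param n number of phantoms (>= 1).
#' @param base base [phantom_spec()].
#' @param jitter named list of c(min, max) ranges; see [default_jitter()].
#'   Supported keys: any scalar intensity/size field plus
#'   `lesion_center_row`, `lesion_center_col`, `pectoral_leg_v`,
#'   `pectoral_leg_h`, `breast_axis_v`, `breast_axis_h`.
#' @param seed master RNG seed.
#' @return list of `n` results of [generate_phantom()].
#' @export
generate_cohort <- function(n, base = phantom_spec(),
                            jitter = default_jitter(base), seed = 1L) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  draws <- lapply(seq_len(n), function(i)
    vapply(jitter, function(rg) stats::runif(1, rg[1L], rg[2L]), numeric(1L)))
  lapply(seq_len(n), function(i) {
    s <- unclass(base)
    d <- draws[[i]]
    for (key in names(d)) {
      val <- d[[key]]
      switch(key,
        lesion_center_row = { s$lesion_center[1L] <- val },
        lesion_center_col = { s$lesion_center[2L] <- val },
        pectoral_leg_v = { s$pectoral_legs[1L] <- val },
        pectoral_leg_h = { s$pectoral_legs[2L] <- val },
        breast_axis_v = { s$breast_axes[1L] <- val },
        breast_axis_h = { s$breast_axes[2L] <- val },
        {
          if (!key %in% names(s)) stop(sprintf("unknown jitter field '%s'", key),
                                       call. = FALSE)
          s[[key]] <- val
        })
    }
    s$seed <- sub_seeds[i]
    args <- s[c("side", "laterality", "breast_axes", "pectoral_legs",
                "background_intensity", "breast_intensity",
                "pectoral_intensity", "lesion_center", "lesion_sigma",
                "lesion_amplitude", "gradient_amplitude", "noise_sigma",
                "seed")]
    generate_phantom(do.call(phantom_spec, args))
  })
}

#' Write a phantom cohort to disk as a pipeline-ready dataset
#'
#' Writes `<id>.png` images, `<id>_breast.png` / `<id>_pectoral.png` /
#' `<id>_lesion.png` truth masks, and a `metadata.csv` consumable by
#' [load_metadata()].  BI-RADS categories are assigned cyclically 1..5 so
#' per-category aggregation is exercised.
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the metadata data.frame.
#' @export
write_phantom_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(cohort), function(i) {
    id <- sprintf("phantom%03d", i)
    ph <- cohort[[i]]
    write_image(ph$image, file.path(dir, paste0(id, ".png")))
    write_mask(ph$truth$breast_mask, file.path(dir, paste0(id, "_breast.png")))
    write_mask(ph$truth$pectoral_mask, file.path(dir, paste0(id, "_pectoral.png")))
    write_mask(ph$truth$lesion_mask, file.path(dir, paste0(id, "_lesion.png")))
    data.frame(id = id, view = "MLO", laterality = ph$truth$spec$laterality,
               birads = ((i - 1L) %% 5L) + 1L,
               path = paste0(id, ".png"), stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, rows)
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}
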