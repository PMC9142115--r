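# Evaluation suite: fidelity (MSE, PSNR), local contrast (EME), and
# region-overlap scores (confusion fractions, accuracy, sensitivity,
# specificity, Dice).
#
# Confusion quantities are fractions of the whole image domain I (not
# raw counts), so TP + TN + FP + FN = 1 and the accuracy
# (TP + TN) / (TP + TN + FP + FN) collapses to TP + TN.

#' Mean squared error between two images
#'
#' @param X,Y integer matrices of the same shape, values in [0, 255].
#' @return non-negative value: mean of (X - Y)^2 over all pixels.
#' @export
mse <- function(X, Y) {
  assert_gray(X); assert_gray(Y); assert_same_shape(X, Y)
  mean((as.numeric(X) - as.numeric(Y))^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' Two modes: `"standard"` computes `10 log10(255^2 / MSE)` (the
#' conventional 8-bit PSNR); `"unsquared_peak"` computes `10 log10(255 / MSE)`
#' with the un-squared peak, the variant some reports print.  Identical
#' images give `Inf`.
#'
#' @inheritParams mse
#' @param mode "standard" (default) or "unsquared_peak".
#' @return PSNR in dB, or `Inf` when MSE is 0.
#' @export
psnr <- function(X, Y, mode = c("standard", "unsquared_peak")) {
  mode <- match.arg(mode)
  m <- mse(X, Y)
  if (m == 0) return(Inf)
  peak <- L_LEVELS - 1L
  if (mode == "standard") 10 * log10(peak^2 / m) else 10 * log10(peak / m)
}

#' Effective measure of enhancement (EME)
#'
#' The image is partitioned into `k1` block columns and `k2` block rows
#' (remainder pixels are absorbed into the last block row/column); each
#' block contributes `20 log10((Imax + eps) / (Imin + eps))` and the EME
#' is the mean over the K1*K2 blocks.  `eps` guards blocks whose
#' minimum is 0.
#'
#' @param img integer matrix in [0, 255].
#' @param k1 number of block columns (horizontal blocks), >= 1, <= N.
#' @param k2 number of block rows (vertical blocks), >= 1, <= M.
#' @param eps additive guard, default 1.
#' @return non-negative value in dB.
#' @export
eme <- function(img, k1 = 8L, k2 = 8L, eps = 1) {
  assert_gray(img)
  k1 <- as.integer(k1); k2 <- as.integer(k2)
  M <- nrow(img); N <- ncol(img)
  if (k1 < 1L || k2 < 1L || k1 > N || k2 > M)
    stop("block counts must be >= 1 and not exceed the image dimensions",
         call. = FALSE)
  rb <- floor(M / k2); cb <- floor(N / k1)
  total <- 0
  for (l in seq_len(k2)) {
    rs <- ((l - 1L) * rb + 1L):(if (l == k2) M else l * rb)
    for (k in seq_len(k1)) {
      cs <- ((k - 1L) * cb + 1L):(if (k == k1) N else k * cb)
      blk <- img[rs, cs]
      total <- total + 20 * log10((max(blk) + eps) / (min(blk) + eps))
    }
  }
  total / (k1 * k2)
}

#' Confusion fractions of a segmentation against ground truth
#'
#' All four quantities are normalised by the full image domain:
#' `tp = |A_S ∩ A_T| / |I|`, `tn = |!A_S ∩ !A_T| / |I|`,
#' `fp = |A_S ∩ !A_T| / |I|`, `fn = |!A_S ∩ A_T| / |I|`; they sum to 1.
#'
#' @param A_S segmented logical mask.
#' @param A_T ground-truth logical mask, same shape.
#' @return named list (tp, tn, fp, fn).
#' @export
confusion_fractions <- function(A_S, A_T) {
  assert_mask(A_S); assert_mask(A_T); assert_same_shape(A_S, A_T)
  n <- length(A_S)
  list(tp = sum(A_S & A_T) / n, tn = sum(!A_S & !A_T) / n,
       fp = sum(A_S & !A_T) / n, fn = sum(!A_S & A_T) / n)
}

#' Segmentation accuracy
#'
#' `(tp + tn) / (tp + tn + fp + fn)`; with domain-normalised fractions
#' the denominator is identically 1, so this equals `tp + tn`.
#'
#' @inheritParams confusion_fractions
#' @return fraction in [0, 1].
#' @export
accuracy <- function(A_S, A_T) {
  f <- confusion_fractions(A_S, A_T)
  (f$tp + f$tn) / (f$tp + f$tn + f$fp + f$fn)
}

#' Sensitivity and specificity
#'
#' `se = tp / (tp + fn)` (undefined, `NA`, when the truth is empty);
#' `sp = tn / (tn + fp)` (undefined when the truth covers the image).
#'
#' @inheritParams confusion_fractions
#' @return named list (sensitivity, specificity); undefined values are
#'   `NA` with a warning.
#' @export
sensitivity_specificity <- function(A_S, A_T) {
  f <- confusion_fractions(A_S, A_T)
  se <- if (f$tp + f$fn == 0) { warning("empty truth mask: sensitivity undefined"); NA_real_ }
        else f$tp / (f$tp + f$fn)
  sp <- if (f$tn + f$fp == 0) { warning("full truth mask: specificity undefined"); NA_real_ }
        else f$tn / (f$tn + f$fp)
  list(sensitivity = se, specificity = sp)
}

#' Assemble a full metrics report for one image
#'
#' Fidelity metrics compare `enhanced` against `reference`; EME is
#' reported for both `original` and `enhanced`; overlap metrics compare
#' `A_S` against `A_T`.  Any pairing may be omitted (its fields are NA).
#'
#' @param A_S,A_T segmentation and truth masks (optional).
#' @param reference,enhanced image pair for MSE/PSNR (optional).
#' @param original image whose EME is reported as `eme_before`
#'   (optional; `enhanced` gives `eme_after`).
#' @param eme_blocks c(k1, k2) block grid for EME.
#' @param psnr_mode passed to [psnr()].
#' @param id,category identifiers carried into the report row.
#' @return one-row data.frame with columns id, category, mse, psnr_db,
#'   eme_before, eme_after, tp, tn, fp, fn, accuracy, sensitivity,
#'   specificity, dice.
#' @export
evaluate <- function(A_S = NULL, A_T = NULL, reference = NULL, enhanced = NULL,
                     original = NULL, eme_blocks = c(8L, 8L),
                     psnr_mode = "standard", id = NA_character_,
                     category = NA_integer_) {
  row <- data.frame(id = id, category = category, mse = NA_real_,
                    psnr_db = NA_real_, eme_before = NA_real_,
                    eme_after = NA_real_, tp = NA_real_, tn = NA_real_,
                    fp = NA_real_, fn = NA_real_, accuracy = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_,
                    dice = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(reference) && !is.null(enhanced)) {
    row$mse <- mse(reference, enhanced)
    row$psnr_db <- psnr(reference, enhanced, psnr_mode)
  }
  if (!is.null(original)) row$eme_before <- eme(original, eme_blocks[1L], eme_blocks[2L])
  if (!is.null(enhanced)) row$eme_after <- eme(enhanced, eme_blocks[1L], eme_blocks[2L])
  if (!is.null(A_S) && !is.null(A_T)) {
    f <- confusion_fractions(A_S, A_T)
    row$tp <- f$tp; row$tn <- f$tn; row$fp <- f$fp; row$fn <- f$fn
    row$accuracy <- f$tp + f$tn
    ss <- suppressWarnings(sensitivity_specificity(A_S, A_T))
    row$sensitivity <- ss$sensitivity; row$specificity <- ss$specificity
    row$dice <- dice(A_S, A_T)
  }
  row
}
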