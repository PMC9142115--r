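test_that("MSE matches hand-computed cases", {
  X <- matrix(0L, 2, 2)
  expect_identical(mse(X, X), 0)
  Y <- matrix(10L, 2, 2)
  expect_identical(mse(X, Y), 100)
  Z <- matrix(c(1L, 3L, 2L, 4L), 2, 2)
  expect_identical(mse(X, Z), 7.5)   # (1+4+9+16)/4
  expect_error(mse(X, matrix(0L, 3, 3)), "shape")
})

test_that("PSNR follows both published forms and decreases in MSE", {
  X <- matrix(0L, 4, 4)
  expect_identical(psnr(X, X), Inf)
  expect_identical(psnr(X, X, "unsquared_peak"), Inf)

  Y255 <- matrix(255L, 4, 4)
  expect_equal(psnr(X, Y255), 0)
  Y16 <- matrix(16L, 4, 4)     # MSE = 256
  expect_equal(psnr(X, Y16), 10 * log10(65025 / 256))
  expect_equal(psnr(X, Y16, "unsquared_peak"), 10 * log10(255 / 256))

  set.seed(51)
  X8 <- matrix(0L, 8, 8)
  mses <- psnrs <- numeric(10)
  for (i in 1:10) {
    Y <- random_image(8, 8)
    mses[i] <- mse(X8, Y); psnrs[i] <- psnr(X8, Y)
  }
  ord <- order(mses)
  expect_true(all(diff(psnrs[ord]) <= 0))
})

test_that("EME matches block-wise hand evaluation", {
  expect_identical(eme(matrix(33L, 8, 8), 4, 4), 0)

  blk <- matrix(c(200L, 2L, 2L, 200L), 2, 2)
  expect_equal(eme(blk, 1, 1, eps = 0), 40)   # 20 log10(100)

  two <- cbind(matrix(c(200L, 2L), 2, 2), matrix(9L, 2, 2))
  expect_equal(eme(two, 2, 1, eps = 0), 20)   # mean of 40 and 0

  expect_error(eme(matrix(0L, 4, 4), 5, 1), "block")

  # remainder pixels are absorbed by the last block, not dropped
  img <- matrix(0L, 5, 5); img[5, 5] <- 255L
  expect_gt(eme(img, 2, 2), 0)
})

test_that("confusion fractions, accuracy and se/sp match the pixel-count case", {
  A_T <- matrix(FALSE, 4, 4); A_T[1, 1:4] <- TRUE          # |A_T| = 4
  A_S <- matrix(FALSE, 4, 4); A_S[1, 1:2] <- TRUE; A_S[3, 3] <- TRUE
  f <- confusion_fractions(A_S, A_T)
  expect_equal(unlist(f), c(tp = 2, tn = 11, fp = 1, fn = 2) / 16)
  expect_equal(accuracy(A_S, A_T), 13 / 16)
  ss <- sensitivity_specificity(A_S, A_T)
  expect_equal(ss$sensitivity, 0.5)
  expect_equal(ss$specificity, 11 / 12)

  expect_equal(accuracy(A_T, A_T), 1)
  expect_equal(accuracy(!A_T, A_T), 0)
  f2 <- confusion_fractions(!A_T, A_T)
  expect_equal(f2$tp + f2$tn, 0)

  empty <- matrix(FALSE, 4, 4)
  expect_warning(ss <- sensitivity_specificity(A_S, empty), "sensitivity")
  expect_true(is.na(ss$sensitivity))
})

test_that("metric values agree with brute-force loops on random instances", {
  set.seed(52)
  for (rep in 1:20) {
    X <- random_image(16, 16); Y <- random_image(16, 16)
    expect_equal(mse(X, Y), o_mse(X, Y), tolerance = 1e-12)
    A <- random_mask(16, 16); B <- random_mask(16, 16)
    expect_equal(unlist(confusion_fractions(A, B)), unlist(o_confusion(A, B)),
                 tolerance = 1e-12)
    k1 <- sample(1:5, 1); k2 <- sample(1:5, 1)
    expect_equal(eme(X, k1, k2), o_eme(X, k1, k2, 1), tolerance = 1e-12)
  }
})

test_that("overlap metrics are invariant under simultaneous mirroring", {
  set.seed(53)
  for (rep in 1:5) {
    A <- random_mask(9, 12); B <- random_mask(9, 12)
    mir <- function(m) m[, rev(seq_len(ncol(m)))]
    expect_identical(confusion_fractions(A, B),
                     confusion_fractions(mir(A), mir(B)))
    img <- random_image(16, 16)
    expect_equal(eme(img, 4, 4), eme(img[, 16:1], 4, 4), tolerance = 1e-12)
  }
})

test_that("evaluate fills a consistent one-row report", {
  ph <- generate_phantom(small_phantom_spec(noise_sigma = 0))
  row <- evaluate(A_S = ph$truth$lesion_mask, A_T = ph$truth$lesion_mask,
                  reference = ph$image, enhanced = ph$image,
                  original = ph$image, id = "p1", category = 2L)
  expect_identical(row$mse, 0)
  expect_identical(row$psnr_db, Inf)
  expect_equal(row$accuracy, 1)
  expect_equal(row$dice, 1)
  expect_equal(row$tp + row$tn + row$fp + row$fn, 1, tolerance = 1e-12)

  set.seed(54)
  A <- random_mask(8, 8); B <- random_mask(8, 8)
  r2 <- evaluate(A_S = A, A_T = B)
  expect_equal(r2$tp + r2$tn + r2$fp + r2$fn, 1, tolerance = 1e-12)
  expect_equal(r2$accuracy, r2$tp + r2$tn, tolerance = 1e-12)
  expect_true(is.na(r2$mse))
})
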