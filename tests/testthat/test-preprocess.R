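test_that("orientation follows the intensity-mass rule and mirror-flips", {
  img <- matrix(0L, 10, 10); img[, 1:4] <- 200L
  expect_identical(detect_orientation(img), "left")
  expect_identical(detect_orientation(img[, 10:1]), "right")

  set.seed(21)
  for (rep in 1:10) {
    img <- random_image(12, 13)
    lat <- tryCatch(detect_orientation(img), error = function(e) NULL)
    if (is.null(lat)) next
    flipped <- detect_orientation(img[, rev(seq_len(ncol(img)))])
    expect_identical(flipped, setdiff(c("left", "right"), lat))
  }
  expect_error(detect_orientation(matrix(7L, 5, 5)), "constant")

  ph <- generate_phantom(small_phantom_spec(laterality = "right"))
  expect_identical(detect_orientation(ph$image), "right")
})

test_that("breast mask keeps the largest supra-threshold component", {
  s <- small_phantom_spec(noise_sigma = 0, gradient_amplitude = 0)
  ph <- generate_phantom(s)
  m <- extract_breast_mask(ph$image, s$background_intensity)
  expect_gte(dice(m, ph$truth$breast_mask), 0.99)

  img <- matrix(0L, 20, 20)
  img[2:10, 2:10] <- 100L   # large blob
  img[15:16, 15:16] <- 100L # small distant blob
  m <- extract_breast_mask(img, 50)
  expect_true(all(m[2:10, 2:10]))
  expect_false(any(m[15:16, 15:16]))
  expect_error(extract_breast_mask(img, 255), "threshold")
})

test_that("pectoral seed lands at the chest-wall corner inset", {
  img <- matrix(0L, 256, 256)
  expect_identical(select_pectoral_seed(img, "left", 5L), list(row = 5L, col = 5L))
  expect_identical(select_pectoral_seed(img, "right", 5L), list(row = 5L, col = 250L))
  expect_error(select_pectoral_seed(img, "left", 200L), "offset")

  for (lat in c("left", "right")) {
    ph <- generate_phantom(small_phantom_spec(laterality = lat))
    seed <- select_pectoral_seed(ph$image, lat, 5L)
    expect_true(ph$truth$pectoral_mask[seed$row + 1L, seed$col + 1L])
  }
})

test_that("region growing matches closed-form regions on constructed images", {
  const <- matrix(9L, 6, 7)
  grown <- region_grow(const, list(row = 2L, col = 3L), 0)
  expect_true(all(grown))

  img <- matrix(50L, 8, 8)
  r <- matrix(0:7, 8, 8); cc <- matrix(0:7, 8, 8, byrow = TRUE)
  tri <- r + cc <= 3
  img[tri] <- 200L
  for (pred in c("running_mean", "fixed_seed")) {
    grown <- region_grow(img, list(row = 0L, col = 0L), 10, 8L, pred)
    expect_identical(grown, tri)
  }

  iso <- matrix(c(5L, 50L, 50L, 50L), 2, 2)
  grown <- region_grow(iso, list(row = 0L, col = 0L), 0)
  expect_identical(sum(grown), 1L)
  expect_true(grown[1, 1])
})

test_that("region growing is connected, contains the seed, and is monotone in tolerance", {
  set.seed(22)
  for (rep in 1:10) {
    img <- random_image(16, 16)
    seed <- list(row = sample(0:15, 1), col = sample(0:15, 1))
    prev <- NULL
    for (tol in c(0, 10, 50, 255)) {
      m <- region_grow(img, seed, tol, 8L, "fixed_seed")
      expect_true(m[seed$row + 1L, seed$col + 1L])
      lab <- label_components(m, 8L)
      expect_identical(max(lab), 1L)
      if (!is.null(prev)) expect_true(all(m[prev]))
      prev <- m
    }
  }
})

test_that("pectoral removal recovers the phantom wedge and zeroes it", {
  s <- small_phantom_spec(noise_sigma = 0)
  ph <- generate_phantom(s)
  res <- remove_pectoral(ph$image)
  expect_gte(dice(res$pectoral_mask, ph$truth$pectoral_mask), 0.95)
  expect_true(all(res$cleaned[res$pectoral_mask] == 0L))
  expect_identical(res$cleaned[!res$pectoral_mask], ph$image[!res$pectoral_mask])
  expect_true(all(res$pectoral_mask | !res$pectoral_mask))
  expect_true(all(!res$pectoral_mask | res$breast_mask))  # pectoral within breast

  noisy <- generate_phantom(small_phantom_spec(noise_sigma = 5))
  res <- remove_pectoral(noisy$image)
  expect_gte(dice(res$pectoral_mask, noisy$truth$pectoral_mask), 0.90)
})

test_that("CC view skips pectoral removal", {
  ph <- generate_phantom(small_phantom_spec())
  expect_message(res <- remove_pectoral(ph$image, view = "CC"), "CC view")
  expect_identical(sum(res$pectoral_mask), 0L)
  expect_identical(res$cleaned, ph$image)
})

test_that("component labelling agrees with brute-force fill on random masks", {
  set.seed(23)
  for (rep in 1:8) {
    m <- random_mask(12, 12, 0.4)
    for (conn in c(4L, 8L)) {
      a <- label_components(m, conn)
      b <- o_label(m, conn)
      # same partition: labels may differ by renaming only
      expect_identical(a > 0L, b > 0L)
      expect_identical(max(a), max(b))
      for (k in seq_len(max(b))) {
        ids <- unique(a[b == k])
        expect_identical(length(ids), 1L)
      }
    }
  }
})
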