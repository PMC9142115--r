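# K-means -------------------------------------------------------------

test_that("k-means degenerate and analytic optima are recovered", {
  img <- matrix(c(rep(10L, 32), rep(200L, 32)), 8, 8)
  one <- kmeans_segment(img, 1)
  expect_true(all(one$labels == 0L))
  expect_equal(one$model$centroids[1, 1], mean(img))

  two <- kmeans_segment(img, 2, seed = 5)
  expect_true(all(two$labels[img == 10L] == 0L))
  expect_true(all(two$labels[img == 200L] == 1L))
  expect_equal(sort(two$model$centroids[, 1]), c(10, 200))

  img3 <- matrix(rep(c(0L, 100L, 200L), length.out = 36), 6, 6)
  exact <- kmeans_segment(img3, 3, seed = 5)
  expect_equal(exact$model$inertia, 0)

  expect_warning(kmeans_segment(img, 5, seed = 1), "reduced")
})

test_that("k-means is deterministic and its inertia trace never rises", {
  set.seed(41)
  for (rep in 1:5) {
    img <- random_image(24, 24)
    a <- kmeans_segment(img, 4, seed = rep)
    b <- kmeans_segment(img, 4, seed = rep)
    expect_identical(a$labels, b$labels)
    expect_true(all(diff(a$model$inertia_trace) <= 1e-9))
    expect_true(all(a$labels >= 0L & a$labels < a$k))
    expect_identical(sort(unique(as.vector(a$labels))), 0:(a$k - 1L))
  }
})

test_that("converged k-means centroids are a fixed point of stats::kmeans", {
  set.seed(42)
  img <- random_image(20, 20)
  fit <- kmeans_segment(img, 4, seed = 9)
  ref <- stats::kmeans(as.numeric(img), centers = fit$model$centroids,
                       algorithm = "Lloyd", iter.max = 100)
  expect_equal(ref$tot.withinss, fit$model$inertia, tolerance = 1e-9)
})

test_that("spatial k-means reduces to intensity k-means at weight 0", {
  set.seed(43)
  img <- random_image(16, 16)
  plain <- kmeans_segment(img, 3, seed = 2)
  spatial <- kmeans_spatial_segment(img, 3, spatial_weight = 0, seed = 2)
  expect_equal(spatial$model$inertia, plain$model$inertia, tolerance = 1e-9)
  expect_identical(spatial$labels, plain$labels)
})

test_that("spatial k-means separates distant identical-intensity blobs", {
  img <- matrix(0L, 16, 16)
  img[2:4, 2:4] <- 100L
  img[13:15, 13:15] <- 100L
  mask <- img > 0L
  seg <- kmeans_spatial_segment(img, 2, spatial_weight = 500, mask = mask,
                                seed = 1)
  l1 <- unique(as.vector(seg$labels[2:4, 2:4]))
  l2 <- unique(as.vector(seg$labels[13:15, 13:15]))
  expect_identical(length(l1), 1L)
  expect_identical(length(l2), 1L)
  expect_false(l1 == l2)
})

# Mean shift ----------------------------------------------------------

test_that("1-D mean shift finds the intensity modes", {
  expect_identical(mean_shift_segment(matrix(9L, 5, 5), 10)$k, 1L)

  img <- matrix(c(rep(20L, 30), rep(220L, 34)), 8, 8)
  seg <- mean_shift_segment(img, 30)
  expect_identical(seg$k, 2L)
  expect_true(all(seg$labels[img == 20L] == 0L))
  expect_true(all(seg$labels[img == 220L] == 1L))

  set.seed(44)
  wide <- mean_shift_segment(random_image(10, 10), 255)
  expect_identical(wide$k, 1L)
})

test_that("joint-feature mean shift separates spatially distant blobs", {
  expect_identical(mean_shift_spatial_segment(matrix(7L, 8, 8), 3, 10)$k, 1L)

  img <- matrix(0L, 16, 16)
  img[2:4, 2:4] <- 200L
  img[13:15, 13:15] <- 200L
  seg <- mean_shift_spatial_segment(img, 3, 40)
  expect_false(seg$labels[3, 3] == seg$labels[14, 14])
  expect_true(seg$k <= length(img))
  expect_identical(sort(unique(as.vector(seg$labels))), 0:(seg$k - 1L))
})

# Normalized cuts ------------------------------------------------------

test_that("normalized cuts is exact on zero-cross-affinity instances", {
  expect_identical(normalized_cuts_segment(matrix(5L, 8, 8), 1)$k, 1L)

  img <- matrix(0L, 16, 16)
  img[2:5, 2:5] <- 200L
  img[12:15, 12:15] <- 200L
  seg <- suppressMessages(
    normalized_cuts_segment(img, n_segments = 3, sigma_intensity = 10,
                            sigma_distance = 4, neighbourhood_radius = 2,
                            downsample_to = 16))
  expect_identical(length(unique(seg$labels[cbind(c(3, 13), c(3, 13))])), 2L)
  expect_true(all(seg$labels[2:5, 2:5] == seg$labels[3, 3]))
  expect_true(all(seg$labels[12:15, 12:15] == seg$labels[13, 13]))
})

test_that("returned bipartitions are near the exhaustive Ncut optimum", {
  set.seed(45)
  for (rep in 1:6) {
    n <- sample(6:10, 1)
    W <- matrix(stats::runif(n * n, 0.01, 1), n, n)
    W <- (W + t(W)) / 2; diag(W) <- 0
    bp <- ncut_bipartition(W)
    expect_equal(bp$ncut, ncut_value(W, bp$in_a), tolerance = 1e-12)
    expect_lte(bp$ncut, 1.1 * o_ncut_min(W) + 1e-12)
  }
})

# Abnormal-region extraction -------------------------------------------

test_that("the brightest-cluster rule finds the phantom lesion", {
  ph <- generate_phantom(small_phantom_spec(noise_sigma = 2))
  pre <- remove_pectoral(ph$image)
  roi <- pre$breast_mask & !pre$pectoral_mask
  seg <- kmeans_segment(ph$image, 2, mask = roi, seed = 3)
  A_S <- extract_abnormal_region(seg$labels, ph$image, roi)
  ctr <- round(colMeans(which(A_S, arr.ind = TRUE)))
  expect_true(ph$truth$lesion_mask[ctr[1L], ctr[2L]])

  single <- matrix(0L, nrow(ph$image), ncol(ph$image))
  expect_message(deg <- extract_abnormal_region(single, ph$image, roi),
                 "single-label")
  expect_identical(deg, largest_component(roi))

  expect_error(extract_abnormal_region(seg$labels, ph$image,
                                       matrix(FALSE, nrow(ph$image), ncol(ph$image))),
               "empty breast")
  expect_warning(
    empty <- extract_abnormal_region(seg$labels, ph$image, roi,
                                     min_area = length(ph$image)),
    "min_area")
  expect_identical(sum(empty), 0L)
})
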