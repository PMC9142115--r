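# Stage 3: clustering-based segmentation of the abnormal region.
#
# Five segmenters produce pixel label maps: K-means on intensity,
# K-means on joint intensity+position features, mean shift on intensity,
# mean shift on joint features, and normalized cuts (spectral graph
# partitioning).  A selection rule then extracts the candidate abnormal
# region: the brightest cluster inside the breast, reduced to its
# largest connected component.

# ---- K-means (Lloyd) -------------------------------------------------

# k-means++ seeding; assumes the RNG is already seeded by the caller.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      if (sum(d2) == 0) {
        idx <- sample.int(n, 1L)
      } else {
        idx <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2))
    }
  }
  centers
}

assign_nearest <- function(X, centers) {
  n <- nrow(X); k <- nrow(centers)
  D <- matrix(0, n, k)
  for (j in seq_len(k))
    D[, j] <- rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
  list(cluster = max.col(-D, ties.method = "first"),
       mindist = D[cbind(seq_len(n), max.col(-D, ties.method = "first"))])
}

# Lloyd iterations with k-means++ init, per-iteration inertia trace, and
# empty-cluster repair by re-seeding at the farthest point.
lloyd <- function(X, k, seed, max_iter = 100L, tol = 1e-4) {
  set.seed(as.integer(seed))
  centers <- kmeanspp_init(X, k)
  trace <- numeric(0)
  cl <- rep(0L, nrow(X))
  for (it in seq_len(max_iter)) {
    a <- assign_nearest(X, centers)
    trace <- c(trace, sum(a$mindist))
    new_centers <- centers
    for (j in seq_len(k)) {
      memb <- a$cluster == j
      if (!any(memb)) {
        far <- which.max(a$mindist)
        new_centers[j, ] <- X[far, ]
        a$cluster[far] <- j
        a$mindist[far] <- 0
      } else {
        new_centers[j, ] <- colMeans(X[memb, , drop = FALSE])
      }
    }
    shift <- max(abs(new_centers - centers))
    same <- identical(a$cluster, cl)
    centers <- new_centers
    cl <- a$cluster
    if (same || shift < tol) break
  }
  a <- assign_nearest(X, centers)
  list(cluster = a$cluster, centers = centers, inertia = sum(a$mindist),
       inertia_trace = trace, iterations = length(trace))
}

# Shared wrapper: run Lloyd on per-pixel features restricted to a mask
# and return a label map with clusters re-numbered 0..k-1 by ascending
# intensity centroid (outside-mask pixels are NA).
kmeans_core <- function(img, feats, k, mask, seed, max_iter, tol) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  assert_mask(mask); assert_same_shape(img, mask)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  X <- feats[as.vector(mask), , drop = FALSE]
  ndistinct <- nrow(unique(X))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > ndistinct) {
    warning(sprintf("k reduced from %d to %d distinct feature vectors", k, ndistinct))
    k <- ndistinct
  }
  fit <- lloyd(X, k, seed, max_iter, tol)
  ord <- order(fit$centers[, 1L])
  relabel <- integer(k); relabel[ord] <- seq_len(k) - 1L
  labels <- matrix(NA_integer_, nrow(img), ncol(img))
  labels[mask] <- relabel[fit$cluster]
  model <- list(centroids = fit$centers[ord, , drop = FALSE],
                inertia = fit$inertia, inertia_trace = fit$inertia_trace,
                iterations = fit$iterations, k = k)
  list(labels = labels, k = k, model = model)
}

#' K-means intensity segmentation
#'
#' Lloyd iterations with k-means++ seeding on the 1-D pixel-intensity
#' feature, optionally restricted to a mask.  Deterministic given
#' `seed`; the per-iteration inertia trace is returned in the model.
#' Clusters are numbered 0..k-1 by ascending intensity centroid.
#'
#' @param img integer matrix in [0, 255].
#' @param k number of clusters; reduced with a warning if it exceeds the
#'   number of distinct feature vectors present.
#' @param mask optional logical matrix restricting the pixels clustered
#'   (default: whole image); pixels outside get label NA.
#' @param seed RNG seed for the initialisation.
#' @param max_iter,tol Lloyd iteration cap and centroid-shift tolerance.
#' @return list with `labels` (integer matrix, 0-based ids), `k`, and
#'   `model` (centroids, inertia, inertia_trace, iterations).
#' @export
kmeans_segment <- function(img, k, mask = NULL, seed = 0L, max_iter = 100L,
                           tol = 1e-4) {
  assert_gray(img)
  feats <- matrix(as.numeric(img), ncol = 1L)
  kmeans_core(img, feats, k, mask, seed, max_iter, tol)
}

#' K-means segmentation on joint intensity + position features
#'
#' Features are (intensity, w * row / M, w * col / N) with 0-based
#' pixel coordinates; `spatial_weight = 0` reduces exactly to
#' [kmeans_segment()]'s partition (same seed, same inertia).
#'
#' @inheritParams kmeans_segment
#' @param spatial_weight non-negative weight of the normalised
#'   coordinates relative to intensity (intensity spans 0..255, each
#'   normalised coordinate spans 0..w).
#' @export
kmeans_spatial_segment <- function(img, k, spatial_weight = 100,
                                   mask = NULL, seed = 0L, max_iter = 100L,
                                   tol = 1e-4) {
  assert_gray(img)
  if (spatial_weight < 0) stop("spatial_weight must be >= 0", call. = FALSE)
  M <- nrow(img); N <- ncol(img)
  r <- matrix(0:(M - 1L), M, N); cc <- matrix(0:(N - 1L), M, N, byrow = TRUE)
  feats <- cbind(as.numeric(img), spatial_weight * as.numeric(r) / M,
                 spatial_weight * as.numeric(cc) / N)
  kmeans_core(img, feats, k, mask, seed, max_iter, tol)
}

# ---- Mean shift ------------------------------------------------------

#' Mean-shift intensity segmentation
#'
#' Each pixel's intensity ascends to a mode of the 1-D kernel density
#' under a flat kernel of half-width `range_bandwidth` (iterated window
#' means over the intensity histogram); converged modes closer than
#' `merge_tol` are merged.  Labels are 0..k-1 by ascending mode.
#'
#' @param img integer matrix in [0, 255].
#' @param range_bandwidth flat-kernel half-width, intensity units (> 0).
#' @param max_iter iteration cap.
#' @param merge_tol mode merge tolerance (default `range_bandwidth / 2`).
#' @return list with `labels` (integer matrix), `k`, and `modes`.
#' @export
mean_shift_segment <- function(img, range_bandwidth, max_iter = 100L,
                               merge_tol = NULL) {
  assert_gray(img)
  if (range_bandwidth <= 0) stop("range_bandwidth must be > 0", call. = FALSE)
  if (is.null(merge_tol)) merge_tol <- range_bandwidth / 2
  u <- sort(unique(as.vector(img)))
  w <- tabulate(as.integer(img) + 1L, nbins = 256L)[u + 1L]
  x <- as.numeric(u)
  for (it in seq_len(max_iter)) {
    A <- abs(outer(x, as.numeric(u), "-")) <= range_bandwidth
    xn <- as.vector(A %*% (u * w)) / as.vector(A %*% w)
    if (max(abs(xn - x)) < 1e-3) { x <- xn; break }
    x <- xn
  }
  modes <- merge_modes_1d(x, merge_tol)
  value_label <- modes$assign               # per unique value, 1-based
  labels <- matrix(value_label[match(as.vector(img), u)] - 1L,
                   nrow(img), ncol(img))
  list(labels = labels, k = modes$k, modes = modes$centers)
}

# Single-linkage 1-D mode merging: sorted converged modes start a new
# group when the gap to the previous mode exceeds tol.
merge_modes_1d <- function(x, tol) {
  ord <- order(x)
  groups <- integer(length(x))
  cur <- 0L
  prev <- NA_real_
  for (i in ord) {
    if (cur == 0L || x[i] - prev > tol) cur <- cur + 1L
    groups[i] <- cur
    prev <- x[i]
  }
  centers <- as.vector(tapply(x, groups, mean))
  list(assign = groups, k = cur, centers = centers)
}

#' Mean-shift segmentation on joint spatial + intensity features
#'
#' Joint (row, col, intensity) mean-shift filtering with a flat product
#' kernel (Euclidean spatial window of radius `spatial_bandwidth`,
#' intensity window of half-width `range_bandwidth`), followed by mode
#' merging.  Images larger than 64 pixels on a side are processed on a
#' strided downsample and the labels upsampled by nearest neighbour.
#'
#' @param img integer matrix in [0, 255].
#' @param spatial_bandwidth spatial window radius, pixels (> 0).
#' @param range_bandwidth intensity window half-width (> 0).
#' @param max_iter iteration cap.
#' @param merge_tol intensity merge tolerance (default
#'   `range_bandwidth / 2`); spatial merge tolerance is
#'   `spatial_bandwidth / 2`.
#' @return list with `labels` (integer matrix) and `k`.
#' @export
mean_shift_spatial_segment <- function(img, spatial_bandwidth, range_bandwidth,
                                       max_iter = 50L, merge_tol = NULL) {
  assert_gray(img)
  if (spatial_bandwidth <= 0 || range_bandwidth <= 0)
    stop("bandwidths must be > 0", call. = FALSE)
  if (is.null(merge_tol)) merge_tol <- range_bandwidth / 2
  ds <- stride_downsample(img, 64L)
  sub <- ds$img
  M <- nrow(sub); N <- ncol(sub); n <- M * N
  r <- as.numeric(matrix(0:(M - 1L), M, N))
  cc <- as.numeric(matrix(0:(N - 1L), M, N, byrow = TRUE))
  intens <- as.numeric(sub)
  # positions are in downsampled units; scale the spatial bandwidth
  hs <- spatial_bandwidth / ds$stride
  Y <- cbind(r, cc, intens)
  X <- Y
  for (it in seq_len(max_iter)) {
    shift_max <- 0
    for (start in seq(1L, n, by = 2048L)) {
      idx <- start:min(start + 2047L, n)
      d2 <- outer(Y[idx, 1L], X[, 1L], "-")^2 + outer(Y[idx, 2L], X[, 2L], "-")^2
      nb <- d2 <= hs^2 & abs(outer(Y[idx, 3L], X[, 3L], "-")) <= range_bandwidth
      cnt <- rowSums(nb)
      upd <- cbind(as.vector(nb %*% X[, 1L]), as.vector(nb %*% X[, 2L]),
                   as.vector(nb %*% X[, 3L])) / cnt
      shift_max <- max(shift_max, max(abs(upd - Y[idx, , drop = FALSE])))
      Y[idx, ] <- upd
    }
    if (shift_max < 1e-3) break
  }
  # single-linkage merge of converged points: two modes join when they
  # are within half the spatial bandwidth and merge_tol in intensity
  lab <- merge_joint_modes(Y, hs / 2, merge_tol)
  labels_sub <- matrix(lab - 1L, M, N)
  labels <- upsample_nn(labels_sub, ds, dim(img))
  list(labels = labels, k = max(lab))
}

# Union-find single-linkage clustering of converged mode points; works
# on the deduplicated (rounded) positions so coincident modes are cheap.
# Components are numbered 1..k in order of first pixel appearance.
merge_joint_modes <- function(Y, spatial_tol, intensity_tol) {
  key <- paste(round(Y[, 1L], 2L), round(Y[, 2L], 2L), round(Y[, 3L], 2L))
  uk <- unique(key)
  map <- match(key, uk)
  U <- Y[match(uk, key), , drop = FALSE]
  m <- nrow(U)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (start in seq(1L, m, by = 1024L)) {
    idx <- start:min(start + 1023L, m)
    d2 <- outer(U[idx, 1L], U[, 1L], "-")^2 + outer(U[idx, 2L], U[, 2L], "-")^2
    close <- d2 <= spatial_tol^2 &
      abs(outer(U[idx, 3L], U[, 3L], "-")) <= intensity_tol
    ee <- which(close, arr.ind = TRUE)
    for (k in seq_len(nrow(ee))) {
      a <- find(idx[ee[k, 1L]]); b <- find(ee[k, 2L])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(map, find, integer(1L))
  match(roots, unique(roots))
}

# Strided downsampling so that both dimensions are <= max_side; keeps
# the sampling grid for nearest-neighbour upsampling.
stride_downsample <- function(img, max_side) {
  stride <- max(1L, as.integer(ceiling(max(dim(img)) / max_side)))
  ri <- seq(1L, nrow(img), by = stride)
  ci <- seq(1L, ncol(img), by = stride)
  list(img = img[ri, ci, drop = FALSE], stride = stride, ri = ri, ci = ci)
}

upsample_nn <- function(labels_sub, ds, full_dim) {
  if (ds$stride == 1L) return(labels_sub)
  rmap <- pmin(((seq_len(full_dim[1L]) - 1L) %/% ds$stride) + 1L, nrow(labels_sub))
  cmap <- pmin(((seq_len(full_dim[2L]) - 1L) %/% ds$stride) + 1L, ncol(labels_sub))
  labels_sub[rmap, cmap, drop = FALSE]
}

# ---- Normalized cuts -------------------------------------------------

#' The normalized-cut value of a bipartition
#'
#' `cut(A, B) / assoc(A, V) + cut(A, B) / assoc(B, V)` for an affinity
#' matrix `W`; `Inf` when a side has zero association.
#'
#' @param W symmetric non-negative affinity matrix (base or Matrix).
#' @param in_a logical vector marking side A.
#' @return non-negative value (0 for a zero cut).
#' @export
ncut_value <- function(W, in_a) {
  d <- Matrix::rowSums(W)
  cut <- sum(W[in_a, !in_a, drop = FALSE])
  aA <- sum(d[in_a]); aB <- sum(d[!in_a])
  if (cut == 0) return(0)
  if (aA == 0 || aB == 0) return(Inf)
  cut / aA + cut / aB
}

graph_components_W <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    ind <- logical(n); ind[s] <- TRUE
    repeat {
      grown <- ind | (as.vector(W %*% ind) > 0)
      grown[comp > 0L] <- ind[comp > 0L]
      if (identical(grown, ind)) break
      ind <- grown
    }
    comp[ind] <- cur
  }
  comp
}

#' Two-way normalized-cut bipartition of an affinity matrix
#'
#' For a disconnected graph, the first component is split off (a zero
#' cut, the exact optimum).  Otherwise eigenvectors 2 and 3 of the
#' normalized Laplacian are computed; every prefix split along each
#' eigenvector's ordering is scored by [ncut_value()] and the best kept.
#'
#' @param W symmetric non-negative affinity matrix, n >= 2.
#' @return list with `in_a` (logical side-A indicator) and `ncut`.
#' @export
ncut_bipartition <- function(W) {
  n <- nrow(W)
  if (n < 2L) stop("cannot bipartition fewer than 2 nodes", call. = FALSE)
  comp <- graph_components_W(W)
  if (max(comp) > 1L) {
    message("disconnected affinity graph: splitting a component off")
    return(list(in_a = comp == 1L, ncut = 0))
  }
  d <- as.vector(Matrix::rowSums(W))
  dm <- 1 / sqrt(d)
  Wd <- as.matrix(W) * (dm %o% dm)
  Lsym <- diag(n) - Wd
  ev <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  best <- NULL
  n_try <- min(2L, n - 1L)
  for (j in seq_len(n_try)) {
    v <- ev$vectors[, n - j]           # ascending eigenvalue order
    z <- v * dm
    ord <- order(z)
    for (cutpt in seq_len(n - 1L)) {
      in_a <- logical(n); in_a[ord[seq_len(cutpt)]] <- TRUE
      val <- ncut_value(W, in_a)
      if (is.null(best) || val < best$ncut) best <- list(in_a = in_a, ncut = val)
    }
  }
  best
}

#' Normalized-cuts image segmentation
#'
#' Pixels of the (possibly downsampled) image are graph nodes; the
#' affinity between pixels within `neighbourhood_radius` is
#' `exp(-dI^2 / sigma_intensity^2) * exp(-dist^2 / sigma_distance^2)`.
#' The graph is recursively bipartitioned by [ncut_bipartition()]
#' (always splitting the largest current segment) until `n_segments`
#' labels exist; labels are upsampled to full resolution by nearest
#' neighbour.
#'
#' @param img integer matrix in [0, 255].
#' @param n_segments target number of segments (>= 1).
#' @param sigma_intensity,sigma_distance affinity scale parameters in
#'   intensity units and pixels.
#' @param neighbourhood_radius graph edge radius, pixels (on the
#'   downsampled grid).
#' @param downsample_to maximum processing side length; capped at 64.
#' @return list with `labels` (integer matrix, 0..k-1) and `k`.
#' @export
normalized_cuts_segment <- function(img, n_segments = 2L, sigma_intensity = 30,
                                    sigma_distance = 6,
                                    neighbourhood_radius = 5L,
                                    downsample_to = 32L) {
  assert_gray(img)
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L) stop("n_segments must be >= 1", call. = FALSE)
  downsample_to <- min(as.integer(downsample_to), 64L)
  ds <- stride_downsample(img, downsample_to)
  sub <- ds$img
  M <- nrow(sub); N <- ncol(sub); n <- M * N
  W <- pixel_affinity(sub, sigma_intensity, sigma_distance,
                      as.integer(neighbourhood_radius))
  segs <- list(seq_len(n))
  while (length(segs) < n_segments) {
    sizes <- vapply(segs, length, integer(1L))
    cand <- order(-sizes)
    split_done <- FALSE
    for (si in cand) {
      if (sizes[si] < 2L) next
      idx <- segs[[si]]
      bp <- ncut_bipartition(W[idx, idx, drop = FALSE])
      if (all(bp$in_a) || !any(bp$in_a)) next
      segs[[si]] <- idx[bp$in_a]
      segs[[length(segs) + 1L]] <- idx[!bp$in_a]
      split_done <- TRUE
      break
    }
    if (!split_done) {
      warning("could not reach the requested number of segments")
      break
    }
  }
  lab <- integer(n)
  for (j in seq_along(segs)) lab[segs[[j]]] <- j - 1L
  labels <- upsample_nn(matrix(lab, M, N), ds, dim(img))
  list(labels = labels, k = length(segs))
}

# Sparse pixel-graph affinity within a Euclidean pixel radius.
pixel_affinity <- function(img, sigma_i, sigma_d, radius) {
  M <- nrow(img); N <- ncol(img); n <- M * N
  I <- as.numeric(img)
  idx <- matrix(seq_len(n), M, N)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (dy in 0:radius) for (dx in (-radius):radius) {
    if (dy == 0L && dx <= 0L) next           # upper half-plane: symmetrize later
    d2 <- dy^2 + dx^2
    if (d2 > radius^2) next
    rs <- seq_len(M - dy)
    cs <- if (dx >= 0L) seq_len(N - dx) else (1L - dx):N
    a <- as.vector(idx[rs, cs, drop = FALSE])
    b <- as.vector(idx[rs + dy, cs + dx, drop = FALSE])
    w <- exp(-((I[a] - I[b])^2) / sigma_i^2) * exp(-d2 / sigma_d^2)
    ii <- c(ii, a); jj <- c(jj, b); xx <- c(xx, w)
  }
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(xx, xx),
                            dims = c(n, n))
  W
}

# ---- Abnormal-region extraction --------------------------------------

#' Extract the candidate abnormal region from a label map
#'
#' Selects the cluster with the highest mean image intensity inside the
#' breast mask and keeps its largest 8-connected component, provided it
#' reaches `min_area` pixels (otherwise an empty mask is returned with a
#' warning).
#'
#' @param labels integer label matrix (NA allowed outside the clustered
#'   mask).
#' @param img the intensity image the labels were computed from.
#' @param breast_mask logical matrix; must be non-empty.
#' @param min_area minimum component area in pixels (default scaled as
#'   25 px at side 256, quadratically with image side).
#' @return logical matrix (the segmented region A_S).
#' @export
extract_abnormal_region <- function(labels, img, breast_mask, min_area = NULL) {
  assert_gray(img); assert_mask(breast_mask)
  assert_same_shape(labels, img); assert_same_shape(img, breast_mask)
  if (!any(breast_mask)) stop("empty breast mask", call. = FALSE)
  if (is.null(min_area))
    min_area <- max(1L, as.integer(round(25 * (max(dim(img)) / 256)^2)))
  sel <- breast_mask & !is.na(labels)
  if (!any(sel)) stop("no labelled pixels inside the breast mask", call. = FALSE)
  means <- tapply(as.numeric(img[sel]), labels[sel], mean)
  if (length(means) == 1L)
    message("single-label map: abnormal region defaults to the breast component")
  top <- as.integer(names(means)[which.max(means)])
  cand <- sel & labels == top
  cand[is.na(cand)] <- FALSE
  comp <- largest_component(cand, 8L)
  if (sum(comp) < min_area) {
    warning(sprintf("no component reaches min_area = %d; returning empty mask",
                    min_area))
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  comp
}
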