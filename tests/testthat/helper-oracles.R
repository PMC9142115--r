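# Independent brute-force oracles.  Every oracle here is written as the
# most literal possible implementation (explicit loops, no shared code
# with the package) so it can stand as a second route against the
# package's vectorised implementations.

random_image <- function(m, n) matrix(sample(0:255, m * n, replace = TRUE), m, n)
random_mask <- function(m, n, p = 0.3) matrix(stats::runif(m * n) < p, m, n)

# Naive min/max filter with replicate padding: per-pixel loop over the
# structuring-element offsets.
o_minmax <- function(img, se_mat, what = c("min", "max")) {
  what <- match.arg(what)
  ry <- (nrow(se_mat) - 1L) %/% 2L; rx <- (ncol(se_mat) - 1L) %/% 2L
  M <- nrow(img); N <- ncol(img)
  out <- matrix(0, M, N)
  f <- if (what == "min") min else max
  for (r in seq_len(M)) for (c in seq_len(N)) {
    vals <- c()
    for (dy in -ry:ry) for (dx in -rx:rx) {
      if (!se_mat[dy + ry + 1L, dx + rx + 1L]) next
      rr <- min(max(r + dy, 1L), M); cc <- min(max(c + dx, 1L), N)
      vals <- c(vals, img[rr, cc])
    }
    out[r, c] <- f(vals)
  }
  storage.mode(out) <- "integer"
  out
}

o_open <- function(img, se_mat) o_minmax(o_minmax(img, se_mat, "min"), se_mat, "max")
o_close <- function(img, se_mat) o_minmax(o_minmax(img, se_mat, "max"), se_mat, "min")
o_top_hat <- function(img, se_mat) img - o_open(img, se_mat)
o_bottom_hat <- function(img, se_mat) o_close(img, se_mat) - img

# Stack-based flood fill admitting |img - img[seed]| <= tol.
o_flood_fill <- function(img, seed_row, seed_col, tol, connectivity = 8L) {
  M <- nrow(img); N <- ncol(img)
  ref <- img[seed_row + 1L, seed_col + 1L]
  offs <- if (connectivity == 4L) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                    c(1, -1), c(1, 0), c(1, 1))
  out <- matrix(FALSE, M, N)
  stack <- list(c(seed_row + 1L, seed_col + 1L))
  out[seed_row + 1L, seed_col + 1L] <- TRUE
  while (length(stack) > 0L) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    for (o in offs) {
      r <- p[1L] + o[1L]; c <- p[2L] + o[2L]
      if (r < 1L || r > M || c < 1L || c > N) next
      if (out[r, c]) next
      if (abs(img[r, c] - ref) <= tol) {
        out[r, c] <- TRUE
        stack[[length(stack) + 1L]] <- c(r, c)
      }
    }
  }
  out
}

# Per-pixel loop confusion counts.
o_confusion <- function(A_S, A_T) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(A_S)) {
    s <- A_S[i]; t <- A_T[i]
    if (s && t) tp <- tp + 1L
    else if (!s && !t) tn <- tn + 1L
    else if (s && !t) fp <- fp + 1L
    else fn <- fn + 1L
  }
  n <- length(A_S)
  list(tp = tp / n, tn = tn / n, fp = fp / n, fn = fn / n)
}

o_mse <- function(X, Y) {
  s <- 0
  for (i in seq_along(X)) s <- s + (as.numeric(X[i]) - as.numeric(Y[i]))^2
  s / length(X)
}

o_eme <- function(img, k1, k2, eps) {
  M <- nrow(img); N <- ncol(img)
  rb <- floor(M / k2); cb <- floor(N / k1)
  acc <- 0
  for (l in seq_len(k2)) for (k in seq_len(k1)) {
    r1 <- (l - 1L) * rb + 1L; r2 <- if (l == k2) M else l * rb
    c1 <- (k - 1L) * cb + 1L; c2 <- if (k == k1) N else k * cb
    mx <- -Inf; mn <- Inf
    for (r in r1:r2) for (c in c1:c2) {
      mx <- max(mx, img[r, c]); mn <- min(mn, img[r, c])
    }
    acc <- acc + 20 * log10((mx + eps) / (mn + eps))
  }
  acc / (k1 * k2)
}

# Exhaustive minimum normalized cut over all nontrivial bipartitions.
o_ncut_min <- function(W) {
  n <- nrow(W)
  d <- rowSums(W)
  best <- Inf
  for (code in 1:(2^(n - 1L) - 1L)) {   # fix node n in side B; skip trivial
    in_a <- c(as.logical(bitwAnd(code, 2^(0:(n - 2L)))), FALSE)
    cut <- sum(W[in_a, !in_a])
    aA <- sum(d[in_a]); aB <- sum(d[!in_a])
    val <- if (cut == 0) 0 else if (aA == 0 || aB == 0) Inf else cut / aA + cut / aB
    if (val < best) best <- val
  }
  best
}

# Brute-force connected-component labelling by repeated seed fill.
o_label <- function(mask, connectivity = 8L) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (i in which(mask & lab == 0L)) {
    if (lab[i] != 0L) next
    rc <- arrayInd(i, dim(mask))
    comp <- o_flood_fill(ifelse(mask, 1, 0), rc[1L] - 1L, rc[2L] - 1L, 0,
                         connectivity)
    comp <- comp & mask
    nxt <- nxt + 1L
    lab[comp] <- nxt
  }
  lab
}

# Phantom spec scaled to a smaller canvas for fast module tests.
small_phantom_spec <- function(side = 128L, ...) {
  phantom_spec(side = side, breast_axes = c(50, 57), pectoral_legs = c(55, 35),
               lesion_center = c(75, 30), lesion_sigma = 7, ...)
}
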