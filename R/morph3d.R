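# Internal 3D image primitives: array shifts, separable Gaussian blur,
# binary morphology on the 6-connected lattice, hole filling, Otsu
# thresholding, Euclidean distance transform and local maxima.
# All operate on plain arrays; physical anisotropy enters through `spacing`.

# shift an array by (dx, dy, dz), padding with `fill`
shift_array <- function(a, sh, fill = 0) {
  d <- dim(a)
  nd <- length(d)
  idx <- vector("list", nd)
  src <- vector("list", nd)
  for (i in seq_len(nd)) {
    s <- sh[i]
    if (s >= 0) {
      idx[[i]] <- seq_len(d[i] - s) + s
      src[[i]] <- seq_len(d[i] - s)
    } else {
      idx[[i]] <- seq_len(d[i] + s)
      src[[i]] <- seq_len(d[i] + s) - s
    }
  }
  out <- array(fill, d)
  out[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

as_3d <- function(a) {
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  a
}

# one 6-connected dilation step
dilate1 <- function(m) {
  m <- as_3d(m)
  out <- m
  for (sh in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    out <- out | shift_array(m, sh, FALSE)
  out
}

erode1 <- function(m) {
  m <- as_3d(m)
  out <- m
  for (sh in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    out <- out & shift_array(m, sh, TRUE)
  out
}

binary_dilate <- function(m, iters) { for (i in seq_len(iters)) m <- dilate1(m); m }
binary_erode  <- function(m, iters) { for (i in seq_len(iters)) m <- erode1(m); m }

# fill cavities: background components not connected to the grid boundary
fill_holes <- function(m) {
  m3 <- as_3d(m)
  d <- dim(m3)
  bg <- !m3
  lab <- array(cpp_label_components(as.logical(bg), d), d)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- setdiff(border, 0L)
  holes <- bg & !(lab %in% border)
  out <- m3 | holes
  dim(out) <- dim(m)
  out
}

label_components <- function(m) {
  m3 <- as_3d(m)
  lab <- array(cpp_label_components(as.logical(m3), dim(m3)), dim(m3))
  dim(lab) <- dim(m)
  lab
}

# separable Gaussian blur; sigma_vox per axis in voxels, replicate-padded edges
gaussian_blur <- function(a, sigma_vox) {
  d0 <- dim(a)
  a <- as_3d(a)
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  if (length(sigma_vox) == 2L) sigma_vox <- c(sigma_vox, 0)
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0 || d[ax] == 1L) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    n <- nrow(m)
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_len(2L * r + 1L))
      out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
    a <- aperm(array(out, dp), order(perm))
  }
  dim(a) <- d0
  a
}

# Otsu's threshold on a numeric vector (256-bin histogram over the range);
# returns a cut value: foreground is strictly above it
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  b <- pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins))
  h <- as.numeric(tabulate(b, n_bins))
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  bc <- w1 * w2 * (m1 - m2)^2
  bc[n_bins] <- -Inf
  i <- which.max(bc)
  rng[1] + i / n_bins * diff(rng)  # upper edge of the chosen bin
}

# two-level Otsu (three classes: background | dim | bright); returns the two
# cut values maximizing between-class variance, by exhaustive search over the
# binned histogram
multi_otsu_two <- function(x, n_bins = 128L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(c(rng[1], rng[1]))
  b <- pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins))
  h <- as.numeric(tabulate(b, n_bins))
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  W <- cumsum(h)
  S <- cumsum(h * mids)
  cw <- function(i, j) W[j] - if (i > 0) W[i] else 0       # mass of bins (i, j]
  cs <- function(i, j) S[j] - if (i > 0) S[i] else 0
  best <- c(-Inf, 1L, 2L)
  for (t1 in 1:(n_bins - 2)) {
    w1 <- cw(0, t1)
    if (w1 == 0) next
    m1 <- cs(0, t1) / w1
    for (t2 in (t1 + 1):(n_bins - 1)) {
      w2 <- cw(t1, t2); w3 <- cw(t2, n_bins)
      if (w2 == 0 || w3 == 0) next
      m2 <- cs(t1, t2) / w2
      m3 <- cs(t2, n_bins) / w3
      m <- S[n_bins] / W[n_bins]
      v <- w1 * (m1 - m)^2 + w2 * (m2 - m)^2 + w3 * (m3 - m)^2
      if (v > best[1]) best <- c(v, t1, t2)
    }
  }
  rng[1] + best[2:3] / n_bins * diff(rng)
}

# histogram mode ("modal gray value") at 8-bit-equivalent granularity
modal_value <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  b <- pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins))
  h <- tabulate(b, n_bins)
  i <- which.max(h)
  rng[1] + (i - 0.5) / n_bins * diff(rng)
}

# Euclidean distance (physical units of `spacing`) from foreground voxels to
# the nearest background voxel; the grid edge is not treated as background
edt <- function(fg, spacing) {
  fg3 <- as_3d(fg)
  sp <- if (length(spacing) == 2L) c(spacing, 1) else spacing
  d <- sqrt(array(cpp_edt_sq(as.logical(fg3), dim(fg3), as.numeric(sp)), dim(fg3)))
  dim(d) <- dim(fg)
  d
}

# 26-connected strict-or-equal local maxima of `v` restricted to `support`
local_maxima <- function(v, support) {
  v3 <- as_3d(v)
  s3 <- as_3d(support)
  vm <- v3
  vm[!s3] <- -Inf
  is_max <- s3
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    is_max <- is_max & (vm >= shift_array(vm, c(dx, dy, dz), -Inf))
  }
  out <- is_max & s3
  dim(out) <- dim(v)
  out
}
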