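# Matrix-level Hi-C and Repli-Seq analysis: balancing, O/E, Pearson maps,
# compartment eigenvector, histone k-means clusters, between-cluster contact
# ratios, APA and replication-timing preservation.

#' Balance a contact matrix to uniform row sums
#'
#' Finds the symmetric diagonal scaling `D M D` whose row sums over
#' non-masked bins all equal 1, via the damped fixed-point iteration
#' `x <- sqrt(x / (M x))` (fully zero rows are masked out and left NA). If
#' the iteration fails to converge a warning is raised and the best iterate
#' is returned.
#'
#' @param m a [contact_matrix()] (symmetric, non-negative).
#' @param tol maximum allowed deviation of any non-masked row sum from 1.
#' @param max_iter iteration cap.
#' @return a balanced [contact_matrix()] carrying the scaling vector.
#' @export
kr_balance <- function(m, tol = 1e-6, max_iter = 1000L) {
  mat <- m$mat
  good <- rowSums(mat) > 0
  sub <- mat[good, good, drop = FALSE]
  x <- rep(1 / sqrt(mean(rowSums(sub))), nrow(sub))
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    s <- as.numeric(sub %*% x)
    if (any(s <= 0)) stop("balancing failed: zero row encountered")
    x <- sqrt(x / s)
    dev <- max(abs(x * as.numeric(sub %*% x) - 1))
    if (dev < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("balancing did not reach tol %g in %d iterations (dev %.3g)",
                    tol, max_iter, dev))
  out <- matrix(NA_real_, nrow(mat), ncol(mat))
  out[good, good] <- sub * outer(x, x)
  scaling <- rep(NA_real_, nrow(mat))
  scaling[good] <- x
  res <- m
  res$mat <- out
  res$balanced <- TRUE
  res$scaling <- scaling
  res
}

#' Observed/expected transform
#'
#' Divides each entry by the mean of its diagonal (genomic-distance stratum);
#' strata whose mean is zero or undefined give NA.
#'
#' @param m a [contact_matrix()] (normally balanced).
#' @return numeric matrix of O/E values.
#' @export
oe_transform <- function(m) {
  mat <- m$mat
  n <- nrow(mat)
  dist <- abs(outer(seq_len(n), seq_len(n), "-"))
  expd <- vapply(0:(n - 1), function(d) {
    v <- mat[dist == d]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  e <- expd[dist + 1]
  out <- mat / e
  out[!is.finite(out)] <- NA_real_
  dim(out) <- dim(mat)
  out
}

#' Pearson correlation map of an O/E matrix
#'
#' Pairwise Pearson correlation of matrix rows with masked bins excluded;
#' zero-variance rows come back NA, the usable diagonal is 1.
#'
#' @param oe O/E matrix from [oe_transform()].
#' @export
pearson_map <- function(oe) {
  usable <- which(apply(oe, 1, function(r) sum(is.finite(r)) >= 3 &&
                          stats::sd(r, na.rm = TRUE) > 0))
  if (length(usable) < 3) stop("need at least 3 usable rows")
  p <- suppressWarnings(stats::cor(t(oe[usable, usable, drop = FALSE]),
                                   use = "pairwise.complete.obs"))
  out <- matrix(NA_real_, nrow(oe), ncol(oe))
  out[usable, usable] <- p
  diag(out)[usable] <- 1
  out
}

#' Compartment eigenvector of a Pearson map
#'
#' Leading eigenvector (largest eigenvalue) of the double-centered Pearson
#' matrix over usable bins. Its sign is anchored so that the correlation with
#' the reference track is positive -- with an early/late replication-timing
#' reference this orients the A compartment (early replicating) positive.
#'
#' @param pearson matrix from [pearson_map()].
#' @param reference numeric per-bin reference track (e.g. log2 E/L ratio).
#' @return per-bin eigenvector (NA on masked bins).
#' @export
compartment_eigenvector <- function(pearson, reference) {
  usable <- which(apply(pearson, 1, function(r) any(is.finite(r))))
  p <- pearson[usable, usable, drop = FALSE]
  p[!is.finite(p)] <- 0
  rm_ <- rowMeans(p)
  p <- p - outer(rm_, rep(1, ncol(p))) - outer(rep(1, nrow(p)), colMeans(p)) + mean(p)
  eg <- eigen(p, symmetric = TRUE)
  if (length(eg$values) > 1 &&
      abs(eg$values[1] - eg$values[2]) < 1e-10 * max(abs(eg$values[1]), 1))
    stop("degenerate leading eigenvalue: compartment eigenvector is not unique")
  v <- eg$vectors[, 1]
  ref <- reference[usable]
  s <- suppressWarnings(stats::cor(v, ref, use = "complete.obs"))
  if (is.finite(s) && s < 0) v <- -v
  out <- rep(NA_real_, nrow(pearson))
  out[usable] <- v
  out
}

#' K-means clustering of histone-mark tracks
#'
#' Each mark is converted to a per-bin z-score (to equalize dynamic range
#' between marks), then clustered with k-means using a fixed seed and
#' multiple restarts; clusters are relabeled in order of descending size so
#' the numbering is deterministic (the numbering itself is arbitrary).
#'
#' @param tracks matrix or data.frame of per-bin mark values (bins x marks).
#' @param k cluster count.
#' @param seed RNG seed for the restarts.
#' @param nstart k-means restarts.
#' @return list with `clusters` (per-bin id in 1..k), `sizes`, `centers`
#'   (k x marks, z-score units), `zscores`.
#' @export
kmeans_histone_clusters <- function(tracks, k = 6L, seed = 1L, nstart = 25L) {
  z <- scale(as.matrix(tracks))
  if (k > nrow(z)) stop("k exceeds the number of bins")
  fit <- with_seed(seed, stats::kmeans(z, centers = k, nstart = nstart,
                                       iter.max = 100L))
  ord <- order(-tabulate(fit$cluster, k))
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  cl <- remap[fit$cluster]
  list(clusters = cl, sizes = tabulate(cl, k),
       centers = fit$centers[ord, , drop = FALSE], zscores = z)
}

#' Between-cluster contact log2 ratios
#'
#' For each cluster pair (a, b), the mean contact value over all bin pairs
#' (i in a, j in b, i != j) is computed in both matrices and the entry is
#' `log2(mean_post / mean_pre)`. Symmetric; pairs involving an empty cluster
#' are NA.
#'
#' @param post,pre [contact_matrix()]s on the same bins (normally balanced).
#' @param clusters per-bin cluster ids in 1..k.
#' @param k cluster count (default `max(clusters)`).
#' @return k x k numeric matrix.
#' @export
cluster_contact_log2ratio <- function(post, pre, clusters, k = max(clusters)) {
  if (!identical(dim(post$mat), dim(pre$mat))) stop("matrices differ in bins")
  n <- nrow(pre$mat)
  if (length(clusters) != n) stop("clusters must cover all bins")
  off <- !diag(n)
  out <- matrix(NA_real_, k, k)
  for (a in seq_len(k)) for (b in a:k) {
    sel <- outer(clusters == a, clusters == b) & off
    sel <- sel | t(sel)
    if (!any(sel)) next
    mp <- mean(post$mat[sel], na.rm = TRUE)
    mq <- mean(pre$mat[sel], na.rm = TRUE)
    out[a, b] <- out[b, a] <- log2(mp / mq)
  }
  out
}

#' Aggregate peak analysis
#'
#' Sums the (2*window+1)^2 submatrices centered on each loop pixel. Loops
#' closer than `window` bins to the diagonal or the matrix edge are skipped
#' (and counted). The center score is the central value of the aggregate;
#' the enrichment ratio divides it by the mean of the lower-left corner
#' block of size floor(window/2) squared.
#'
#' @param m a [contact_matrix()].
#' @param loops data.frame of 1-based `bin_i` < `bin_j` loop pixels.
#' @param window half-width in bins.
#' @return list with `aggregate` matrix, `center_score`, `enrichment_ratio`,
#'   `n_used`, `n_skipped`.
#' @export
apa <- function(m, loops, window = 10L) {
  n <- nrow(m$mat)
  w <- as.integer(window)
  usable <- loops$bin_i - w >= 1 & loops$bin_j + w <= n &
    (loops$bin_j - loops$bin_i) >= w &
    loops$bin_i + w <= n & loops$bin_j - w >= 1
  if (!any(usable)) stop("no usable loops at this window")
  agg <- matrix(0, 2 * w + 1, 2 * w + 1)
  for (r in which(usable)) {
    i <- loops$bin_i[r]; j <- loops$bin_j[r]
    agg <- agg + m$mat[(i - w):(i + w), (j - w):(j + w)]
  }
  b <- max(1L, w %/% 2L)
  corner <- agg[(2 * w + 2 - b):(2 * w + 1), 1:b]
  center <- agg[w + 1, w + 1]
  list(aggregate = agg, center_score = center,
       enrichment_ratio = center / mean(corner),
       n_used = sum(usable), n_skipped = sum(!usable))
}

#' Replication-timing track from early/late bin counts
#'
#' log2 of the pseudocounted early/late ratio per bin, plus the percentile of
#' that ratio across bins (0-100).
#'
#' @param early,late per-bin counts on matching bins.
#' @param pseudocount added to both before the ratio.
#' @return data.frame `early`, `late`, `log2_ratio`, `percentile`.
#' @export
replication_timing <- function(early, late, pseudocount = 1) {
  if (length(early) != length(late)) stop("tracks differ in bins")
  if (all(early == 0) && all(late == 0)) stop("all-zero tracks")
  lr <- log2((early + pseudocount) / (late + pseudocount))
  pct <- (rank(lr, ties.method = "average") - 0.5) / length(lr) * 100
  data.frame(early = early, late = late, log2_ratio = lr, percentile = pct)
}

#' Replication-timing preservation between two tracks
#'
#' Spearman rank correlation of the E/L percentiles plus the paired scatter
#' table behind it.
#'
#' @param t1,t2 data.frames from [replication_timing()] on the same bins.
#' @return list with `rho` and `scatter` (data.frame of paired percentiles).
#' @export
timing_preservation <- function(t1, t2) {
  if (nrow(t1) != nrow(t2)) stop("tracks differ in bins")
  if (nrow(t1) < 3) stop("need at least 3 shared bins")
  rho <- stats::cor(t1$percentile, t2$percentile, method = "spearman")
  list(rho = rho,
       scatter = data.frame(percentile_1 = t1$percentile,
                            percentile_2 = t2$percentile))
}
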