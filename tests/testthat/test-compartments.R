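# Hi-C / Repli-Seq matrix analyses.

balanced_pair <- function(seed = 5) {
  gd <- generate_contact_data(genome_spec(seed = seed))
  list(gd = gd, pre = kr_balance(gd$pre), post = kr_balance(gd$post))
}

test_that("balancing reaches uniform row sums and the 2x2 closed form", {
  gd <- generate_contact_data(genome_spec(seed = 5))
  bal <- kr_balance(gd$pre)
  rs <- rowSums(bal$mat, na.rm = TRUE)
  expect_lt(max(abs(rs[rs > 0] - 1)), 1e-6)
  b <- kr_balance(contact_matrix(matrix(c(1, 2, 2, 4), 2), 1000), tol = 1e-12)
  expect_equal(b$scaling, c(1 / sqrt(2), 1 / (2 * sqrt(2))), tolerance = 1e-9)
  expect_equal(unname(rowSums(b$mat)), c(1, 1), tolerance = 1e-9)
  # already-balanced matrix: constant scaling, output equals input
  pre_bal <- kr_balance(gd$pre, tol = 1e-10)
  again <- kr_balance(contact_matrix(pre_bal$mat[!is.na(pre_bal$scaling),
                                                 !is.na(pre_bal$scaling)],
                                     1000), tol = 1e-10)
  expect_lt(diff(range(again$scaling)), 1e-6)
  expect_equal(again$mat, again$scaling[1]^2 *
                 pre_bal$mat[!is.na(pre_bal$scaling), !is.na(pre_bal$scaling)],
               tolerance = 1e-6)
  expect_error(contact_matrix(matrix(c(1, 2, 3, 4), 2), 1000), "symmetric")
})

test_that("O/E of a constant matrix is 1 and the transform is idempotent", {
  m <- contact_matrix(matrix(5, 8, 8), 1000, balanced = TRUE)
  oe <- oe_transform(m)
  expect_equal(oe, matrix(1, 8, 8))
  bp <- balanced_pair()
  oe1 <- oe_transform(bp$pre)
  oe2 <- oe_transform(contact_matrix(oe1, bp$pre$resolution, balanced = TRUE))
  expect_equal(oe2, oe1, tolerance = 1e-9)
})

test_that("planted checkerboard gives higher O/E within same-compartment blocks", {
  bp <- balanced_pair()
  oe <- oe_transform(bp$pre)
  same <- outer(bp$gd$truth$compartment, bp$gd$truth$compartment, "==")
  off <- abs(outer(seq_len(nrow(oe)), seq_len(nrow(oe)), "-")) > 5
  expect_gt(mean(oe[same & off], na.rm = TRUE), mean(oe[!same & off], na.rm = TRUE))
})

test_that("Pearson map has unit diagonal, +-1 for identical/negated rows", {
  oe <- matrix(rnorm(100), 10, 10)
  oe <- oe + t(oe)
  oe[2, ] <- oe[1, ]; oe[, 2] <- oe[, 1]
  pm <- pearson_map(oe)
  expect_equal(unname(diag(pm)), rep(1, 10))
  expect_equal(pm[1, 2], 1)
  oe[3, ] <- -oe[1, ]; oe[, 3] <- -oe[, 1]
  oe[3, 3] <- oe[1, 1]  # keep symmetry of the construction irrelevant entries
  pm2 <- pearson_map(oe)
  expect_lt(pm2[1, 3], -0.8)
})

test_that("the compartment eigenvector recovers a planted checkerboard (spectral oracle)", {
  # noiseless expected matrix: the 60-bin spectral oracle is exact
  gd <- generate_contact_data(genome_spec(n_bins = 60, block_size = 10,
                                          n_loops = 0, count_noise = "none",
                                          seed = 8))
  bal <- kr_balance(gd$pre)
  pm <- pearson_map(oe_transform(bal))
  rt <- replication_timing(gd$tracks$early, gd$tracks$late)
  ev <- compartment_eigenvector(pm, rt$log2_ratio)
  expect_equal(sign(ev), gd$truth$compartment)
  # orientation rule: correlation with the reference is positive
  expect_gt(cor(ev, rt$log2_ratio), 0)
  # permutation equivariance
  p <- sample(60)
  evp <- compartment_eigenvector(pm[p, p], rt$log2_ratio[p])
  expect_equal(abs(evp), abs(ev[p]), tolerance = 1e-9)
})

test_that("z-scored tracks have mean 0, sd 1 and k-means separates archetypes", {
  gd <- generate_contact_data(genome_spec(seed = 9, track_noise = 0.15))  # low noise
  km <- kmeans_histone_clusters(gd$tracks[, nucarch:::histone_marks], k = 6, seed = 1)
  expect_equal(unname(colMeans(km$zscores)), rep(0, 9), tolerance = 1e-12)
  expect_equal(unname(apply(km$zscores, 2, sd)), rep(1, 9), tolerance = 1e-12)
  expect_true(all(diff(km$sizes) <= 0))  # relabeled by descending size
  # two clean archetypes, k = 2: perfect partition
  z2 <- rbind(matrix(rnorm(50 * 3, mean = 3, sd = 0.05), 50),
              matrix(rnorm(50 * 3, mean = -3, sd = 0.05), 50))
  km2 <- kmeans_histone_clusters(z2, k = 2, seed = 1)
  expect_equal(length(unique(km2$clusters[1:50])), 1)
  expect_equal(length(unique(km2$clusters[51:100])), 1)
  expect_error(kmeans_histone_clusters(z2[1:3, ], k = 6), "k exceeds")
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(km$clusters, gd$truth$clusters)
  expect_gte(ari, 0.95)
})

test_that("cluster contact log2 ratios: zero at equality, exact one for doubling, antisymmetric", {
  gd <- generate_contact_data(genome_spec(count_noise = "none", seed = 10))
  cl <- gd$truth$clusters
  z <- cluster_contact_log2ratio(gd$pre, gd$pre, cl)
  expect_equal(z, matrix(0, 6, 6))
  lr <- cluster_contact_log2ratio(gd$post, gd$pre, cl)
  cc <- gd$truth$strengthen_cluster
  expect_equal(lr[cc, cc], 1)
  expect_equal(lr[-cc, -cc], matrix(0, 5, 5))
  expect_equal(cluster_contact_log2ratio(gd$pre, gd$post, cl), -lr)
})

test_that("under noise and balancing the strengthened cluster is the maximal entry", {
  bp <- balanced_pair(seed = 12)
  lr <- cluster_contact_log2ratio(bp$post, bp$pre, bp$gd$truth$clusters)
  cc <- bp$gd$truth$strengthen_cluster
  expect_equal(which.max(lr), (cc - 1) * 6 + cc)
})

test_that("APA: uniform matrices score 1, planted loops above shuffled controls", {
  u <- contact_matrix(matrix(3, 80, 80), 1000)
  lp <- data.frame(bin_i = c(20, 30), bin_j = c(50, 65))
  expect_equal(apa(u, lp, window = 5)$enrichment_ratio, 1)
  bp <- balanced_pair(seed = 3)
  ap <- apa(bp$pre, bp$gd$loops)
  expect_gt(ap$enrichment_ratio, 1)
  set.seed(77)
  d <- bp$gd$loops$bin_j - bp$gd$loops$bin_i
  bi <- vapply(d, function(dd) sample(12:(240 - 12 - dd), 1), numeric(1))
  shuf <- apa(bp$pre, data.frame(bin_i = bi, bin_j = bi + d))
  expect_gt(ap$enrichment_ratio, shuf$enrichment_ratio)
  near <- data.frame(bin_i = 100, bin_j = 104)  # too close to the diagonal
  expect_error(apa(bp$pre, near), "no usable loops")
})

test_that("replication timing: zero log-ratio at equality, percentiles are scaled ranks", {
  rt <- replication_timing(rep(5, 10), rep(5, 10))
  expect_equal(rt$log2_ratio, rep(0, 10))
  inc <- replication_timing(2^(1:10), rep(1, 10), pseudocount = 0)
  expect_equal(inc$percentile, ((1:10) - 0.5) * 10)
  expect_error(replication_timing(rep(0, 5), rep(0, 5)), "all-zero")
})

test_that("timing preservation: identical 1, reversed -1, noisy replicate >= 0.95", {
  t1 <- replication_timing(c(50, 40, 30, 20, 10, 5), c(5, 10, 20, 30, 40, 50))
  expect_equal(timing_preservation(t1, t1)$rho, 1)
  t2 <- replication_timing(rev(c(50, 40, 30, 20, 10, 5)), rev(c(5, 10, 20, 30, 40, 50)))
  expect_equal(timing_preservation(t1, t2)$rho, -1)
  gd <- generate_contact_data(genome_spec(seed = 14))
  ta <- replication_timing(gd$tracks$early, gd$tracks$late)
  set.seed(15)
  tb <- replication_timing(pmax(gd$tracks$early + rpois(240, 3) - 3, 0),
                           pmax(gd$tracks$late + rpois(240, 3) - 3, 0))
  expect_gte(timing_preservation(ta, tb)$rho, 0.95)
})
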