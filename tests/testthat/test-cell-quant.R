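# Nucleus segmentation, volumes, DNA content, trace filtering.

make_ellipsoid_grid <- function(d = c(150, 150, 60), vs = c(100, 100, 300),
                                semi = c(5, 4, 3), center = NULL, bg = 10) {
  cg <- nucarch:::coord_grids(d, vs)
  if (is.null(center)) center <- d * vs / 1000 / 2
  ell <- ((cg$x - center[1]) / semi[1])^2 + ((cg$y - center[2]) / semi[2])^2 +
    ((cg$z - center[3]) / semi[3])^2 <= 1
  img <- array(bg, d)
  img[ell] <- 200
  voxel_grid(img, vs)
}

test_that("a bright ellipsoid is segmented with its analytic volume", {
  g <- make_ellipsoid_grid()
  masks <- segment_nuclei(g, min_volume = 100)
  expect_length(masks, 1)
  expect_equal(nuclear_volume(masks[[1]]), 4 / 3 * pi * 60, tolerance = 0.1)
})

test_that("objects below the minimum volume are dropped", {
  # semi-axes chosen for a 150 um^3 ellipsoid: (4/3)pi*abc = 150
  g <- make_ellipsoid_grid(semi = c(4.1, 3.5, 2.5))
  expect_equal(4 / 3 * pi * prod(c(4.1, 3.5, 2.5)), 150, tolerance = 0.01)
  expect_length(segment_nuclei(g, min_volume = 200), 0)
  expect_length(segment_nuclei(g, min_volume = 100), 1)
})

test_that("nuclei on the XY image border are removed", {
  g <- make_ellipsoid_grid(center = c(0, 7.5, 9))
  expect_length(segment_nuclei(g, min_volume = 50), 0)
})

test_that("empty images give an empty mask list", {
  g <- voxel_grid(array(7, c(20, 20, 8)), c(100, 100, 300))
  expect_length(segment_nuclei(g), 0)
})

test_that("volume converts voxel counts with anisotropy and is translation invariant", {
  m <- array(FALSE, c(20, 20, 10))
  m[3:12, 3:12, 3:7] <- TRUE
  expect_equal(nuclear_volume(nucleus_mask(m, c(100, 100, 100))),
               sum(m) * 1e-3)
  m2 <- array(FALSE, c(20, 20, 10))
  m2[8:17, 6:15, 4:8] <- TRUE
  expect_equal(nuclear_volume(nucleus_mask(m2, c(100, 100, 100))),
               nuclear_volume(nucleus_mask(m, c(100, 100, 100))))
  expect_equal(nuclear_volume(nucleus_mask(array(FALSE, c(4, 4, 4)), c(40, 40, 125))), 0)
})

test_that("segmentation recovers the generator mask with Jaccard >= 0.9", {
  sc <- generate_nucleus_scene(
    nucleus_scene_spec(grid_shape = c(96, 96, 32), seed = 11))
  masks <- segment_nuclei(sc$channels$DAPI, min_volume = 1, dilate_erode_iters = 3)
  expect_length(masks, 1)
  jac <- sum(masks[[1]]$mask & sc$truth$mask) / sum(masks[[1]]$mask | sc$truth$mask)
  expect_gte(jac, 0.9)
})

test_that("integrated DNA content is linear and zero on uniform frames", {
  m <- array(FALSE, c(30, 30, 10)); m[10:20, 10:20, 3:8] <- TRUE
  base <- array(0, c(30, 30, 10)); base[m] <- 500
  g1 <- voxel_grid(base, c(100, 100, 300))
  g2 <- voxel_grid(base * 2, c(100, 100, 300))
  nm <- nucleus_mask(m, c(100, 100, 300))
  expect_equal(integrated_dna_content(g2, nm) / integrated_dna_content(g1, nm), 2)
  flat <- voxel_grid(array(123, c(30, 30, 10)), c(100, 100, 300))
  expect_equal(integrated_dna_content(flat, nm), 0)
})

test_that("2n vs 4n synthetic populations give a median content ratio of 2", {
  contents <- function(scale, seeds) vapply(seeds, function(s) {
    sc <- generate_nucleus_scene(
      nucleus_scene_spec(grid_shape = c(64, 64, 16), nucleus_scale = scale,
                         noise_sd = 500, seed = s))
    integrated_dna_content(sc$channels$DAPI, scene_mask(sc))
  }, numeric(1))
  c2n <- contents(0.9, 1:5)
  c4n <- contents(0.9 * 2^(1/3), 11:15)
  expect_equal(median(c4n) / median(c2n), 2, tolerance = 0.1)
})

test_that("trace filtering applies the start threshold and normalization", {
  g <- generate_decay_traces(6, nonresponder_fraction = 0, noise_sd = 0,
                             n_timepoints = 12, start_range = c(100, 300), seed = 3)
  low <- g$traces[g$traces$cell_id == 1, ]
  low$intensity <- low$intensity / low$intensity[1] * 40  # starts at 40 counts
  traces <- rbind(low, g$traces[g$traces$cell_id != 1, ])
  res <- filter_and_normalize_traces(traces)
  expect_true(1 %in% res$exclusions$cell_id)
  expect_equal(res$exclusions$reason[res$exclusions$cell_id == 1], "start_below_min")
  firsts <- res$traces$normalized[res$traces$t_index == 0]
  expect_true(all(firsts == 1))
})

test_that("perfectly constant traces are all retained (degenerate ties)", {
  tr <- data.frame(cell_id = rep(1:5, each = 8), t_index = rep(0:7, 5),
                   intensity = 100)
  res <- filter_and_normalize_traces(tr)
  expect_equal(length(unique(res$traces$cell_id)), 5)
  expect_equal(nrow(res$exclusions), 0)
})

test_that("the fluctuation rule removes at most ceiling(10%) of cells", {
  g <- generate_decay_traces(40, noise_sd = 8, n_timepoints = 20, seed = 9)
  res <- filter_and_normalize_traces(g$traces)
  n_fl <- sum(res$exclusions$reason == "fluctuation_above_quantile")
  expect_lte(n_fl, ceiling(0.1 * 40))
})
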