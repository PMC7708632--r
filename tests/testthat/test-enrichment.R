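# Marker enrichment/depletion over compaction classes.

# a class field taken directly from generator truth (segmentation-free route)
truth_field <- function(sc) {
  structure(list(labels = sc$truth$label_field,
                 params = list(K = 7, mu = sc$spec$class_means,
                               sigma = sc$spec$class_sigma,
                               pi = sc$truth$true_class_fractions, beta = 0),
                 mask = sc$truth$mask, voxel_size = sc$spec$voxel_size),
            class = "class_field")
}

test_that("a uniform marker covering the whole mask has zero deltas", {
  sc <- small_scene(seed = 4)
  seg <- structure(list(voxels = which(sc$truth$mask),
                        intensities = rep(5, sum(sc$truth$mask)),
                        threshold = 0, marker = "uniform"),
                   class = "marker_segmentation")
  ep <- enrichment_profile(seg, truth_field(sc))
  expect_equal(ep$delta, rep(0, 7), tolerance = 1e-9)
  expect_equal(sum(ep$delta), 0, tolerance = 1e-9)
})

test_that("a marker confined to class 1 forces the closed-form deltas", {
  sc <- small_scene(seed = 4)
  fld <- truth_field(sc)
  idx <- which(sc$truth$mask & sc$truth$label_field == 1)
  seg <- structure(list(voxels = idx, intensities = rep(1, length(idx)),
                        threshold = 0, marker = "c1"),
                   class = "marker_segmentation")
  ep <- enrichment_profile(seg, fld)
  f1 <- unname(sc$truth$true_class_fractions[1])
  expect_equal(ep$delta[1], 100 * (1 - f1))
  expect_equal(ep$delta[-1], unname(-100 * sc$truth$true_class_fractions[-1]))
})

test_that("deltas are invariant to global rescaling of marker intensities", {
  sc <- small_scene(seed = 4)
  fld <- truth_field(sc)
  idx <- which(sc$truth$mask)[seq(1, sum(sc$truth$mask), by = 7)]
  ints <- runif(length(idx), 1, 10)
  mk <- function(w) structure(list(voxels = idx, intensities = w, threshold = 0,
                                   marker = "m"), class = "marker_segmentation")
  expect_equal(enrichment_profile(mk(ints), fld)$delta,
               enrichment_profile(mk(ints * 37.5), fld)$delta)
})

test_that("marker segmentation recovers a planted binary channel exactly", {
  sc <- generate_nucleus_scene(nucleus_scene_spec(
    grid_shape = c(64, 64, 16), seed = 6,
    markers = list(list(name = "M", weights = c(4, 2, 1, 0.5, 0.2, 0.1, 0.1),
                        density = 0.05))))
  seg <- segment_marker(sc$channels$M, scene_mask(sc))
  expect_setequal(seg$voxels, sc$truth$marker_truth$M$positive_voxels)
  # binary channel: any factor in (0, 1] keeps exactly the bright voxels
  seg2 <- segment_marker(sc$channels$M, scene_mask(sc), threshold_factor = 0.3)
  expect_setequal(seg2$voxels, seg$voxels)
  # a huge factor empties the segmentation
  seg3 <- segment_marker(sc$channels$M, scene_mask(sc), threshold_factor = 1e9)
  expect_length(seg3$voxels, 0)
  expect_error(enrichment_profile(seg3, truth_field(sc)), "no marker signal")
})

test_that("an all-zero marker channel warns and yields an empty segmentation", {
  sc <- small_scene(seed = 4)
  z <- voxel_grid(array(0, dim(sc$truth$mask)), sc$spec$voxel_size, channel = "Z")
  expect_warning(seg <- segment_marker(z, scene_mask(sc)), "all zero")
  expect_length(seg$voxels, 0)
})

test_that("an SC35-like IC marker shows class-1 enrichment and high-class depletion", {
  sc <- generate_nucleus_scene(nucleus_scene_spec(
    grid_shape = c(64, 64, 16), seed = 9,
    markers = list(list(name = "SC35", weights = c(8, 2, 1, 0, 0, 0, 0),
                        density = 0.04))))
  seg <- segment_marker(sc$channels$SC35, scene_mask(sc))
  ep <- enrichment_profile(seg, truth_field(sc))
  expect_gt(ep$delta[1], 0)
  expect_true(all(ep$delta[5:7] < 0))
})

test_that("a class-independent marker gives near-zero deltas at large n", {
  sc <- generate_nucleus_scene(nucleus_scene_spec(
    grid_shape = c(128, 128, 32), seed = 10,
    markers = list(list(name = "null", weights = rep(1, 7), density = 0.85))))
  seg <- segment_marker(sc$channels$null, scene_mask(sc))
  expect_gte(length(seg$voxels), 1e5)
  ep <- enrichment_profile(seg, truth_field(sc))
  expect_lt(max(abs(ep$delta)), 1)
})

test_that("aggregation averages deltas with SEM and rejects mixed K", {
  mk_prof <- function(delta) {
    f <- rep(1 / 7, 7)
    structure(data.frame(class = 1:7, dapi_fraction = f,
                         marker_fraction = f + delta / 100, delta = delta),
              class = c("enrichment_profile", "data.frame"))
  }
  d1 <- c(10, -10, rep(0, 5)); d2 <- c(-10, 10, rep(0, 5))
  agg <- aggregate_profiles(list(mk_prof(d1), mk_prof(d2)))
  expect_equal(agg$mean_delta, rep(0, 7))
  expect_equal(aggregate_profiles(list(mk_prof(d1), mk_prof(d1)))$sem_delta,
               rep(0, 7))
  bad <- structure(data.frame(class = 1:6, dapi_fraction = 1/6,
                              marker_fraction = 1/6, delta = 0),
                   class = c("enrichment_profile", "data.frame"))
  expect_error(aggregate_profiles(list(mk_prof(d1), bad)), "mixed K")
})

test_that("a planted +15 point class-1 enrichment is recovered across nuclei", {
  deltas <- vapply(1:8, function(s) {
    spec0 <- nucleus_scene_spec(grid_shape = c(64, 64, 16), seed = 100 + s)
    sc0 <- generate_nucleus_scene(spec0)
    w <- marker_weights_for_delta(sc0$truth$true_class_fractions, 1, 0.15)
    sc <- generate_nucleus_scene(nucleus_scene_spec(
      grid_shape = c(64, 64, 16), seed = 100 + s,
      markers = list(list(name = "M", weights = w, density = 0.10))))
    seg <- segment_marker(sc$channels$M, scene_mask(sc))
    enrichment_profile(seg, truth_field(sc))$delta[1]
  }, numeric(1))
  expect_lt(abs(mean(deltas) - 15), 2)
})
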