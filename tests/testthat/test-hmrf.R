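# HMRF compaction classifier: recovery, oracle equivalence, energy, profiles.

test_that("zero-noise scenes are recovered perfectly", {
  sc <- generate_nucleus_scene(
    nucleus_scene_spec(grid_shape = c(64, 64, 16), class_sigma = 0, seed = 3))
  cf <- fit_hmrf(sc$channels$DAPI, scene_mask(sc), hmrf_params(beta = 0.8))
  expect_equal(mean(cf$labels[sc$truth$mask] == sc$truth$label_field[sc$truth$mask]), 1)
  expect_true(all(cf$labels[!sc$truth$mask] == 0))
})

test_that("beta = 0 reduces to the per-voxel mixture MAP (argmax oracle)", {
  sc <- small_scene(seed = 4)
  cf <- fit_hmrf(sc$channels$DAPI, scene_mask(sc), hmrf_params(beta = 0))
  p <- cf$params
  I <- sc$channels$DAPI$data[sc$truth$mask]
  cost <- vapply(seq_len(p$K),
                 function(k) (I - p$mu[k])^2 / (2 * p$sigma^2) - log(p$pi[k]),
                 numeric(length(I)))
  oracle <- max.col(-cost, ties.method = "first")
  expect_equal(unname(cf$labels[sc$truth$mask]), oracle)
})

test_that("ICM energy is non-increasing within every fixed-parameter phase", {
  sc <- small_scene(seed = 4)
  cf <- fit_hmrf(sc$channels$DAPI, scene_mask(sc),
                 hmrf_params(beta = 0.8, icm_sweeps = 5L))
  et <- cf$energy_trace
  for (ph in split(et$energy, et$phase))
    expect_true(all(diff(ph) <= 1e-6 * max(abs(ph))))
})

test_that("classifier accuracy reaches 0.90 at sigma = half the inter-mean gap", {
  spec <- nucleus_scene_spec(seed = 21)
  spec$class_sigma <- min(diff(spec$class_means)) / 2
  sc <- generate_nucleus_scene(spec)
  cf <- fit_hmrf(sc$channels$DAPI, scene_mask(sc), hmrf_params(beta = 0.8))
  acc <- mean(cf$labels[sc$truth$mask] == sc$truth$label_field[sc$truth$mask])
  expect_gte(acc, 0.90)
})

test_that("fitted parameters recover the generator emission model", {
  sc <- small_scene(seed = 4)  # default noise
  cf <- fit_hmrf(sc$channels$DAPI, scene_mask(sc), hmrf_params(beta = 0.8))
  expect_lt(max(abs(cf$params$mu - sc$spec$class_means) / sc$spec$class_means), 0.05)
  expect_lt(abs(cf$params$sigma - sc$spec$class_sigma) / sc$spec$class_sigma, 0.10)
  expect_true(all(diff(cf$params$mu) > 0))
})

test_that("final neighbor agreement never decreases with beta on a fixed scene", {
  sc <- small_scene(seed = 4)
  ag <- vapply(c(0, 0.5, 1), function(b) {
    cf <- fit_hmrf(sc$channels$DAPI, scene_mask(sc), hmrf_params(beta = b))
    neighbor_agreement(cf$labels, sc$truth$mask)
  }, numeric(1))
  expect_true(all(diff(ag) >= 0))
})

test_that("degenerate inputs raise the documented errors", {
  g <- voxel_grid(array(100, c(8, 8, 4)), c(40, 40, 125))
  m <- nucleus_mask(array(TRUE, c(8, 8, 4)), c(40, 40, 125))
  expect_error(fit_hmrf(g, m), "constant")
  m2 <- nucleus_mask(array(FALSE, c(8, 8, 4)), c(40, 40, 125))
  expect_error(fit_hmrf(g, m2), "fewer in-mask voxels")
})

test_that("class profiles are normalized fractions of in-mask labels", {
  sc <- small_scene(seed = 4)
  cf <- fit_hmrf(sc$channels$DAPI, scene_mask(sc), hmrf_params(beta = 0.8))
  pr <- class_profile(cf)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_equal(unname(pr),
               unname(tabulate(cf$labels[sc$truth$mask], 7) / sum(sc$truth$mask)))
  # fitted fractions track the generator truth within 2 percentage points
  expect_lt(max(abs(pr - sc$truth$true_class_fractions)), 0.02)
})

test_that("profile summaries give mean and SEM with hand-checked values", {
  p1 <- c(1, 0, 0, 0, 0, 0, 0)
  p2 <- c(0, 1, 0, 0, 0, 0, 0)
  s <- profile_summary(list(p1, p2))
  expect_equal(s$mean[1], 0.5)
  expect_equal(s$sem[1], sd(c(1, 0)) / sqrt(2))
  expect_equal(profile_summary(list(p2, p1))$mean, s$mean)  # order invariance
  s1 <- profile_summary(list(p1))
  expect_true(all(s1$sem == 0))
  expect_true(attr(s1, "single_nucleus"))
  expect_true(all(profile_summary(list(p1, p1))$sem == 0))
})

test_that("label TIFF export round-trips every label", {
  sc <- small_scene(seed = 4)
  cf <- fit_hmrf(sc$channels$DAPI, scene_mask(sc), hmrf_params(beta = 0.5))
  f <- tempfile(fileext = ".tif")
  on.exit(unlink(f))
  export_class_tiff(cf, f)
  back <- read_class_tiff(f)
  expect_equal(as.integer(back), as.integer(nucarch:::as_3d(cf$labels)))
  lut <- nucarch:::class_lut(7)
  expect_equal(unname(lut[1, ]), c(0, 0, 0))  # class 0 renders black
  expect_equal(nrow(lut), 8)
})
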