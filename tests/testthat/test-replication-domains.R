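# RD segmentation, summaries and the rank-sum / Holm statistics.

vs_sim <- c(40, 40, 125)

all_mask <- function(d) nucleus_mask(array(TRUE, d), vs_sim)

test_that("disjoint spheres are counted exactly with analytic volumes", {
  set.seed(1)
  d <- c(100, 100, 30)
  centers <- as.matrix(expand.grid(x = c(1, 2.2, 3.4), y = c(1, 2.2, 3.4), z = c(1.2, 2.6)))
  centers <- centers[1:10, ]
  g <- render_spheres(d, vs_sim, centers, 0.3)
  tab <- segment_rds(g, all_mask(d))
  expect_equal(nrow(tab), 10)
  expect_true(all(abs(tab$volume_um3 - 4 / 3 * pi * 0.3^3) / (4 / 3 * pi * 0.3^3) < 0.1))
})

test_that("objects below the size exclusion are dropped", {
  d <- c(40, 40, 16)
  r004 <- (3 * 0.004 / (4 * pi))^(1/3)
  g <- render_spheres(d, vs_sim, rbind(c(0.8, 0.8, 1.0)), r004)
  expect_equal(nrow(segment_rds(g, all_mask(d))), 0)
  tab <- segment_rds(render_spheres(d, vs_sim, rbind(c(0.8, 0.8, 1.0)), 0.2),
                     all_mask(d))
  expect_true(all(tab$volume_um3 >= 0.005))
})

test_that("two overlapping spheres are separated into two objects", {
  d <- c(60, 60, 24)
  g <- render_spheres(d, vs_sim, rbind(c(1.0, 1.0, 1.2), c(1.45, 1.0, 1.2)), 0.25)
  tab <- segment_rds(g, all_mask(d))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$volume_um3[1], tab$volume_um3[2], tolerance = 0.05)
})

test_that("segmentation respects the nuclear mask and errors on an empty one", {
  d <- c(40, 40, 16)
  g <- render_spheres(d, vs_sim, rbind(c(0.8, 0.8, 1.0)), 0.2)
  m <- array(FALSE, d)
  expect_error(segment_rds(g, nucleus_mask(m, vs_sim)), "empty nuclear mask")
  m[1:10, 1:10, ] <- TRUE  # sphere outside this region
  expect_equal(nrow(segment_rds(g, nucleus_mask(m, vs_sim))), 0)
})

test_that("volume summaries use Tukey hinges and doubling leaves volumes unchanged", {
  tab <- data.frame(id = 1:5, volume_um3 = 1:5, x = 0, y = 0, z = 0,
                    nucleus_id = 1, condition = "control")
  s <- rd_counts_and_volumes(tab)
  expect_equal(s$volume_summary$median, 3)
  expect_equal(s$volume_summary$hinge_lo, 2)
  expect_equal(s$volume_summary$hinge_hi, 4)
  one <- rd_counts_and_volumes(tab[1, ])
  expect_equal(one$volume_summary$median, 1)
  expect_equal(one$volume_summary$hinge_hi - one$volume_summary$hinge_lo, 0)
  # doubling every object doubles counts but not the volume distribution
  tab2 <- rbind(tab, transform(tab, id = id + 5))
  s2 <- rd_counts_and_volumes(tab2)
  expect_equal(s2$counts$n, 2 * s$counts$n)
  expect_equal(s2$volume_summary$median, s$volume_summary$median)
  expect_equal(s2$volume_summary$hinge_lo, s$volume_summary$hinge_lo)
})

test_that("Mann-Whitney exact p for {1,2,3} vs {4,5,6} is 0.1", {
  r <- mann_whitney_two_sided(1:3, 4:6)
  expect_equal(r$p, 0.1)
  expect_equal(r$U, 0)
})

test_that("Mann-Whitney is symmetric and degenerate samples give p = 1", {
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(2.8, 4.4, 0.7)
  expect_equal(mann_whitney_two_sided(a, b)$p, mann_whitney_two_sided(b, a)$p)
  expect_equal(mann_whitney_two_sided(rep(2, 4), rep(2, 5))$p, 1)
  expect_gte(mann_whitney_two_sided(c(1, 2, 3), c(1, 2, 3))$p, 0.99)
  expect_error(mann_whitney_two_sided(numeric(), 1:3), "empty")
})

test_that("the exact path agrees with a permutation oracle for n_a + n_b <= 10", {
  set.seed(42)
  for (rep in 1:12) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    vals <- sample(1:100, na + nb)  # tie-free
    a <- vals[1:na]; b <- vals[-(1:na)]
    expect_equal(mann_whitney_two_sided(a, b)$p, mw_permutation_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Holm adjustment matches hand computation and preserves order", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("a cohesin-depletion-like effect is detected on counts and volumes", {
  # crowded nuclei may not fit every requested domain; the placement warning
  # is expected at these densities
  arm <- function(cond, n_obj, mv, cv, seeds) do.call(rbind, lapply(seeds, function(s) {
    sc <- suppressWarnings(generate_nucleus_scene(nucleus_scene_spec(
      grid_shape = c(96, 96, 24), seed = s,
      rd = list(pattern = "early", n_objects = n_obj, mean_volume = mv, cv = cv,
                separation = 0.45))))
    segment_rds(sc$channels$RD, scene_mask(sc), nucleus_id = s, condition = cond)
  }))
  ctrl <- arm("control", 20, 0.025, 0.2, 1:10)
  depl <- arm("30h", 30, 0.04, 0.5, 11:20)  # 1.5x counts and volumes
  counts <- rbind(stats::aggregate(id ~ nucleus_id, ctrl, length),
                  stats::aggregate(id ~ nucleus_id, depl, length))
  cond <- c(rep("control", 10), rep("30h", 10))
  expect_lt(mann_whitney_two_sided(counts$id[cond == "control"],
                                   counts$id[cond == "30h"])$p, 0.05)
  expect_lt(mann_whitney_two_sided(ctrl$volume_um3, depl$volume_um3)$p, 0.05)
  tests <- pairwise_condition_tests(c(ctrl$volume_um3, depl$volume_um3),
                                    c(ctrl$condition, depl$condition))
  expect_equal(nrow(tests), 1)
  expect_true(all(tests$p_holm >= tests$p))
})
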