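# shared fixtures, built in code and cached per test run

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) assign(key, expr, envir = fixture_env)
  get(key, envir = fixture_env)
}

small_scene <- function(seed = 4, ...) {
  key <- paste0("scene_", seed, "_", paste(deparse(substitute(list(...))), collapse = ""))
  cached(key, generate_nucleus_scene(
    nucleus_scene_spec(grid_shape = c(64, 64, 16), seed = seed, ...)))
}

scene_mask <- function(sc) nucleus_mask(sc$truth$mask, sc$spec$voxel_size)

# exhaustive two-sided Mann-Whitney p-value by enumerating all assignments
# of the pooled sample to group A (independent oracle for the exact path)
mw_permutation_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  u_of <- function(av, bv) sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  u_obs <- u_of(a, b)
  mu <- na * length(b) / 2
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
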