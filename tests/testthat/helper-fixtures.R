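# Shared fixtures. Heavy artifacts (phantoms, full pipeline runs) are
# memoised per session so several test files can share one computation.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# default-size phantom + full segmentation for a seed/phase
phantom_run <- function(seed, phase = c("insp", "exp"), degrade = 0) {
  phase <- match.arg(phase)
  key <- sprintf("run_%d_%s_%g", seed, phase, degrade)
  memo(key, {
    spec <- phantom_spec(seed = seed)
    if (degrade > 0) spec <- degrade_expiratory_contrast(spec, degrade)
    ph <- generate_phantom(spec)
    ct <- if (phase == "insp") ph$insp else ph$exp
    res <- segment_lobes(ct)
    list(phantom = ph, result = res, ct = ct)
  })
}

default_phantom <- function(seed = 1) {
  memo(sprintf("phantom_%d", seed), generate_phantom(phantom_spec(seed = seed)))
}

per_lobe_dice <- function(map, truth) {
  vapply(1:6, function(k) {
    a <- map$labels == k
    m <- truth$labels == k
    if (!any(a) && !any(m)) return(NA_real_)
    2 * sum(a & m) / (sum(a) + sum(m))
  }, numeric(1))
}

# random boolean mask with a controllable fill fraction
random_mask <- function(dims, p = 0.3) {
  array(stats::runif(prod(dims)) < p, dims)
}

# random valid six-lobe map on a small grid
random_lobe_map <- function(dims = c(6, 6, 6), spacing = c(1, 1, 1)) {
  lobe_map(array(sample(0:6, prod(dims), replace = TRUE), dims), spacing)
}

# solid cylinder along the y axis
cylinder_mask <- function(dims, radius, axis_z, axis_x, y_range) {
  Z <- slice.index(array(0L, dims), 1)
  Y <- slice.index(array(0L, dims), 2)
  X <- slice.index(array(0L, dims), 3)
  ((Z - axis_z)^2 + (X - axis_x)^2 <= radius^2) &
    Y >= y_range[1] & Y <= y_range[2]
}
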