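## Shared fixtures, built in code.

## Axis-aligned cube of given side, triangulated (12 faces, outward winding).
cube_mesh <- function(side = 2, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  v <- sweep(v, 2, origin, "+")
  colnames(v) <- NULL
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  triangle_mesh(v, f, topology_id = "cube")
}

## Regular tetrahedron as an ascii PLY file; returns the path.
tetra_ply <- function(path = tempfile(fileext = ".ply")) {
  writeLines(c(
    "ply", "format ascii 1.0",
    "element vertex 4",
    "property float x", "property float y", "property float z",
    "element face 4",
    "property list uchar int vertex_indices",
    "end_header",
    "0 0 0", "1 0 0", "0 1 0", "0 0 1",
    "3 0 2 1", "3 0 1 3", "3 0 3 2", "3 1 2 3"), path)
  path
}

## Small cohort config for fast tests.
tiny_config <- function(n = 5L, resolution = 2L, seed = 1L, ...) {
  cohort_config(group_sizes = c(CON = n, OLZ = n, HAL = n),
                template_resolution = resolution, seed = seed, ...)
}

## Fully deterministic config: no stochastic fields at all.
noiseless_config <- function(n = 2L, resolution = 2L, seed = 1L, ...) {
  defaults <- list(
    group_sizes = c(CON = n, OLZ = n, HAL = n),
    template_resolution = resolution, seed = seed,
    retention = list(CON = c(`0` = 1, `12` = 1, `52` = 1),
                     OLZ = c(`0` = 1, `12` = 1, `24` = 1, `52` = 1, `104` = 1),
                     HAL = c(`0` = 1, `12` = 1, `24` = 1, `52` = 1, `104` = 1)),
    slope_spatial_sd = c(CON = 0, OLZ = 0, HAL = 0),
    subject_mean_slope_sd = 0, subject_spatial_slope_sd = 0,
    vertex_noise_sd = 0,
    baseline_inward = c(CON = 0, OLZ = 0, HAL = 0),
    baseline_subject_offset_sd = 0, baseline_subject_spatial_sd = 0,
    sex_male_offset = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

## Independent brute-force Mann-Whitney enumeration oracle (two-sided).
mwu_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  pooled <- c(x, y)
  us <- apply(idx, 2, function(sel) {
    rr <- rank(pooled)
    sum(rr[sel]) - nx * (nx + 1) / 2
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

## Independent brute-force BH step-up oracle.
bh_oracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  if (k == 0) rep(FALSE, m) else p <= ps[k]
}

## run_pipeline without log chatter or small-n truncation warnings
quiet_run <- function(x) suppressWarnings(suppressMessages(x))
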