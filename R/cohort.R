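#' Configuration for the synthetic longitudinal cohort
#'
#' Defaults emulate a three-group antipsychotic trial design: 51 controls
#' (CON) and two patient arms (OLZ, HAL) of 67, imaged at weeks 0, 12, 24,
#' 52, 104 with group-specific per-visit retention; controls are scheduled
#' only at weeks 0, 12 and 52. Group mean vertex-slope fields default to
#' -0.011 / -0.022 / -0.066 mm/year along the outward normal; the spatial
#' variation of the group fields rides on a single smooth susceptibility
#' pattern shared across groups, scaled per group so the group mean slope
#' maps have across-vertex SDs near 0.057 / 0.057 / 0.077 mm/year.
#' Between-subject slope variation has a scalar (whole-surface) component
#' of SD 0.057 mm/year plus a smooth spatial component of SD 0.12 mm/year;
#' per-visit vertex measurement noise is 0.13 mm. Baseline templates enclose
#' the control mean volumes (left 2528, right 3010 mm^3) and patients
#' receive an inward deformation concentrated on the head and lateral zones.
#'
#' @param group_sizes named integer vector (CON, OLZ, HAL).
#' @param visit_weeks ordered visit schedule in weeks, first must be 0.
#' @param retention named list: per group, a named numeric vector of
#'   per-visit retention probabilities keyed by week; week 0 must be 1.
#'   Weeks absent from a group's vector are not scheduled for that group.
#' @param template_resolution icosphere subdivision level per hemisphere
#'   (3 gives 642 vertices per hemisphere).
#' @param template_volumes target enclosed volumes (mm^3) for the left and
#'   right template.
#' @param slope_mean named group mean vertex slope, mm/year (negative =
#'   inward drift).
#' @param slope_spatial_sd named per-group across-vertex SD of the group
#'   slope field, mm/year.
#' @param subject_mean_slope_sd SD of the per-subject scalar slope offset,
#'   mm/year.
#' @param subject_spatial_slope_sd SD of the per-subject smooth spatial
#'   slope field, mm/year.
#' @param vertex_noise_sd per-visit vertex measurement noise SD, mm.
#' @param baseline_inward named per-group peak inward baseline deformation
#'   (mm, negative = inward) applied on the head + lateral zones.
#' @param baseline_subject_offset_sd SD (mm) of the per-subject scalar
#'   baseline offset, shared across hemispheres.
#' @param baseline_subject_spatial_sd SD (mm) of the per-subject smooth
#'   baseline field, independent per hemisphere.
#' @param sex_male_offset additive baseline offset (mm) for male subjects.
#' @param female_prop named per-group probability of female sex.
#' @param gray_matter_mean,gray_matter_sd mm^3 moments of the supplied
#'   total gray-matter covariate (named CON / PSY).
#' @param illness_lognormal named list of `c(meanlog, sdlog)` for patient
#'   illness duration in weeks.
#' @param smooth_iters neighbor-averaging iterations for smooth fields.
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the config.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(
    group_sizes = c(CON = 51L, OLZ = 67L, HAL = 67L),
    visit_weeks = c(0, 12, 24, 52, 104),
    retention = list(
      CON = c(`0` = 1, `12` = 0.922, `52` = 0.843),
      OLZ = c(`0` = 1, `12` = 0.896, `24` = 0.836, `52` = 0.552, `104` = 0.358),
      HAL = c(`0` = 1, `12` = 0.910, `24` = 0.597, `52` = 0.448, `104` = 0.164)),
    template_resolution = 3L,
    template_volumes = c(left = 2528, right = 3010),
    slope_mean = c(CON = -0.011, OLZ = -0.022, HAL = -0.066),
    slope_spatial_sd = c(CON = 0.049, OLZ = 0.049, HAL = 0.071),
    subject_mean_slope_sd = 0.057,
    subject_spatial_slope_sd = 0.12,
    vertex_noise_sd = 0.13,
    baseline_inward = c(CON = 0, OLZ = -0.55, HAL = -0.55),
    baseline_subject_offset_sd = 0.25,
    baseline_subject_spatial_sd = 0.25,
    sex_male_offset = 0.12,
    female_prop = c(CON = 16 / 51, OLZ = 13 / 67, HAL = 8 / 67),
    gray_matter_mean = c(CON = 705594, PSY = 691758),
    gray_matter_sd = 65000,
    illness_lognormal = list(OLZ = c(meanlog = 3.743, sdlog = 0.777),
                             HAL = c(meanlog = 4.113, sdlog = 0.706)),
    smooth_iters = 20L,
    seed = 1L) {
  stopifnot(all(diff(visit_weeks) > 0), visit_weeks[1] == 0)
  for (g in names(retention)) {
    r <- retention[[g]]
    stopifnot(all(r >= 0 & r <= 1), r[["0"]] == 1,
              all(as.numeric(names(r)) %in% visit_weeks))
  }
  stopifnot(identical(sort(names(group_sizes)), sort(names(retention))))
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("cohort_config:", paste(sprintf("%s=%d", names(x$group_sizes),
                                      x$group_sizes), collapse = " "),
      "| visits", paste(x$visit_weeks, collapse = "/"),
      "| resolution", x$template_resolution, "| seed", x$seed, "\n")
  invisible(x)
}

## ---- template ---------------------------------------------------------

#' Build the left/right template meshes
#'
#' A bent, tapered ellipsoid ("banana") per hemisphere, built from a
#' subdivided icosphere: long axis along x, elliptical cross-section
#' tapering toward the tail, with a gentle dorsal bend. The right mesh is
#' the mirror image of the left (x negated, winding fixed); both are scaled
#' to exactly enclose the requested volumes. Vertices carry zone labels
#' (head/body/tail thirds along the long axis; lateral/medial halves) in
#' `attr(mesh, "zones")` so deformation fields can target anterior-lateral
#' regions.
#'
#' @param resolution icosphere subdivision level (>= 1).
#' @param volumes named target volumes `c(left=, right=)` in mm^3.
#' @return list with elements `left` and `right` (`triangle_mesh`).
#' @export
make_template <- function(resolution = 3L, volumes = c(left = 2528, right = 3010)) {
  stopifnot(resolution >= 1)
  sph <- icosphere(resolution)
  u <- sph$vertices                      # unit-sphere coordinates
  taper <- 1 - 0.3 * (1 - u[, 1]) / 2    # tail (x = -1) thinner than head
  v <- cbind(18 * u[, 1],
             7 * u[, 2] * taper,
             6 * u[, 3] * taper + 0.012 * (18 * u[, 1])^2)
  third <- cut(u[, 1], breaks = c(-1.0001, -1 / 3, 1 / 3, 1.0001),
               labels = c("tail", "body", "head"))
  zones <- list(axis_third = third, lateral = u[, 2] > 0)
  topo <- paste0("hippo-template-res", resolution)
  left <- triangle_mesh(v, sph$faces, "left", topo, validate = FALSE)
  left$vertices <- left$vertices *
    (volumes[["left"]] / enclosed_volume(left))^(1 / 3)
  rv <- left$vertices * (volumes[["right"]] / volumes[["left"]])^(1 / 3)
  rv[, 1] <- -rv[, 1]
  right <- triangle_mesh(rv, sph$faces[, c(1, 3, 2)], "right", topo,
                         validate = FALSE)
  attr(left, "zones") <- zones
  attr(right, "zones") <- zones
  list(left = left, right = right)
}

## ---- smooth fields on the mesh graph ----------------------------------

mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  list(from = e[, 1], to = e[, 2],
       deg = tabulate(e[, 1], nrow(mesh$vertices)))
}

## k iterations of neighbor averaging; accepts a vector or V x n matrix.
smooth_field <- function(x, adj, iters) {
  x <- as.matrix(x)
  for (i in seq_len(iters)) {
    s <- rowsum(x[adj$to, , drop = FALSE], adj$from, reorder = TRUE)
    x <- s / adj$deg
  }
  x
}

## smooth unit field: white noise -> smoothed -> centered, unit SD
random_smooth_field <- function(V, adj, iters, n = 1) {
  z <- matrix(stats::rnorm(V * n), V, n)
  z <- smooth_field(z, adj, iters)
  z <- scale(z)            # column mean 0, sd 1
  z[, , drop = TRUE]
}

## template context: normals + adjacency, cached on the template list
template_context <- function(template) {
  ctx <- attr(template, "hippomorph_ctx")
  if (!is.null(ctx)) return(ctx)
  ctx <- list(
    normals = lapply(template, vertex_normals),
    adjacency = mesh_adjacency(template$left),  # shared topology
    V = nrow(template$left$vertices))
  ctx
}

#' Attach cached geometry (normals, adjacency) to a template
#'
#' Precomputing the context once makes repeated subject sampling cheap.
#' @param template list(left, right) from [make_template()].
#' @return the template with a cached context attribute.
#' @export
prepare_template <- function(template) {
  attr(template, "hippomorph_ctx") <- template_context(template)
  template
}

#' Deterministic group baseline deformation field
#'
#' Patients receive an inward (negative) displacement along the outward
#' template normal, concentrated on the head third and the lateral half of
#' the surface and smoothed over the mesh graph so the deformation has soft
#' edges. Controls default to a zero field.
#'
#' @param template template list.
#' @param group group label present in `config$baseline_inward`.
#' @param config a `cohort_config`.
#' @return list of per-vertex fields (mm), one per hemisphere.
#' @export
baseline_field <- function(template, group, config) {
  ctx <- template_context(template)
  amp <- config$baseline_inward[[group]]
  lapply(template, function(mesh) {
    z <- attr(mesh, "zones")
    w <- as.numeric(z$axis_third == "head" | z$lateral)
    w <- smooth_field(w, ctx$adjacency, 5)[, 1]
    if (max(w) > 0) w <- w / max(w)
    amp * w
  })
}

## Group slope field: mean + shared susceptibility pattern scaled per group.
## `pattern` is a list(left, right) of centered unit-SD fields.
group_slope_field <- function(group, config, pattern) {
  lapply(pattern, function(psi)
    config$slope_mean[[group]] + config$slope_spatial_sd[[group]] * psi)
}

## ---- subject-level sampling -------------------------------------------

#' Sample a subject's baseline surfaces
#'
#' Each vertex is displaced from the template along the outward template
#' normal by the group baseline field plus a subject effect: a scalar
#' offset (shared across hemispheres, with a sex term) plus a smooth
#' zero-mean spatial field per hemisphere. Draws come from the current RNG
#' stream.
#'
#' @param template (prepared) template list.
#' @param group group label.
#' @param config a `cohort_config`.
#' @param bfield optional precomputed [baseline_field()] result.
#' @param sex `"F"` or `"M"`; drawn from `config$female_prop` if missing.
#' @return list with `left`/`right` V x 3 vertex matrices, `sex`, and the
#'   scalar `offset` used (mm).
#' @export
sample_subject_baseline <- function(template, group, config,
                                    bfield = NULL, sex = NULL) {
  ctx <- template_context(template)
  if (is.null(bfield)) bfield <- baseline_field(template, group, config)
  if (is.null(sex))
    sex <- if (stats::runif(1) < config$female_prop[[group]]) "F" else "M"
  offset <- stats::rnorm(1, 0, config$baseline_subject_offset_sd) +
    if (sex == "M") config$sex_male_offset else 0
  out <- list()
  for (h in c("left", "right")) {
    spatial <- if (config$baseline_subject_spatial_sd > 0)
      config$baseline_subject_spatial_sd *
        random_smooth_field(ctx$V, ctx$adjacency, config$smooth_iters)
    else rep(0, ctx$V)
    disp <- bfield[[h]] + offset + spatial
    out[[h]] <- template[[h]]$vertices + disp * ctx$normals[[h]]
  }
  out$sex <- sex
  out$offset <- offset
  out
}

#' Sample a subject's longitudinal visit series
#'
#' The subject's true slope field is the group slope field plus a scalar
#' subject offset and a smooth spatial subject field. At retained visit
#' week t the vertex is displaced from its baseline position along the
#' baseline outward normal by slope * t/52 plus i.i.d. vertex noise; week 0
#' is always present and noise-free (it is the reference surface).
#'
#' @param baseline list with `left`/`right` baseline vertex matrices.
#' @param group group label.
#' @param config a `cohort_config`.
#' @param template prepared template (supplies topology for baseline
#'   normals).
#' @param sfield optional precomputed group slope field (list left/right);
#'   if `NULL` a flat field at `config$slope_mean[[group]]` is used.
#' @return list: `weeks` (retained weeks), `visits` (per retained week, a
#'   list of left/right vertex matrices), `true_slope` (the subject's true
#'   per-vertex slope field, mm/year, per hemisphere).
#' @export
sample_longitudinal_series <- function(baseline, group, config, template,
                                       sfield = NULL) {
  ctx <- template_context(template)
  V <- ctx$V
  if (is.null(sfield))
    sfield <- list(left = rep(config$slope_mean[[group]], V),
                   right = rep(config$slope_mean[[group]], V))
  ret <- config$retention[[group]]
  weeks <- as.numeric(names(ret))
  keep <- c(TRUE, stats::runif(length(weeks) - 1) < ret[-1])
  weeks <- weeks[keep]
  slope_offset <- stats::rnorm(1, 0, config$subject_mean_slope_sd)
  true_slope <- list()
  bn <- list()
  for (h in c("left", "right")) {
    spatial <- if (config$subject_spatial_slope_sd > 0)
      config$subject_spatial_slope_sd *
        random_smooth_field(V, ctx$adjacency, config$smooth_iters)
    else rep(0, V)
    true_slope[[h]] <- sfield[[h]] + slope_offset + spatial
    bmesh <- template[[h]]
    bmesh$vertices <- baseline[[h]]
    bn[[h]] <- vertex_normals(bmesh)
  }
  visits <- list()
  for (w in weeks) {
    vis <- list()
    for (h in c("left", "right")) {
      if (w == 0) {
        vis[[h]] <- baseline[[h]]
      } else {
        disp <- true_slope[[h]] * (w / 52) +
          stats::rnorm(V, 0, config$vertex_noise_sd)
        vis[[h]] <- baseline[[h]] + disp * bn[[h]]
      }
    }
    visits[[as.character(w)]] <- vis
  }
  list(weeks = weeks, visits = visits, true_slope = true_slope)
}

## ---- whole-cohort generation ------------------------------------------

#' Generate a synthetic longitudinal cohort
#'
#' Deterministic given `config$seed`: builds the template, draws the shared
#' slope susceptibility pattern, then samples every subject's baseline and
#' longitudinal series in a fixed order. Optionally writes the cohort to a
#' dataset directory (`metadata.csv` + `meshes/<id>_<hemi>_<week>.vtk`).
#'
#' @param config a `cohort_config`.
#' @param dir optional output directory for the on-disk dataset.
#' @return a `synthetic_cohort` object: `template`, `subjects` metadata
#'   data.frame, `visits` (per subject), and `truth` (realized group slope
#'   and baseline fields, for recovery checks).
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  template <- prepare_template(
    make_template(config$template_resolution, config$template_volumes))
  ctx <- template_context(template)
  pattern <- list(left = random_smooth_field(ctx$V, ctx$adjacency,
                                             config$smooth_iters),
                  right = random_smooth_field(ctx$V, ctx$adjacency,
                                              config$smooth_iters))
  groups <- names(config$group_sizes)
  bfields <- lapply(groups, baseline_field, template = template,
                    config = config)
  names(bfields) <- groups
  sfields <- lapply(groups, group_slope_field, config = config,
                    pattern = pattern)
  names(sfields) <- groups
  subjects <- list()
  visits <- list()
  true_slopes <- list()
  for (g in groups) {
    for (i in seq_len(config$group_sizes[[g]])) {
      id <- sprintf("%s%03d", g, i)
      bl <- sample_subject_baseline(template, g, config, bfields[[g]])
      series <- sample_longitudinal_series(bl[c("left", "right")], g, config,
                                           template, sfields[[g]])
      gm_grp <- if (g == "CON") "CON" else "PSY"
      gm <- stats::rnorm(1, config$gray_matter_mean[[gm_grp]],
                         config$gray_matter_sd) + 120000 * bl$offset
      ill <- if (g %in% names(config$illness_lognormal)) {
        pars <- config$illness_lognormal[[g]]
        stats::rlnorm(1, pars[["meanlog"]], pars[["sdlog"]])
      } else NA_real_
      subjects[[id]] <- data.frame(
        subject_id = id, group = g, sex = bl$sex,
        gray_matter_volume_mm3 = gm,
        illness_duration_weeks = ill,
        weeks_available = paste(series$weeks, collapse = ";"),
        stringsAsFactors = FALSE)
      visits[[id]] <- series$visits
      true_slopes[[id]] <- series$true_slope
    }
  }
  cohort <- structure(list(
    config = config,
    template = template,
    subjects = do.call(rbind, c(subjects, list(make.row.names = FALSE))),
    visits = visits,
    truth = list(slope_fields = sfields, baseline_fields = bfields,
                 subject_slopes = true_slopes, pattern = pattern)),
    class = "synthetic_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat("synthetic_cohort:", paste(sprintf("%s=%d", names(tab), tab),
                                 collapse = " "),
      "| V per hemisphere:", nrow(x$template$left$vertices),
      "| seed", x$config$seed, "\n")
  invisible(x)
}

#' Subject weeks available, as numeric vector
#' @param cohort a `synthetic_cohort`.
#' @param id subject id.
#' @return numeric weeks.
#' @export
subject_weeks <- function(cohort, id) {
  as.numeric(names(cohort$visits[[id]]))
}

#' Materialize one subject visit as a `triangle_mesh`
#' @param cohort a `synthetic_cohort`.
#' @param id subject id.
#' @param week visit week.
#' @param hemisphere `"left"` or `"right"`.
#' @return a `triangle_mesh` sharing the template topology.
#' @export
subject_mesh <- function(cohort, id, week, hemisphere) {
  vm <- cohort$visits[[id]][[as.character(week)]][[hemisphere]]
  if (is.null(vm)) stop("no mesh for ", id, " week ", week, " ", hemisphere)
  tm <- cohort$template[[hemisphere]]
  tm$vertices <- vm
  tm
}

#' Write a cohort to a dataset directory
#'
#' Layout: `metadata.csv` (subject_id, group, sex, gray_matter_volume_mm3,
#' illness_duration_weeks, weeks_available) and
#' `meshes/<subjectID>_<hemi>_<week>.vtk`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  mdir <- file.path(dir, "meshes")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  for (tpl in c("left", "right"))
    write_surface(cohort$template[[tpl]],
                  file.path(dir, sprintf("template_%s.vtk", tpl)))
  for (id in cohort$subjects$subject_id) {
    for (w in subject_weeks(cohort, id)) {
      for (h in c("left", "right")) {
        write_surface(subject_mesh(cohort, id, w, h),
                      file.path(mdir, sprintf("%s_%s_%d.vtk", id, h, w)))
      }
    }
  }
  invisible(dir)
}

#' Load a cohort dataset directory written by [write_cohort()]
#'
#' @param dir dataset directory.
#' @param template_resolution resolution used when the dataset was written
#'   (only needed to rebuild zone labels; geometry is read from disk).
#' @return a `synthetic_cohort` (without generator truth fields).
#' @export
read_cohort <- function(dir, template_resolution = NULL) {
  md <- utils::read.csv(file.path(dir, "metadata.csv"),
                        stringsAsFactors = FALSE)
  template <- list(
    left = read_surface(file.path(dir, "template_left.vtk"),
                        hemisphere = "left"),
    right = read_surface(file.path(dir, "template_right.vtk"),
                         hemisphere = "right"))
  if (!is.null(template_resolution)) {
    zones <- attr(make_template(template_resolution)$left, "zones")
    attr(template$left, "zones") <- zones
    attr(template$right, "zones") <- zones
  }
  template <- prepare_template(template)
  visits <- list()
  for (i in seq_len(nrow(md))) {
    id <- md$subject_id[i]
    weeks <- as.numeric(strsplit(md$weeks_available[i], ";")[[1]])
    visits[[id]] <- list()
    for (w in weeks) {
      visits[[id]][[as.character(w)]] <- lapply(
        c(left = "left", right = "right"),
        function(h) read_surface(
          file.path(dir, "meshes", sprintf("%s_%s_%d.vtk", id, h, w)),
          hemisphere = h)$vertices)
    }
  }
  structure(list(config = NULL, template = template, subjects = md,
                 visits = visits, truth = NULL),
            class = "synthetic_cohort")
}
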