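## Longitudinal analyses: per-subject volume and vertex slopes, slope CDFs,
## percent-negative / large-magnitude statistics, vertex-wise comparisons.

#' Per-vertex longitudinal slope map for one subject
#'
#' For each vertex the scalar trajectory is the displacement of the vertex
#' at week t from its week-0 position, projected on the subject's baseline
#' outward normal (week 0 contributes the value 0). The least-squares slope
#' over available weeks is converted to mm/year (52 weeks/year).
#' Hemispheres are concatenated left-then-right.
#'
#' @param cohort a `synthetic_cohort`.
#' @param id subject id.
#' @param min_visits minimum visits required (default 2).
#' @return a `slope_map` numeric vector of length 2V (mm/year) with
#'   attributes `V_left`, `n_visits`, `label`.
#' @export
vertex_slope_map <- function(cohort, id, min_visits = 2) {
  weeks <- subject_weeks(cohort, id)
  if (length(weeks) < min_visits)
    stop("subject ", id, " has ", length(weeks),
         " visit(s); slope map undefined")
  t_yr <- weeks / 52
  tc <- t_yr - mean(t_yr)
  sxx <- sum(tc^2)
  slopes <- unlist(lapply(c("left", "right"), function(h) {
    base <- cohort$visits[[id]][["0"]][[h]]
    bmesh <- cohort$template[[h]]
    bmesh$vertices <- base
    n0 <- vertex_normals(bmesh)
    ## V x n_weeks displacement matrix (week 0 column is exactly 0)
    D <- vapply(as.character(weeks), function(w)
      rowSums((cohort$visits[[id]][[w]][[h]] - base) * n0),
      numeric(nrow(base)))
    drop(D %*% tc) / sxx
  }), use.names = FALSE)
  structure(slopes, V_left = nrow(cohort$template$left$vertices),
            n_visits = length(weeks), label = id, class = "slope_map")
}

#' @export
print.slope_map <- function(x, ...) {
  cat(sprintf("slope_map '%s': %d vertices, mean %.4f mm/year (%d visits)\n",
              attr(x, "label"), length(x), mean(x),
              if (is.null(attr(x, "n_visits"))) NA else attr(x, "n_visits")))
  invisible(x)
}

#' Slope maps for all eligible subjects
#'
#' Computes [vertex_slope_map()] for every subject with at least
#' `min_visits` visits; subjects with only a baseline visit are excluded
#' (least squares needs two points).
#'
#' @param cohort a `synthetic_cohort`.
#' @param min_visits minimum visits (default 2).
#' @return `slope_map_set`: `slopes` (subjects x 2V matrix, mm/year),
#'   `subjects` (metadata subset), `n_visits`, `V_left`.
#' @export
subject_slope_maps <- function(cohort, min_visits = 2) {
  md <- cohort$subjects
  nv <- vapply(md$subject_id, function(id) length(subject_weeks(cohort, id)), 0L)
  keep <- nv >= min_visits
  md <- md[keep, ]
  maps <- t(vapply(md$subject_id, function(id)
    as.numeric(vertex_slope_map(cohort, id, min_visits)),
    numeric(2 * nrow(cohort$template$left$vertices))))
  structure(list(slopes = maps, subjects = md, n_visits = nv[keep],
                 V_left = nrow(cohort$template$left$vertices)),
            class = "slope_map_set")
}

#' @export
print.slope_map_set <- function(x, ...) {
  cat(sprintf("slope_map_set: %d subjects x %d vertices\n",
              nrow(x$slopes), ncol(x$slopes)))
  invisible(x)
}

#' Group mean slope map
#'
#' Vertex-wise arithmetic mean of subject slope maps.
#'
#' @param maps a `slope_map_set`, or a subjects x vertices matrix.
#' @param subset optional logical/index vector selecting subjects.
#' @param label label stored on the result.
#' @return a `slope_map`.
#' @export
group_mean_slope_map <- function(maps, subset = NULL, label = "group") {
  m <- if (inherits(maps, "slope_map_set")) maps$slopes else as.matrix(maps)
  vl <- if (inherits(maps, "slope_map_set")) maps$V_left else ncol(m) %/% 2
  if (!is.null(subset)) m <- m[subset, , drop = FALSE]
  stopifnot(nrow(m) >= 1)
  structure(colMeans(m), V_left = vl, n_visits = NA_integer_, label = label,
            class = "slope_map")
}

#' Empirical CDF of a slope map
#'
#' Right-continuous empirical cumulative distribution of per-vertex slopes
#' (left and right hemispheres combined), evaluated at the sorted unique
#' slope values.
#'
#' @param map a `slope_map` (or numeric vector of slopes).
#' @return data.frame with columns `slope`, `cum_frac`.
#' @export
slope_cdf <- function(map) {
  v <- sort(unique(as.numeric(map)))
  data.frame(slope = v, cum_frac = stats::ecdf(as.numeric(map))(v))
}

#' Control-referenced large-magnitude slope thresholds
#'
#' Thresholds are the control mean +/- 1 SD of a control slope
#' distribution. Methods: `"mean_map"` (default; moments over vertices of
#' the control group mean slope map), `"pooled_vertices"` (moments over all
#' control subjects' vertex slopes pooled), `"subject_means"` (moments over
#' control subjects' per-subject mean slopes). The mean-map method is the
#' default because the group mean map is the distribution the slope CDFs
#' summarize, and its dispersion — not the much larger dispersion of
#' individual noisy maps — is what places the thresholds a workable
#' distance from zero. The method used is recorded in the output.
#'
#' @param maps a `slope_map_set`.
#' @param control_groups labels treated as controls (default `"CON"`).
#' @param method threshold method.
#' @return `threshold_pair`: `lower`, `upper` (mm/year), `mean`, `sd`,
#'   `method`.
#' @export
control_thresholds <- function(maps, control_groups = "CON",
                               method = c("mean_map", "pooled_vertices",
                                          "subject_means")) {
  method <- match.arg(method)
  sel <- maps$subjects$group %in% control_groups
  stopifnot(sum(sel) >= 2)
  m <- maps$slopes[sel, , drop = FALSE]
  x <- switch(method,
              mean_map = colMeans(m),
              pooled_vertices = as.numeric(m),
              subject_means = rowMeans(m))
  threshold_pair(mean(x), stats::sd(x), method)
}

#' Construct a threshold pair from moments
#'
#' `lower = mean - sd`, `upper = mean + sd`. Exposed separately so
#' thresholds can also be formed from externally reported moments.
#'
#' @param mean,sd moments of the reference slope distribution (mm/year);
#'   `sd` must be positive.
#' @param method label recorded with the pair.
#' @return `threshold_pair` list.
#' @export
threshold_pair <- function(mean, sd, method = "moments") {
  if (!is.finite(sd) || sd <= 1e-9)
    stop("degenerate reference distribution: SD must be positive ",
         "(got ", format(sd), " mm/year)")
  structure(list(lower = mean - sd, upper = mean + sd,
                 mean = mean, sd = sd, method = method),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("thresholds (%s): lower %.5f, upper %.5f mm/year\n",
              x$method, x$lower, x$upper))
  invisible(x)
}

#' Percentage summaries of one slope map
#'
#' Percent of vertices with negative slope, with slope below the lower
#' threshold ("very negative") and above the upper threshold ("very
#' positive"), per hemisphere and combined. Inequalities are strict; exact
#' zeros count as non-negative.
#'
#' @param map a `slope_map` (length 2V, left then right).
#' @param thresholds a `threshold_pair`.
#' @param V_left number of left-hemisphere vertices (taken from the map
#'   attribute if absent).
#' @return one-row data.frame with columns
#'   `pct_negative_{left,right,combined}`,
#'   `pct_very_negative_{left,right,combined}`,
#'   `pct_very_positive_{left,right,combined}`.
#' @export
slope_percentages <- function(map, thresholds, V_left = attr(map, "V_left")) {
  stopifnot(inherits(thresholds, "threshold_pair"), !is.null(V_left))
  x <- as.numeric(map)
  idx <- list(left = seq_len(V_left),
              right = (V_left + 1):length(x),
              combined = seq_along(x))
  out <- lapply(idx, function(i) c(
    pct_negative = 100 * mean(x[i] < 0),
    pct_very_negative = 100 * mean(x[i] < thresholds$lower),
    pct_very_positive = 100 * mean(x[i] > thresholds$upper)))
  res <- as.data.frame(as.list(unlist(lapply(names(out), function(h)
    stats::setNames(out[[h]], paste0(names(out[[h]]), "_", h))))))
  res
}

#' Percentage summaries for every subject in a slope map set
#'
#' @param maps a `slope_map_set`.
#' @param thresholds a `threshold_pair`.
#' @return data.frame: subject_id, group, n_visits and the
#'   [slope_percentages()] columns.
#' @export
summarize_slopes <- function(maps, thresholds) {
  pc <- do.call(rbind, lapply(seq_len(nrow(maps$slopes)), function(i)
    slope_percentages(structure(maps$slopes[i, ], V_left = maps$V_left,
                                class = "slope_map"),
                      thresholds, maps$V_left)))
  cbind(maps$subjects[c("subject_id", "group")],
        n_visits = maps$n_visits, pc)
}

#' Group comparison of slope percentage metrics
#'
#' For each metric (percent negative, percent very negative, percent very
#' positive): Shapiro-Wilk normality per group on the combined-hemisphere
#' values (diagnostic, not blocking), a mixed ANOVA with hemisphere as the
#' repeated factor, a one-way ANOVA on the hemisphere-averaged values, and
#' Fisher's-LSD post hoc pairwise tests.
#'
#' @param summaries a [summarize_slopes()] table.
#' @return list per metric with `shapiro` (named p per group), `rm_anova`,
#'   `anova`, `posthoc`; class `percentage_comparison`.
#' @export
compare_percentages <- function(summaries) {
  g <- factor(summaries$group)
  metrics <- c("pct_negative", "pct_very_negative", "pct_very_positive")
  out <- lapply(metrics, function(mt) {
    L <- summaries[[paste0(mt, "_left")]]
    R <- summaries[[paste0(mt, "_right")]]
    comb <- summaries[[paste0(mt, "_combined")]]
    sw <- vapply(levels(g), function(l) {
      xi <- comb[g == l]
      if (length(xi) >= 3 && stats::sd(xi) > 0) shapiro_normality(xi)$p_value
      else NA_real_
    }, 0)
    const <- stats::sd((L + R) / 2) == 0
    list(shapiro = sw,
         rm_anova = if (!const) rm_anova_group_hemisphere(L, R, g) else NULL,
         anova = if (!const) oneway_anova((L + R) / 2, g) else
           morph_test(0, "F", c(nlevels(g) - 1, length(L) - nlevels(g)), 1),
         posthoc = if (!const) pairwise_posthoc((L + R) / 2, g) else NULL)
  })
  names(out) <- metrics
  structure(out, class = "percentage_comparison")
}

#' @export
print.percentage_comparison <- function(x, ...) {
  for (mt in names(x)) {
    cat(mt, ": "); print(x[[mt]]$anova)
  }
  invisible(x)
}

#' Vertex-wise comparison of subject slope maps between two groups
#'
#' Mann-Whitney U per vertex on the subject slope values, FDR thresholding
#' at `q`, and the mean slope difference map for visualization.
#'
#' @param maps a `slope_map_set`.
#' @param group_a,group_b group labels (`"PSY"` pools OLZ+HAL).
#' @param q FDR level (default 0.05).
#' @return `displacement_map`-shaped result: `mean_diff` (mm/year), `p`,
#'   `fdr_mask`, `p_threshold`, `V_left`.
#' @export
vertexwise_slope_test <- function(maps, group_a, group_b, q = 0.05) {
  sel_a <- pick_group(maps$subjects$group, group_a)
  sel_b <- pick_group(maps$subjects$group, group_b)
  stopifnot(sum(sel_a) >= 2, sum(sel_b) >= 2)
  A <- maps$slopes[sel_a, , drop = FALSE]
  B <- maps$slopes[sel_b, , drop = FALSE]
  p <- vapply(seq_len(ncol(A)), function(j)
    mann_whitney_u(A[, j], B[, j])$p_value, 0)
  fdr <- bh_fdr(p, q)
  structure(list(mean_diff = colMeans(A) - colMeans(B), p = p,
                 fdr_mask = fdr$rejected, p_threshold = fdr$p_threshold,
                 q = q, V_left = maps$V_left, groups = c(group_a, group_b)),
            class = "vertexwise_slope_test")
}

#' @export
print.vertexwise_slope_test <- function(x, ...) {
  cat(sprintf("vertex-wise slope test %s vs %s: %d/%d FDR rejections (q=%.2g)\n",
              x$groups[1], x$groups[2], sum(x$fdr_mask), length(x$fdr_mask),
              x$q))
  invisible(x)
}

#' Per-subject volume slopes and group comparisons
#'
#' Per subject and hemisphere, the least-squares slope of enclosed volume
#' against week (mm^3/week) over available visits; a mixed ANOVA of the
#' slopes with hemisphere as the repeated factor; and the random-intercept
#' mixed model of volume per hemisphere (time and group-by-time Wald F).
#' Subjects with fewer than two visits are excluded from the slope table.
#'
#' @param cohort a `synthetic_cohort`.
#' @return `volume_slope_analysis` list: `slopes` table (subject_id, group,
#'   left_slope, right_slope), `rm_anova`, `mixed` (per hemisphere),
#'   `long_volumes` (the long table used).
#' @export
volume_slope_analysis <- function(cohort) {
  md <- cohort$subjects
  long <- list()
  for (id in md$subject_id) {
    wk <- subject_weeks(cohort, id)
    for (h in c("left", "right")) {
      vols <- vapply(wk, function(w)
        enclosed_volume(subject_mesh(cohort, id, w, h)), 0)
      long[[length(long) + 1L]] <- data.frame(
        subject = id, group = md$group[md$subject_id == id],
        hemisphere = h, week = wk, volume = vols,
        stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, long)
  nv <- table(long$subject[long$hemisphere == "left"])
  eligible <- names(nv)[nv >= 2]
  slopes <- do.call(rbind, lapply(eligible, function(id) {
    sl <- long[long$subject == id, ]
    data.frame(subject_id = id, group = sl$group[1],
               left_slope = ls_slope(sl$week[sl$hemisphere == "left"],
                                     sl$volume[sl$hemisphere == "left"])$slope,
               right_slope = ls_slope(sl$week[sl$hemisphere == "right"],
                                      sl$volume[sl$hemisphere == "right"])$slope,
               stringsAsFactors = FALSE)
  }))
  slopes <- slopes[match(md$subject_id[md$subject_id %in% eligible],
                         slopes$subject_id), ]
  rm <- rm_anova_group_hemisphere(slopes$left_slope, slopes$right_slope,
                                  factor(slopes$group))
  mixed <- lapply(c(left = "left", right = "right"), function(h)
    mixed_model_volume(long[long$hemisphere == h,
                            c("subject", "group", "week", "volume")]))
  structure(list(slopes = slopes, rm_anova = rm, mixed = mixed,
                 long_volumes = long),
            class = "volume_slope_analysis")
}

#' @export
print.volume_slope_analysis <- function(x, ...) {
  for (g in unique(x$slopes$group)) {
    sel <- x$slopes$group == g
    cat(sprintf("  %s: left %.2f (%.1f), right %.2f (%.1f) mm^3/week [n=%d]\n",
                g, mean(x$slopes$left_slope[sel]),
                stats::sd(x$slopes$left_slope[sel]),
                mean(x$slopes$right_slope[sel]),
                stats::sd(x$slopes$right_slope[sel]), sum(sel)))
  }
  print(x$rm_anova)
  cat("mixed model (left):  time "); print(x$mixed$left$time)
  cat("mixed model (left):  group:time "); print(x$mixed$left$group_time)
  invisible(x)
}

#' Export a slope map as a VTK surface with display clamping
#'
#' Writes one hemisphere of a slope map onto the template geometry with two
#' scalar fields: `slope_display` clamped to +/- `display_range` (the
#' conventional rendering window) and the unclamped `slope`.
#'
#' @param template template list (or a cohort's `$template`).
#' @param map a `slope_map` (length 2V).
#' @param hemisphere `"left"` or `"right"`.
#' @param path output file.
#' @param display_range clamp half-width in mm/year (default 0.1).
#' @return `path`, invisibly.
#' @export
export_slope_surface <- function(template, map, hemisphere, path,
                                 display_range = 0.1) {
  vl <- attr(map, "V_left")
  x <- as.numeric(map)
  idx <- if (hemisphere == "left") seq_len(vl) else (vl + 1):length(x)
  s <- x[idx]
  write_surface(template[[hemisphere]], path,
                scalars = list(
                  slope_display = pmin(pmax(s, -display_range), display_range),
                  slope = s),
                digits = 9)
}
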