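test_that("noiseless slope maps recover the configured field exactly", {
  ## flat field: every vertex slope equals the group mean
  co <- generate_cohort(noiseless_config(
    n = 2L, slope_mean = c(CON = 0.1, OLZ = 0.1, HAL = 0.1)))
  sm <- vertex_slope_map(co, "CON001")
  expect_lt(max(abs(as.numeric(sm) - 0.1)), 1e-9)

  ## spatially varying field: recovered vertex-wise
  co2 <- generate_cohort(noiseless_config(
    n = 2L, seed = 5L, slope_spatial_sd = c(CON = 0.05, OLZ = 0.05, HAL = 0.08)))
  truth <- co2$truth$subject_slopes[["HAL001"]]
  got <- vertex_slope_map(co2, "HAL001")
  expect_lt(max(abs(as.numeric(got) - c(truth$left, truth$right))), 1e-9)

  ## a single visit is refused
  co3 <- generate_cohort(tiny_config(n = 2L, seed = 6L))
  co3$visits[["CON001"]] <- co3$visits[["CON001"]]["0"]
  expect_error(vertex_slope_map(co3, "CON001"), "undefined")
  maps <- subject_slope_maps(co3)
  expect_false("CON001" %in% maps$subjects$subject_id)
})

test_that("two-visit slopes are the two-point line in mm/year", {
  co <- generate_cohort(noiseless_config(
    n = 2L,
    retention = list(CON = c(`0` = 1, `12` = 1),
                     OLZ = c(`0` = 1, `12` = 1),
                     HAL = c(`0` = 1, `12` = 1)),
    slope_mean = c(CON = -0.04, OLZ = -0.04, HAL = -0.04)))
  sm <- vertex_slope_map(co, "OLZ001")
  ## displacement at week 12 is slope * 12/52; the fitted slope recovers it
  m0 <- subject_mesh(co, "OLZ001", 0, "left")
  disp12 <- rowSums((subject_mesh(co, "OLZ001", 12, "left")$vertices -
                       m0$vertices) * vertex_normals(m0))
  expect_equal(as.numeric(sm)[1:162], disp12 * 52 / 12, tolerance = 1e-9)
})

test_that("group mean maps are linear and label-correct", {
  co <- generate_cohort(tiny_config(n = 3L, seed = 41L))
  maps <- subject_slope_maps(co)
  one <- group_mean_slope_map(maps, 1, "solo")
  expect_equal(as.numeric(one), maps$slopes[1, ], tolerance = 0)
  ## +a and -a average to zero
  m2 <- rbind(maps$slopes[1, ], -maps$slopes[1, ])
  expect_equal(max(abs(group_mean_slope_map(m2))), 0)
  ## group mean map average equals the mean of subject map averages
  grp <- maps$subjects$group == "HAL"
  expect_equal(mean(group_mean_slope_map(maps, grp)),
               mean(rowMeans(maps$slopes[grp, ])), tolerance = 1e-12)
})

test_that("slope CDFs are proper right-continuous distribution functions", {
  cdf <- slope_cdf(structure(rep(2.5, 10), V_left = 5, class = "slope_map"))
  expect_equal(nrow(cdf), 1)
  expect_equal(cdf$slope, 2.5)
  expect_equal(cdf$cum_frac, 1)
  co <- generate_cohort(tiny_config(n = 3L, seed = 42L))
  maps <- subject_slope_maps(co)
  cdf2 <- slope_cdf(group_mean_slope_map(maps, label = "all"))
  expect_true(all(diff(cdf2$cum_frac) > 0))
  expect_equal(cdf2$cum_frac[nrow(cdf2)], 1)
  expect_true(all(cdf2$cum_frac >= 1 / nrow(cdf2)))
  expect_true(all(diff(cdf2$slope) > 0))
})

test_that("control thresholds: moments arithmetic and method behaviour", {
  ## from externally supplied moments
  tp <- threshold_pair(-0.011, 0.057)
  expect_equal(tp$lower, -0.068, tolerance = 1e-12)
  expect_equal(tp$upper, 0.046, tolerance = 1e-12)
  expect_lt(tp$lower, tp$upper)
  expect_error(threshold_pair(0.1, 0), "degenerate")

  ## degenerate control distribution is refused
  co <- generate_cohort(noiseless_config(n = 3L))
  maps <- subject_slope_maps(co)
  expect_error(control_thresholds(maps), "degenerate")

  ## with a flat field and only scalar between-subject variation,
  ## pooled_vertices and subject_means agree up to Bessel correction
  co2 <- generate_cohort(noiseless_config(
    n = 50L, seed = 43L, subject_mean_slope_sd = 0.05))
  maps2 <- subject_slope_maps(co2)
  t_pool <- control_thresholds(maps2, method = "pooled_vertices")
  t_subj <- control_thresholds(maps2, method = "subject_means")
  expect_equal(t_pool$mean, t_subj$mean, tolerance = 1e-9)
  expect_equal(t_pool$sd, t_subj$sd, tolerance = 0.02)
  expect_equal(t_pool$method, "pooled_vertices")
  ## the mean map itself is flat here (scalar offsets average to a
  ## constant), so the mean_map method correctly refuses to define a band
  expect_error(control_thresholds(maps2, method = "mean_map"), "degenerate")
})

test_that("slope percentages count strict tails per hemisphere", {
  thr <- threshold_pair(-0.011, 0.057)
  allneg <- structure(rep(-1, 20), V_left = 10, class = "slope_map")
  pc <- slope_percentages(allneg, thr)
  expect_equal(pc$pct_negative_combined, 100)
  expect_equal(pc$pct_very_negative_left, 100)
  expect_equal(pc$pct_very_positive_right, 0)

  ## zeros are non-negative; complements sum exactly
  mix <- structure(c(-1, 0, 1, -0.5, 0.2, 0), V_left = 3,
                   class = "slope_map")
  p2 <- slope_percentages(mix, thr)
  expect_equal(p2$pct_negative_combined, 100 * 2 / 6)
  expect_equal(p2$pct_negative_left + 100 * mean(c(-1, 0, 1) >= 0), 100)

  ## symmetric zero-mean map: about half negative
  set.seed(44)
  sym <- rnorm(20000)
  symmap <- structure(c(sym, -sym), V_left = 20000, class = "slope_map")
  p3 <- slope_percentages(symmap, thr)
  expect_equal(p3$pct_negative_combined, 50, tolerance = 0.01)

  ## widening the interval never increases either tail
  wide <- threshold_pair(-0.011, 0.1)
  p4 <- slope_percentages(mix, wide)
  expect_lte(p4$pct_very_negative_combined, p2$pct_very_negative_combined)
  expect_lte(p4$pct_very_positive_combined, p2$pct_very_positive_combined)
})

test_that("percentage comparison pipeline produces the full test family", {
  co <- generate_cohort(tiny_config(n = 8L, seed = 45L))
  maps <- subject_slope_maps(co)
  thr <- control_thresholds(maps)
  summ <- summarize_slopes(maps, thr)
  expect_true(all(c("pct_negative_left", "pct_very_negative_combined") %in%
                    names(summ)))
  expect_true(all(summ$pct_very_negative_left >= 0 &
                    summ$pct_very_negative_left <= 100))
  expect_true(all(summ$pct_very_negative_combined +
                    summ$pct_very_positive_combined <= 100))
  cmp <- compare_percentages(summ)
  expect_named(cmp, c("pct_negative", "pct_very_negative",
                      "pct_very_positive"))
  expect_s3_class(cmp$pct_very_negative$anova, "morph_test")
  expect_s3_class(cmp$pct_very_negative$rm_anova, "rm_anova_gh")
  expect_equal(nrow(cmp$pct_negative$posthoc), 3)
  expect_length(cmp$pct_negative$shapiro, 3)

  ## constant metric degenerates to p = 1 rather than failing
  summ2 <- summ
  for (cl in grep("pct_very_positive", names(summ2), value = TRUE))
    summ2[[cl]] <- 50
  cmp2 <- compare_percentages(summ2)
  expect_equal(cmp2$pct_very_positive$anova$p_value, 1)
})

test_that("vertex-wise slope tests localize painted differences", {
  ## identical groups: no rejections
  co <- generate_cohort(tiny_config(n = 5L, seed = 46L))
  maps <- subject_slope_maps(co)
  fake <- maps
  fake$subjects$group[fake$subjects$group == "HAL"] <- "OLZ"
  sel <- fake$subjects$group == "OLZ"
  ## split the pooled OLZ into two identical halves by duplicating rows
  dup <- maps
  dup$slopes <- rbind(maps$slopes[sel, ], maps$slopes[sel, ])
  dup$subjects <- rbind(transform(maps$subjects[sel, ], group = "A"),
                        transform(maps$subjects[sel, ], group = "B"))
  vt0 <- vertexwise_slope_test(dup, "A", "B")
  expect_equal(sum(vt0$fdr_mask), 0)
  expect_equal(max(abs(vt0$mean_diff)), 0)

  ## a strong difference painted on the tail zone only is found there
  z <- attr(co$template$left, "zones")
  tailzone <- rep(as.logical(z$axis_third == "tail"), 2)
  painted <- maps
  sel_h <- painted$subjects$group == "HAL"
  painted$slopes[sel_h, tailzone] <- painted$slopes[sel_h, tailzone] - 1.5
  vt1 <- vertexwise_slope_test(painted, "HAL", "OLZ")
  expect_gt(sum(vt1$fdr_mask), 0)
  expect_gte(mean(tailzone[vt1$fdr_mask]), 0.8)
})

test_that("volume slope analysis handles noiseless and constant cohorts", {
  ## zero slope field: volumes constant, slopes exactly zero
  co0 <- generate_cohort(noiseless_config(
    n = 3L, slope_mean = c(CON = 0, OLZ = 0, HAL = 0)))
  vsa0 <- volume_slope_analysis(co0)
  expect_lt(max(abs(vsa0$slopes$left_slope)), 1e-9)
  expect_equal(vsa0$mixed$left$time$p_value, 1)

  ## uniform inward slope: negative volume slopes, equal across subjects
  co1 <- generate_cohort(noiseless_config(
    n = 3L, slope_mean = c(CON = -0.05, OLZ = -0.05, HAL = -0.05)))
  vsa1 <- volume_slope_analysis(co1)
  expect_true(all(vsa1$slopes$left_slope < 0))
  expect_lt(diff(range(vsa1$slopes$right_slope[
    vsa1$slopes$group == "OLZ"])), 1e-9)
  ## volume loss rate approximates area * slope / 52 for small displacement
  area_l <- sum(sqrt(rowSums((function(m) {
    v <- m$vertices; f <- m$faces
    e1 <- v[f[, 2], ] - v[f[, 1], ]; e2 <- v[f[, 3], ] - v[f[, 1], ]
    cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
          e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
          e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  })(co1$template$left)^2))) / 2
  expected <- -0.05 * area_l / 52
  expect_equal(mean(vsa1$slopes$left_slope), expected, tolerance = 0.05)
})

test_that("slope surface export clamps for display and round-trips", {
  co <- generate_cohort(tiny_config(n = 2L, seed = 47L))
  maps <- subject_slope_maps(co)
  sm <- structure(maps$slopes[1, ], V_left = maps$V_left,
                  class = "slope_map")
  sm[1] <- 0.5; sm[2] <- -0.05    # outside and inside the display range
  path <- tempfile(fileext = ".vtk")
  export_slope_surface(co$template, sm, "left", path)
  pd <- attr(read_surface(path), "point_data")
  expect_equal(pd$slope_display[1], 0.1)
  expect_equal(pd$slope_display[2], -0.05)
  expect_true(all(abs(pd$slope_display) <= 0.1))
  expect_equal(pd$slope[1], 0.5)  # unclamped copy retained
  expect_equal(pd$slope_display,
               pmin(pmax(as.numeric(sm)[1:162], -0.1), 0.1),
               tolerance = 1e-8)
})
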