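test_that("least-squares slope matches closed-form normal equations", {
  f <- ls_slope(c(0, 52), c(0, 1))
  expect_equal(f$slope, 1 / 52, tolerance = 1e-12)
  expect_equal(f$slope * 52, 1, tolerance = 1e-12)

  f2 <- ls_slope(c(0, 12, 24, 52, 104), rep(7.3, 5))
  expect_equal(f2$slope, 0, tolerance = 1e-12)
  expect_equal(f2$intercept, 7.3, tolerance = 1e-12)

  ## independent normal-equation oracle
  t <- c(0, 12, 24); v <- c(1, 2, 4)
  b_oracle <- (sum(t * v) - length(t) * mean(t) * mean(v)) /
    (sum(t^2) - length(t) * mean(t)^2)
  expect_equal(ls_slope(t, v)$slope, b_oracle, tolerance = 1e-12)
  expect_equal(ls_slope(t, v)$slope, unname(coef(lm(v ~ t))[2]),
               tolerance = 1e-12)

  expect_error(ls_slope(c(5, 5), c(1, 2)), "distinct")
})

test_that("Mann-Whitney exact path equals enumeration for all n_x+n_y <= 10", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  set.seed(7)
  for (nx in 1:9) for (ny in 1:(10 - nx)) {
    if (ny < 1) next
    x <- rnorm(nx); y <- rnorm(ny)
    got <- mann_whitney_u(x, y, exact_max = 9)
    expect_equal(got$p_value, mwu_enum_oracle(x, y), tolerance = 1e-12,
                 info = sprintf("nx=%d ny=%d", nx, ny))
  }
})

test_that("Mann-Whitney approximation is close to exact and handles ties", {
  set.seed(8)
  ## identical multisets give p = 1
  x <- c(1, 2, 2, 3)
  expect_equal(mann_whitney_u(x, x)$p_value, 1)
  expect_equal(mann_whitney_u(rep(1, 5), rep(1, 7))$p_value, 1)
  ## normal approximation vs enumeration at n = 8 per group; the
  ## continuity-corrected approximation sits within 0.02 of exact here
  for (rep in 1:20) {
    x <- rnorm(8); y <- rnorm(8) + runif(1, -1, 1)
    p_apx <- mann_whitney_u(x, y, exact_max = 0)$p_value
    expect_lt(abs(p_apx - mwu_enum_oracle(x, y)), 0.02)
  }
  ## tie-corrected approximation agrees with the standard implementation
  for (rep in 1:20) {
    x <- sample(1:6, 30, TRUE); y <- sample(1:6, 25, TRUE)
    expect_equal(mann_whitney_u(x, y)$p_value,
                 suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE)$p.value),
                 tolerance = 1e-10)
  }
})

test_that("BH FDR equals the brute-force step-up on subsets of a 10-vector", {
  r <- bh_fdr(c(0.001, 0.2, 0.9), 0.05)
  expect_equal(sum(r$rejected), 1)
  expect_equal(r$p_threshold, 0.001)
  expect_equal(sum(bh_fdr(rep(1, 6), 0.05)$rejected), 0)

  set.seed(11)
  p10 <- round(runif(10), 3)
  for (mask in 0:1023) {
    sel <- as.logical(bitwAnd(mask, 2^(0:9)))
    if (!any(sel)) next
    p <- p10[sel]
    expect_identical(unname(bh_fdr(p, 0.05)$rejected), bh_oracle(p, 0.05))
  }
  ## permutation invariance
  p <- runif(50)
  o <- sample(50)
  expect_identical(bh_fdr(p, 0.1)$rejected[o], bh_fdr(p[o], 0.1)$rejected)
  ## monotone in q
  r1 <- bh_fdr(p, 0.01); r2 <- bh_fdr(p, 0.1)
  expect_true(all(r2$rejected[r1$rejected]))
})

test_that("one-way ANOVA matches t-test identity, aov, and degenerate cases", {
  set.seed(3)
  x <- rnorm(12); y <- rnorm(15) + .4
  a <- oneway_anova(list(x, y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(a$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-9)

  g <- rep(1:3, c(6, 7, 8)); v <- rnorm(21) + g / 3
  a3 <- oneway_anova(v, g)
  o <- anova(lm(v ~ factor(g)))
  expect_equal(a3$statistic, o$`F value`[1], tolerance = 1e-9)
  expect_equal(a3$p_value, o$`Pr(>F)`[1], tolerance = 1e-9)

  same <- rep(c(1, 2, 3), 3)
  expect_equal(oneway_anova(same, rep(1:3, each = 3))$p_value, 1)
})

test_that("group/hemisphere mixed ANOVA reduces correctly", {
  set.seed(4)
  ## one group: hemisphere F equals the one-sample t^2 on differences
  L <- rnorm(14); R <- L + .3 + rnorm(14, 0, .6)
  r1 <- rm_anova_group_hemisphere(L, R, rep("g", 14))
  tt <- t.test(R - L)
  expect_equal(r1$hemisphere$statistic, unname(tt$statistic)^2,
               tolerance = 1e-9)
  expect_equal(r1$hemisphere$p_value, tt$p.value, tolerance = 1e-9)

  ## adding a constant to all right values moves hemisphere F, not group F
  g <- rep(1:3, each = 10)
  L <- rnorm(30); R <- L + rnorm(30, 0, .5)
  base <- rm_anova_group_hemisphere(L, R, g)
  shift <- rm_anova_group_hemisphere(L, R + 5, g)
  expect_equal(shift$group$statistic, base$group$statistic, tolerance = 1e-9)
  expect_gt(shift$hemisphere$statistic, base$hemisphere$statistic)
  expect_equal(shift$interaction$statistic, base$interaction$statistic,
               tolerance = 1e-9)

  ## missing hemisphere drops the subject with a warning
  L[1] <- NA
  expect_warning(rm_anova_group_hemisphere(L, R, g), "excluded")
})

test_that("ANCOVA matches the GLM oracle and degenerate covariates", {
  set.seed(5)
  g <- factor(rep(1:3, each = 12))
  y <- rnorm(36) + as.numeric(g) / 2
  z <- rnorm(36)
  a <- ancova(y, g, z)
  o <- anova(lm(y ~ z + g))
  expect_equal(a$statistic, o$`F value`[2], tolerance = 1e-9)
  expect_equal(a$p_value, o$`Pr(>F)`[2], tolerance = 1e-9)

  ## covariate orthogonal to the design and response changes nothing but
  ## one error df: the group sum of squares matches the unadjusted ANOVA
  X <- model.matrix(~g)
  z_orth <- qr.resid(qr(cbind(X, y)), rnorm(36))
  a_orth <- ancova(y, g, z_orth)
  un <- oneway_anova(y, g)
  rss_full <- sum(resid(lm(y ~ g))^2)
  ss_adj <- a_orth$statistic * a_orth$df[1] * rss_full / a_orth$df[2]
  ss_un <- un$statistic * un$df[1] * rss_full / un$df[2]
  expect_equal(ss_adj, ss_un, tolerance = 1e-9)
  expect_equal(a_orth$statistic, un$statistic * a_orth$df[2] / un$df[2],
               tolerance = 1e-9)

  ## covariate equal to y: adjusted group F collapses to 0
  expect_equal(ancova(y, g, y)$statistic, 0)
  expect_error(ancova(y, g, cbind(a = z, b = 2 * z)), "collinear")
})

test_that("Wilks MANOVA matches determinant oracle and univariate reduction", {
  set.seed(6)
  g <- rep(1:3, each = 10)
  S <- matrix(rnorm(60), 30, 2) + cbind(g / 3, 0)
  got <- wilks_manova(S, g)
  ## explicit det(W)/det(W+B) oracle
  Wm <- Reduce(`+`, lapply(split(seq_len(30), g), function(ix)
    crossprod(scale(S[ix, ], scale = FALSE))))
  Tt <- crossprod(scale(S, scale = FALSE))
  expect_equal(got$statistic, det(Wm) / det(Tt), tolerance = 1e-9)
  sm <- summary(manova(S ~ factor(g)), test = "Wilks")$stats
  expect_equal(got$statistic, sm[1, 2], tolerance = 1e-9)
  expect_equal(got$approx_F, sm[1, 3], tolerance = 1e-9)
  expect_equal(got$p_value, sm[1, 6], tolerance = 1e-9)

  ## one variable: Lambda-based F equals the one-way ANOVA F
  s1 <- S[, 1, drop = FALSE]
  expect_equal(wilks_manova(s1, g)$approx_F, oneway_anova(S[, 1], g)$statistic,
               tolerance = 1e-9)
  ## zero between-group scatter: Lambda = 1, p = 1
  Sdup <- rbind(S[1:10, ], S[1:10, ], S[1:10, ])
  r0 <- wilks_manova(Sdup, g)
  expect_equal(r0$statistic, 1, tolerance = 1e-9)
  expect_equal(r0$p_value, 1)
  ## singular within matrix is refused with advice
  expect_error(wilks_manova(matrix(rnorm(30), 30, 1)[, c(1, 1)], g),
               "truncate")
})

test_that("mixed volume model agrees with RM-ANOVA and lmer oracles", {
  skip_if_not_installed("lmerTest")
  set.seed(9)
  n <- 10; tpts <- c(0, 12, 24, 52)
  d <- expand.grid(subject = 1:(3 * n), week = tpts)
  d$group <- rep(rep(c("A", "B", "C"), each = n), length(tpts))
  b <- rnorm(3 * n, 0, 5)
  d$volume <- 100 + b[d$subject] + 0.05 * d$week +
    0.02 * d$week * (d$group == "C") + rnorm(nrow(d), 0, 2)
  fit <- mixed_model_volume(d)
  ## balanced case: classical RM-ANOVA within-subject F values
  d$fs <- factor(d$subject); d$ft <- factor(d$week); d$fg <- factor(d$group)
  a <- summary(aov(volume ~ fg * ft + Error(fs / ft), data = d))
  tab <- a[["Error: fs:ft"]][[1]]
  expect_equal(fit$time$statistic, tab$`F value`[1], tolerance = 0.05)
  expect_equal(fit$group_time$statistic, tab$`F value`[2], tolerance = 0.05)
  ## lmer agreement (REML random intercept, same tests)
  m <- lmerTest::lmer(volume ~ fg * ft + (1 | fs), data = d)
  la <- suppressMessages(anova(m))
  expect_equal(fit$time$statistic, la["ft", "F value"], tolerance = 1e-4)
  expect_equal(fit$group_time$statistic, la["fg:ft", "F value"],
               tolerance = 1e-4)

  ## volumes constant per subject: time effect vanishes
  d2 <- d; d2$volume <- b[d2$subject]
  f2 <- mixed_model_volume(d2)
  expect_equal(f2$time$p_value, 1)

  ## single-visit-only data is refused
  d3 <- d[d$week == 0, ]
  expect_error(mixed_model_volume(d3), "2 visits")
})

test_that("Shapiro gate behaves on normal, skewed, and constant samples", {
  set.seed(10)
  expect_lt(shapiro_normality(rexp(100))$p_value, 0.05)
  r <- shapiro_normality(rnorm(50))
  expect_lte(r$statistic, 1)
  expect_equal(shapiro_normality(rep(2, 10))$p_value, 0)
  ## skewed samples are flagged in the vast majority of draws
  rej <- mean(replicate(100, shapiro_normality(rexp(100))$p_value < 0.05))
  expect_gt(rej, 0.9)
})

test_that("post hoc pairwise tests equal the pooled-t oracle", {
  set.seed(12)
  g <- rep(c("a", "b", "c"), each = 8)
  v <- rnorm(24) + (g == "c")
  ph <- pairwise_posthoc(v, g)
  ## independent pooled-t computation for one pair
  ssw <- sum(unlist(lapply(split(v, g), function(x) sum((x - mean(x))^2))))
  s2 <- ssw / (24 - 3)
  t_ab <- (mean(v[g == "a"]) - mean(v[g == "b"])) / sqrt(s2 * (1 / 8 + 1 / 8))
  row <- ph[ph$group1 == "a" & ph$group2 == "b", ]
  expect_equal(row$t, t_ab, tolerance = 1e-9)
  expect_equal(row$p, 2 * pt(-abs(t_ab), 21), tolerance = 1e-9)
  ## identical samples: p near 1; bonferroni caps at 1
  v2 <- rep(rnorm(8), 3)
  ph2 <- pairwise_posthoc(v2, g)
  expect_true(all(ph2$p > 0.999))
  phb <- pairwise_posthoc(v2, g, correction = "bonferroni")
  expect_true(all(phb$p == 1))
  ## tiny group is skipped with a warning
  g3 <- c(rep("a", 8), rep("b", 8), "c")
  expect_warning(ph3 <- pairwise_posthoc(v[1:17], g3), "skipped")
  expect_false(any(ph3$group1 == "c" | ph3$group2 == "c"))
})
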