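#' Hypothesis-test result container
#'
#' Light S3 container for every test the package computes: a statistic, its
#' name (F, U, W, Wilks, t), degrees of freedom and a two-sided p-value.
#'
#' @param statistic numeric test statistic.
#' @param statistic_name one of `"F"`, `"U"`, `"W"`, `"Wilks"`, `"t"`.
#' @param df numeric vector of degrees of freedom (possibly empty).
#' @param p_value p-value in `[0, 1]`.
#' @param ... further fields stored alongside (e.g. auxiliary statistics).
#' @return an object of class `morph_test`.
#' @export
morph_test <- function(statistic, statistic_name, df, p_value, ...) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(statistic = unname(statistic),
                 statistic_name = statistic_name,
                 df = unname(df), p_value = min(unname(p_value), 1), ...),
            class = "morph_test")
}

#' @export
print.morph_test <- function(x, ...) {
  dfs <- if (length(x$df)) paste0("(", paste(signif(x$df, 5), collapse = ", "), ")") else ""
  cat(sprintf("%s%s = %.4g, p = %.4g\n", x$statistic_name, dfs,
              x$statistic, x$p_value))
  invisible(x)
}

#' Ordinary least-squares slope of a short time series
#'
#' The longitudinal workhorse: the least-squares slope of `values` against
#' `times`, used for both per-subject volume trajectories (mm^3/week) and
#' per-vertex displacement trajectories. Requires at least two distinct time
#' points; callers must exclude subjects that fail this.
#'
#' @param times numeric times (weeks in package usage).
#' @param values numeric observations, same length.
#' @param unit label stored with the fit (e.g. `"per-week"`).
#' @return list with `slope`, `intercept`, `n_points`, `unit`
#'   (class `slope_fit`).
#' @export
ls_slope <- function(times, values, unit = "per-week") {
  stopifnot(length(times) == length(values))
  if (length(unique(times)) < 2)
    stop("slope undefined: fewer than 2 distinct time points")
  tc <- times - mean(times)
  slope <- sum(tc * values) / sum(tc^2)
  structure(list(slope = slope, intercept = mean(values) - slope * mean(times),
                 n_points = length(times), unit = unit), class = "slope_fit")
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from midranks. For small samples (both sizes at most
#' `exact_max`, no ties) the two-sided p-value is exact by full enumeration
#' of all group labelings; otherwise the normal approximation with tie and
#' continuity corrections is used. The cutoff keeps the 13k-vertex map
#' comparisons fast while staying exact where exactness is affordable.
#'
#' @param x,y numeric samples.
#' @param exact_max largest per-group size for the exact path (default 8).
#' @return `morph_test` with statistic U (for `x`), extra fields `method`
#'   (`"exact"`/`"normal"`) and `z` where applicable.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 1, ny >= 1)
  all_v <- c(x, y)
  r <- rank(all_v)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(all_v))
  if (!ties && max(nx, ny) <= exact_max) {
    ## exact: U distribution over all choose(nx+ny, nx) labelings
    combs <- utils::combn(nx + ny, nx)
    ranks <- matrix(seq_len(nx + ny)[combs], nrow = nx)
    us <- colSums(ranks) - nx * (nx + 1) / 2
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    return(morph_test(u, "U", c(nx, ny), p, method = "exact"))
  }
  n <- nx + ny
  mu <- nx * ny / 2
  tie_tab <- table(all_v)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_corr)
  if (sigma2 <= 0) return(morph_test(u, "U", c(nx, ny), 1, method = "normal",
                                     z = 0))
  cc <- sign(u - mu) * 0.5
  z <- (u - mu - cc) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  morph_test(u, "U", c(nx, ny), p, method = "normal", z = z)
}

#' Benjamini-Hochberg step-up FDR thresholding
#'
#' Reject all p-values at or below p_(k*), k* = max{k : p_(k) <= k q / m}.
#' Used to threshold vertex-wise p-value maps at q = 0.05.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param q target false discovery rate in (0, 1).
#' @return list with `q`, logical `rejected`, and `p_threshold` (largest
#'   rejected p, 0 if none); class `fdr_result`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1), q > 0, q < 1)
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  ok <- which(ps <= q * seq_len(m) / m)
  thr <- if (length(ok)) ps[max(ok)] else 0
  structure(list(q = q, rejected = p_values <= thr & thr > 0,
                 p_threshold = thr), class = "fdr_result")
}

#' One-way between-subjects ANOVA
#'
#' @param values numeric vector, or a list of per-group samples (in which
#'   case `groups` is ignored).
#' @param groups grouping factor aligned with `values`.
#' @return `morph_test` (F, df (k-1, N-k)).
#' @export
oneway_anova <- function(values, groups = NULL) {
  if (is.list(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  g <- factor(groups)
  stopifnot(nlevels(g) >= 2, all(table(g) >= 2))
  N <- length(values); k <- nlevels(g)
  gm <- tapply(values, g, mean)
  ssb <- sum(table(g) * (gm - mean(values))^2)
  ssw <- sum((values - gm[g])^2)
  df1 <- k - 1; df2 <- N - k
  if (ssw <= .Machine$double.eps * max(1, sum(values^2))) {
    if (ssb <= .Machine$double.eps * max(1, sum(values^2)))
      return(morph_test(0, "F", c(df1, df2), 1))
    return(morph_test(Inf, "F", c(df1, df2), 0))
  }
  f <- (ssb / df1) / (ssw / df2)
  morph_test(f, "F", c(df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Two-way mixed ANOVA: between-subjects group, within-subjects hemisphere
#'
#' With only two within-subject levels the split-plot design reduces
#' exactly: the group effect is a one-way ANOVA on per-subject hemisphere
#' means, the hemisphere effect is the (type-III, unweighted across groups)
#' test of the mean right-minus-left difference, and the interaction is a
#' one-way ANOVA on the differences. That reduction is implemented directly.
#'
#' @param left,right per-subject values for the two hemisphere levels;
#'   subjects with either side missing (NA) are dropped with a warning.
#' @param groups grouping factor.
#' @return list of `morph_test`: `group`, `hemisphere`, `interaction`
#'   (class `rm_anova_gh`).
#' @export
rm_anova_group_hemisphere <- function(left, right, groups) {
  stopifnot(length(left) == length(right), length(left) == length(groups))
  keep <- !is.na(left) & !is.na(right)
  if (any(!keep)) {
    warning(sum(!keep), " subject(s) missing a hemisphere value excluded")
    left <- left[keep]; right <- right[keep]; groups <- groups[keep]
  }
  g <- factor(groups)
  k <- nlevels(g); N <- length(left)
  m <- (left + right) / 2
  d <- right - left
  if (k == 1L) {
    ## single group: only the hemisphere (one-sample on differences) test
    mse1 <- stats::var(d)
    f1 <- if (mse1 == 0) { if (mean(d) == 0) 0 else Inf } else
      mean(d)^2 / (mse1 / N)
    p1 <- if (is.finite(f1)) stats::pf(f1, 1, N - 1, lower.tail = FALSE) else 0
    if (f1 == 0) p1 <- 1
    return(structure(list(group = NULL,
                          hemisphere = morph_test(f1, "F", c(1, N - 1), p1),
                          interaction = NULL, n = N),
                     class = "rm_anova_gh"))
  }
  grp <- oneway_anova(m, g)
  inter <- oneway_anova(d, g)
  gm <- tapply(d, g, mean)
  ng <- as.numeric(table(g))
  mse <- sum((d - gm[g])^2) / (N - k)
  mu <- mean(gm)                       # unweighted across groups
  if (mse <= .Machine$double.eps * max(1, sum(d^2))) {
    fh <- if (abs(mu) <= sqrt(.Machine$double.eps)) 0 else Inf
    ph <- if (fh == 0) 1 else 0
  } else {
    fh <- mu^2 / (mse / k^2 * sum(1 / ng))
    ph <- stats::pf(fh, 1, N - k, lower.tail = FALSE)
  }
  structure(list(group = grp,
                 hemisphere = morph_test(fh, "F", c(1, N - k), ph),
                 interaction = inter,
                 n = N),
            class = "rm_anova_gh")
}

#' @export
print.rm_anova_gh <- function(x, ...) {
  cat("mixed ANOVA (group between, hemisphere within), n =", x$n, "\n")
  for (nm in c("group", "hemisphere", "interaction")) {
    if (is.null(x[[nm]])) next
    cat(sprintf("  %-12s", nm)); print(x[[nm]])
  }
  invisible(x)
}

#' Analysis of covariance: group effect adjusted for covariates
#'
#' General linear model `y ~ covariates + group`; the group F compares the
#' full model against the covariates-only model (group tested after the
#' covariates, type-III style for this additive design).
#'
#' @param y response vector.
#' @param groups grouping factor.
#' @param covariates numeric vector or matrix of covariates (may be NULL
#'   for an unadjusted fit).
#' @return `morph_test` (adjusted group F).
#' @export
ancova <- function(y, groups, covariates = NULL) {
  g <- factor(groups)
  N <- length(y)
  Xc <- cbind(`(Intercept)` = rep(1, N))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    Xc <- cbind(Xc, covariates)
  }
  Xg <- stats::model.matrix(~g)[, -1, drop = FALSE]
  Xf <- cbind(Xc, Xg)
  qf <- qr(Xf)
  if (qf$rank < ncol(Xf)) {
    bad <- colnames(Xf)[qf$pivot[(qf$rank + 1):ncol(Xf)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  rss_f <- sum(qr.resid(qf, y)^2)
  rss_r <- sum(qr.resid(qr(Xc), y)^2)
  df1 <- nlevels(g) - 1
  df2 <- N - ncol(Xf)
  if (rss_f <= .Machine$double.eps * max(1, sum(y^2))) {
    f <- if ((rss_r - rss_f) / max(rss_r, 1) < 1e-12) 0 else Inf
    return(morph_test(f, "F", c(df1, df2), if (f == 0) 1 else 0))
  }
  f <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  f <- max(f, 0)
  morph_test(f, "F", c(df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' MANOVA via Wilks' lambda with Rao's F approximation
#'
#' Lambda = det(W) / det(W + B), W and B the within- and between-group
#' scatter matrices of the score columns (here: shape PC scores). The
#' p-value uses Rao's F approximation, exact for up to two variables or up
#' to three groups.
#'
#' @param scores numeric n x p matrix of response variables.
#' @param groups grouping factor of length n.
#' @return `morph_test` with statistic Wilks' lambda, extra field
#'   `approx_F` and its df.
#' @export
wilks_manova <- function(scores, groups) {
  scores <- as.matrix(scores)
  g <- factor(groups)
  n <- nrow(scores); p <- ncol(scores); k <- nlevels(g)
  stopifnot(k >= 2, n > k)
  gm <- rowsum(scores, g) / as.numeric(table(g))
  centered <- scores - gm[g, , drop = FALSE]
  W <- crossprod(centered)
  tot <- scale(scores, scale = FALSE)
  Tm <- crossprod(tot)
  B <- Tm - W
  dW <- determinant(W, logarithm = TRUE)
  dT <- determinant(Tm, logarithm = TRUE)
  if (dW$sign <= 0 || !is.finite(dW$modulus) || qr(W)$rank < p)
    stop("singular within-group covariance; reduce the number of score ",
         "columns (truncate PCs) until nonsingular")
  lambda <- exp(as.numeric(dW$modulus - dT$modulus))
  vh <- k - 1; ve <- n - k
  s <- if (p^2 + vh^2 - 5 > 0) sqrt((p^2 * vh^2 - 4) / (p^2 + vh^2 - 5)) else 1
  m <- ve + vh - (p + vh + 1) / 2
  df1 <- p * vh
  df2 <- m * s - p * vh / 2 + 1
  lam_s <- lambda^(1 / s)
  f <- if (lam_s > 0) (1 - lam_s) / lam_s * df2 / df1 else Inf
  pval <- if (is.finite(f)) stats::pf(f, df1, df2, lower.tail = FALSE) else 0
  if (lambda >= 1 - 1e-12) pval <- 1
  morph_test(lambda, "Wilks", c(df1, df2), pval, approx_F = f)
}

#' Random-intercept mixed model for longitudinal volume
#'
#' Linear mixed model with fixed effects group, time (categorical week) and
#' their interaction, a subject-specific random intercept and i.i.d.
#' residuals (compound symmetry). The single variance ratio is estimated by
#' restricted maximum likelihood (1-D profile optimization); the time and
#' group-by-time effects are Wald F tests under sum-to-zero contrasts with
#' containment denominator degrees of freedom
#' (N_obs - n_subjects - df_time - df_interaction), which reproduces the
#' classical repeated-measures ANOVA error df in the balanced case.
#' Unbalanced designs with missing visits are handled naturally.
#'
#' @param data data.frame with columns `subject`, `group`, `week`, `volume`.
#' @return list with `time` and `group_time` (`morph_test`), plus variance
#'   components `sigma2_subject`, `sigma2_resid`; class `mixed_volume_fit`.
#' @export
mixed_model_volume <- function(data) {
  stopifnot(all(c("subject", "group", "week", "volume") %in% names(data)))
  data <- data[stats::complete.cases(data[c("subject", "group", "week", "volume")]), ]
  subj <- factor(data$subject)
  if (!any(table(subj) >= 2))
    stop("no subject has >= 2 visits; mixed model undefined")
  g <- factor(data$group)
  tm <- factor(data$week)
  if (nlevels(tm) < 2) stop("need >= 2 time points")
  y <- data$volume
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  X <- stats::model.matrix(~ g * tm)
  asg <- attr(X, "assign")      # 0 intercept, 1 group, 2 time, 3 interaction
  ## groups may lack some visit weeks entirely (missing cells): drop the
  ## non-estimable columns, as standard mixed-model software does
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    X <- X[, keep, drop = FALSE]
    asg <- asg[keep]
  }
  N <- length(y)
  p <- ncol(X)
  si <- as.integer(subj)
  ns <- nlevels(subj)
  yscale <- max(1, stats::var(y))

  gls_fit <- function(lambda) {
    ## weights implementing V^-1 = I - lambda/(1+n_i lambda) J per subject
    ni <- tabulate(si, ns)
    shrink <- lambda / (1 + ni * lambda)       # per subject
    sy <- rowsum(y, si, reorder = TRUE)        # subject sums (sorted levels)
    sX <- rowsum(X, si, reorder = TRUE)
    XtVX <- crossprod(X) - crossprod(sX * sqrt(shrink))
    XtVy <- crossprod(X, y) - crossprod(sX * sqrt(shrink), sy * sqrt(shrink))
    ch <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
    r <- y - X %*% beta
    sr <- rowsum(as.numeric(r), si, reorder = TRUE)
    rVr <- sum(r^2) - sum(shrink * sr^2)
    list(beta = beta, rVr = rVr, XtVX = XtVX, chol = ch, ni = ni,
         shrink = shrink)
  }
  reml_neg <- function(loglam) {
    lambda <- exp(loglam)
    ft <- gls_fit(lambda)
    if (is.null(ft) || ft$rVr <= 0) return(1e10)
    ldV <- sum(log(1 + ft$ni * lambda))
    ldX <- 2 * sum(log(diag(ft$chol)))
    0.5 * (ldV + ldX + (N - p) * log(ft$rVr))
  }
  opt <- stats::optimize(reml_neg, c(log(1e-8), log(1e6)))
  lambda <- exp(opt$minimum)
  if (reml_neg(log(1e-8)) <= opt$objective) lambda <- 1e-8  # boundary: no subject variance
  ft <- gls_fit(lambda)
  sigma2 <- ft$rVr / (N - p)
  vbeta <- sigma2 * chol2inv(ft$chol)
  ddf <- N - ns - sum(asg == 2) - sum(asg == 3)
  ## perfect fit (e.g. volumes constant per subject): the Wald ratio is
  ## floating-point noise over floating-point noise — decide on the
  ## coefficients themselves
  perfect <- ft$rVr < max(1e-10 * sum((y - mean(y))^2),
                          1e-16 * sum(y^2), .Machine$double.xmin)
  wald <- function(cols) {
    q <- length(cols)
    b <- ft$beta[cols]
    if (perfect) {
      null_b <- all(abs(b) < 1e-8 * max(1, sqrt(yscale)))
      return(morph_test(if (null_b) 0 else Inf, "F", c(q, ddf),
                        if (null_b) 1 else 0))
    }
    vb <- vbeta[cols, cols, drop = FALSE]
    num <- tryCatch(drop(t(b) %*% solve(vb, b)), error = function(e) NA_real_)
    if (!is.finite(num)) return(morph_test(0, "F", c(q, ddf), 1))
    f <- num / q
    morph_test(f, "F", c(q, ddf), stats::pf(f, q, ddf, lower.tail = FALSE))
  }
  structure(list(time = wald(which(asg == 2)),
                 group_time = wald(which(asg == 3)),
                 sigma2_subject = lambda * sigma2, sigma2_resid = sigma2,
                 n_subjects = ns, n_obs = N),
            class = "mixed_volume_fit")
}

#' @export
print.mixed_volume_fit <- function(x, ...) {
  cat(sprintf("random-intercept mixed model: %d subjects, %d observations\n",
              x$n_subjects, x$n_obs))
  cat(sprintf("  var(subject) = %.4g, var(resid) = %.4g\n",
              x$sigma2_subject, x$sigma2_resid))
  cat("  time        "); print(x$time)
  cat("  group:time  "); print(x$group_time)
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper over the Royston approximation in base R, used as a
#' diagnostic gate before the percentage ANOVAs. A constant sample is
#' degenerate and returns p = 0.
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return `morph_test` (statistic W).
#' @export
shapiro_normality <- function(x) {
  stopifnot(length(x) >= 3, length(x) <= 5000)
  if (stats::sd(x) == 0) return(morph_test(NA_real_, "W", numeric(0), 0))
  sw <- stats::shapiro.test(x)
  morph_test(unname(sw$statistic), "W", numeric(0), sw$p.value)
}

#' Pairwise post hoc comparisons after a one-way ANOVA
#'
#' Fisher's-LSD-style pairwise t-tests using the pooled within-group
#' variance from the ANOVA (df N - k); optional Bonferroni correction.
#' The uncorrected pooled-t default matches how post hoc p-values are most
#' often reported alongside a significant omnibus F.
#'
#' @param values numeric vector.
#' @param groups grouping factor.
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return data.frame with columns `group1`, `group2`, `t`, `df`, `p`.
#' @export
pairwise_posthoc <- function(values, groups, correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  g <- factor(groups)
  lv <- levels(g)
  ng <- table(g)
  usable <- lv[ng >= 2]
  if (length(usable) < length(lv))
    warning("group(s) with n < 2 skipped: ",
            paste(setdiff(lv, usable), collapse = ", "))
  gm <- tapply(values, g, mean)
  N <- sum(ng[usable]); k <- length(usable)
  ssw <- sum(unlist(lapply(usable, function(l)
    sum((values[g == l] - gm[l])^2))))
  df <- N - k
  s2 <- ssw / df
  pairs <- utils::combn(usable, 2)
  res <- apply(pairs, 2, function(pr) {
    a <- pr[1]; b <- pr[2]
    se <- sqrt(s2 * (1 / ng[[a]] + 1 / ng[[b]]))
    tt <- if (se == 0) 0 else (gm[[a]] - gm[[b]]) / se
    p <- if (se == 0) 1 else 2 * stats::pt(-abs(tt), df)
    c(t = tt, p = p)
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    t = res["t", ], df = df, p = res["p", ],
                    stringsAsFactors = FALSE)
  if (correction == "bonferroni") out$p <- pmin(1, out$p * ncol(pairs))
  rownames(out) <- NULL
  out
}
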