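## Cross-sectional (week 0) analyses: volumes, shape PCA + MANOVA,
## vertex-wise displacement maps.

#' Per-subject baseline volumes and covariates
#'
#' @param cohort a `synthetic_cohort`.
#' @return data.frame: subject_id, group, sex, covariates, left_vol,
#'   right_vol (mm^3).
#' @export
baseline_volumes <- function(cohort) {
  md <- cohort$subjects
  has0 <- vapply(md$subject_id,
                 function(id) "0" %in% names(cohort$visits[[id]]), TRUE)
  if (any(!has0)) {
    warning(sum(!has0), " subject(s) without a week-0 mesh excluded")
    md <- md[has0, ]
  }
  md$left_vol <- vapply(md$subject_id, function(id)
    enclosed_volume(subject_mesh(cohort, id, 0, "left")), 0)
  md$right_vol <- vapply(md$subject_id, function(id)
    enclosed_volume(subject_mesh(cohort, id, 0, "right")), 0)
  md
}

#' Baseline volume comparison
#'
#' Repeated-measures ANOVA of left/right week-0 volumes with patient
#' status (PSY = both treatment arms vs CON) as the between factor and
#' hemisphere as the repeated factor, ANCOVA variants adjusting the
#' patient-status effect for sex and for total gray-matter volume, an
#' illness-duration-adjusted comparison of the two treatment arms, and
#' plain per-hemisphere pooled-t comparisons of the arms.
#'
#' @param cohort a `synthetic_cohort`.
#' @param volumes optional precomputed [baseline_volumes()] table.
#' @return list of results (class `baseline_volume_analysis`): `volumes`,
#'   `rm_anova` (PSY vs CON), `ancova_sex`, `ancova_gray_matter`,
#'   `ancova_illness` (OLZ vs HAL), `olz_vs_hal` (per-hemisphere t).
#' @export
baseline_volume_analysis <- function(cohort, volumes = NULL) {
  bv <- if (is.null(volumes)) baseline_volumes(cohort) else volumes
  status <- factor(ifelse(bv$group == "CON", "CON", "PSY"),
                   levels = c("CON", "PSY"))
  rm <- rm_anova_group_hemisphere(bv$left_vol, bv$right_vol, status)
  mvol <- (bv$left_vol + bv$right_vol) / 2
  anc_sex <- ancova(mvol, status, as.numeric(bv$sex == "M"))
  anc_gm <- ancova(mvol, status, bv$gray_matter_volume_mm3)
  pat <- bv[bv$group != "CON", ]
  anc_ill <- if (nrow(pat) && !all(is.na(pat$illness_duration_weeks)))
    ancova((pat$left_vol + pat$right_vol) / 2, factor(pat$group),
           pat$illness_duration_weeks) else NULL
  ph_l <- pairwise_posthoc(pat$left_vol, factor(pat$group))
  ph_r <- pairwise_posthoc(pat$right_vol, factor(pat$group))
  structure(list(volumes = bv, rm_anova = rm, ancova_sex = anc_sex,
                 ancova_gray_matter = anc_gm, ancova_illness = anc_ill,
                 olz_vs_hal = list(left = ph_l, right = ph_r)),
            class = "baseline_volume_analysis")
}

#' @export
print.baseline_volume_analysis <- function(x, ...) {
  bv <- x$volumes
  st <- ifelse(bv$group == "CON", "CON", "PSY")
  for (s in unique(st)) {
    sel <- st == s
    cat(sprintf("  %s: left %.0f (%.0f), right %.0f (%.0f) mm^3 [n=%d]\n", s,
                mean(bv$left_vol[sel]), stats::sd(bv$left_vol[sel]),
                mean(bv$right_vol[sel]), stats::sd(bv$right_vol[sel]),
                sum(sel)))
  }
  print(x$rm_anova)
  cat("  group | sex       "); print(x$ancova_sex)
  cat("  group | gray mat. "); print(x$ancova_gray_matter)
  invisible(x)
}

#' Shape PCA of corresponded baseline surfaces
#'
#' Each subject's week-0 surface (one hemisphere) is flattened to a 3V
#' vector; the grand mean is subtracted and principal components are
#' computed by singular value decomposition. Scores are the centered data
#' projected on the components.
#'
#' @param cohort a `synthetic_cohort`.
#' @param hemisphere `"left"` or `"right"`.
#' @param K number of components to retain (default 20, truncated with a
#'   warning to n - 1 if fewer subjects).
#' @return `shape_pca` object: `mean_surface` (V x 3), `components`
#'   (K x 3V, orthonormal rows), `explained_variance_fraction`, `scores`
#'   (subjects x K), `subjects`, `hemisphere`.
#' @export
shape_pca <- function(cohort, hemisphere = c("left", "right"), K = 20) {
  hemisphere <- match.arg(hemisphere)
  md <- cohort$subjects
  stopifnot(nrow(md) >= 3)
  X <- t(vapply(md$subject_id, function(id)
    as.numeric(t(cohort$visits[[id]][["0"]][[hemisphere]])),
    numeric(3 * nrow(cohort$template[[hemisphere]]$vertices))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  n <- nrow(X)
  if (K > n - 1) {
    warning("K reduced from ", K, " to n-1 = ", n - 1)
    K <- n - 1
  }
  sv <- svd(Xc, nu = 0, nv = K)
  varfrac <- (sv$d^2 / sum(sv$d^2))[seq_len(K)]
  scores <- Xc %*% sv$v
  colnames(scores) <- paste0("PC", seq_len(K))
  structure(list(hemisphere = hemisphere,
                 mean_surface = matrix(mu, ncol = 3, byrow = TRUE),
                 components = t(sv$v),
                 explained_variance_fraction = varfrac,
                 scores = scores,
                 subjects = md$subject_id,
                 groups = md$group),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("shape_pca (%s): %d subjects, %d components, %.1f%% variance\n",
              x$hemisphere, nrow(x$scores), ncol(x$scores),
              100 * sum(x$explained_variance_fraction)))
  invisible(x)
}

#' MANOVA on shape PC scores
#'
#' Wilks' lambda comparison of the PC score vectors across groups,
#' optionally after residualizing the scores on covariates (the covariate
#' adjustment used for sex / illness-duration control).
#'
#' @param pca a [shape_pca()] model.
#' @param groups grouping factor aligned with the PCA subjects (default:
#'   the cohort groups stored in the model).
#' @param covariates optional numeric vector/matrix to residualize on.
#' @return `morph_test` (Wilks).
#' @export
shape_manova <- function(pca, groups = NULL, covariates = NULL) {
  if (is.null(groups)) groups <- pca$groups
  sc <- pca$scores
  k <- nlevels(factor(groups))
  pmax_ok <- nrow(sc) - k - 1
  if (ncol(sc) > pmax_ok) {
    warning("scores truncated from ", ncol(sc), " to ", pmax_ok,
            " columns to keep the within-group scatter nonsingular")
    sc <- sc[, seq_len(pmax_ok), drop = FALSE]
  }
  if (!is.null(covariates)) {
    q <- qr(cbind(1, as.matrix(covariates)))
    sc <- qr.resid(q, sc)
  }
  wilks_manova(sc, groups)
}

#' Vertex-wise baseline displacement comparison
#'
#' Scalar per-vertex displacement of each subject's week-0 surface from the
#' template, projected on the outward template normal (positive = outward);
#' hemispheres are concatenated left-then-right. Groups are compared per
#' vertex with the Mann-Whitney U test and the p-value map is thresholded
#' by Benjamini-Hochberg FDR.
#'
#' @param cohort a `synthetic_cohort`.
#' @param group_a,group_b group labels; `"PSY"` pools OLZ and HAL.
#' @param q FDR level (default 0.05).
#' @return `displacement_map`: `displacement` (mean A - mean B, mm), `p`,
#'   `fdr_mask`, `V_left`, plus per-group subject displacement matrices.
#' @export
vertex_displacement_map <- function(cohort, group_a = "PSY", group_b = "CON",
                                    q = 0.05) {
  D <- baseline_displacements(cohort)
  sel_a <- pick_group(cohort$subjects$group, group_a)
  sel_b <- pick_group(cohort$subjects$group, group_b)
  stopifnot(any(sel_a), any(sel_b))
  A <- D[sel_a, , drop = FALSE]
  B <- D[sel_b, , drop = FALSE]
  p <- vapply(seq_len(ncol(D)), function(j)
    mann_whitney_u(A[, j], B[, j])$p_value, 0)
  fdr <- bh_fdr(p, q)
  structure(list(displacement = colMeans(A) - colMeans(B), p = p,
                 fdr_mask = fdr$rejected, p_threshold = fdr$p_threshold,
                 q = q, V_left = nrow(cohort$template$left$vertices),
                 groups = c(group_a, group_b)),
            class = "displacement_map")
}

#' @export
print.displacement_map <- function(x, ...) {
  cat(sprintf("displacement_map %s vs %s: mean %.3f mm, %d/%d vertices FDR-significant (q=%.2g)\n",
              x$groups[1], x$groups[2], mean(x$displacement),
              sum(x$fdr_mask), length(x$fdr_mask), x$q))
  invisible(x)
}

pick_group <- function(groups, label) {
  if (label == "PSY") groups %in% c("OLZ", "HAL") else groups == label
}

## subjects x 2V matrix of signed template-normal displacements at week 0
baseline_displacements <- function(cohort) {
  ctx <- template_context(cohort$template)
  md <- cohort$subjects
  t(vapply(md$subject_id, function(id) {
    unlist(lapply(c("left", "right"), function(h) {
      vm <- cohort$visits[[id]][["0"]][[h]]
      rowSums((vm - cohort$template[[h]]$vertices) * ctx$normals[[h]])
    }), use.names = FALSE)
  }, numeric(2 * ctx$V)))
}

#' Export a baseline displacement map as a VTK surface
#'
#' Writes one hemisphere of the map onto the template geometry with three
#' scalar fields: signed displacement, -log10 p, and the FDR mask.
#'
#' @param cohort a `synthetic_cohort`.
#' @param map a [vertex_displacement_map()] result.
#' @param hemisphere `"left"` or `"right"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_displacement_surface <- function(cohort, map, hemisphere, path) {
  idx <- if (hemisphere == "left") seq_len(map$V_left)
  else map$V_left + seq_len(length(map$p) - map$V_left)
  write_surface(cohort$template[[hemisphere]], path,
                scalars = list(displacement = map$displacement[idx],
                               neg_log10_p = -log10(pmax(map$p[idx], 1e-300)),
                               fdr_mask = as.numeric(map$fdr_mask[idx])),
                digits = 9)
}
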