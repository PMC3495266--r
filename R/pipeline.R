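## Configuration-driven end-to-end runner: generate/load a cohort, run the
## baseline and longitudinal stages, emit CSV/VTK outputs + a JSON manifest.

#' Pipeline run configuration
#'
#' @param cohort a [cohort_config()] describing the cohort to generate, or
#'   `NULL` when loading from disk.
#' @param load path to a dataset directory written by [write_cohort()]
#'   (overrides `cohort`).
#' @param stages character subset of `c("baseline", "longitudinal")`.
#' @param q FDR level for vertex-wise maps.
#' @param threshold_method method for [control_thresholds()].
#' @param display_range slope display clamp, mm/year.
#' @param seed optional override of the cohort seed.
#' @param subject_maps write one VTK slope map per subject (off by default;
#'   the group mean maps are always written).
#' @return a `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(), load = NULL,
                       stages = c("baseline", "longitudinal"),
                       q = 0.05,
                       threshold_method = c("mean_map", "pooled_vertices",
                                            "subject_means"),
                       display_range = 0.1, seed = NULL,
                       subject_maps = FALSE) {
  stopifnot(q > 0, q < 1, all(stages %in% c("baseline", "longitudinal")))
  threshold_method <- match.arg(threshold_method)
  if (!is.null(seed) && !is.null(cohort)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, load = load, stages = stages, q = q,
                 threshold_method = threshold_method,
                 display_range = display_range,
                 subject_maps = subject_maps),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors [run_config()]; a `cohort:` block mirrors
#' [cohort_config()] fields (named vectors as mappings).
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cc <- cohort_config()
  if (!is.null(y$cohort)) {
    for (nm in names(y$cohort)) {
      if (!nm %in% names(cc)) stop("unknown cohort config field: ", nm)
      val <- y$cohort[[nm]]
      if (is.list(val) && !nm %in% c("retention", "illness_lognormal"))
        val <- unlist(val)
      if (nm %in% c("retention", "illness_lognormal"))
        val <- lapply(val, unlist)
      if (nm %in% c("group_sizes", "template_resolution", "smooth_iters",
                    "seed"))
        val <- setNames(as.integer(val), names(val))
      cc[[nm]] <- val
    }
    class(cc) <- "cohort_config"
  }
  args <- y[setdiff(names(y), "cohort")]
  do.call(run_config, c(list(cohort = cc), args))
}

log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

tests_to_df <- function(named_tests) {
  do.call(rbind, lapply(names(named_tests), function(nm) {
    tst <- named_tests[[nm]]
    if (is.null(tst)) return(NULL)
    data.frame(test = nm, statistic_name = tst$statistic_name,
               statistic = tst$statistic,
               df1 = if (length(tst$df) >= 1) tst$df[1] else NA,
               df2 = if (length(tst$df) >= 2) tst$df[2] else NA,
               p = tst$p_value, stringsAsFactors = FALSE)
  }))
}

write_csv_stable <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the cohort, validates mesh correspondence, runs the
#' requested stages and writes all tables and maps plus a machine-readable
#' `manifest.json` listing every output file with its MD5 checksum.
#' Identical config and seed reproduce byte-identical outputs. On stage
#' failure, outputs written so far are retained next to a `.partial`
#' marker file.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (list with `files`, `summary`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, ".partial")
  file.create(marker)
  files <- character()
  add <- function(path) files <<- c(files, path)
  stage <- "generate"
  res <- try({
    if (!is.null(config$load)) {
      log_msg("loading cohort from ", config$load)
      cohort <- read_cohort(config$load)
    } else {
      log_msg("generating cohort (seed ", config$cohort$seed, ")")
      cohort <- generate_cohort(config$cohort)
    }
    stage <- "validate"
    check_ids <- utils::head(cohort$subjects$subject_id, 10)
    for (h in c("left", "right")) {
      ms <- c(list(template = cohort$template[[h]]),
              stats::setNames(lapply(check_ids, function(id)
                subject_mesh(cohort, id, 0, h)), check_ids))
      repc <- validate_correspondence(ms)
      if (!repc$ok) stop("correspondence check failed (", h, " hemisphere)")
    }
    summary_info <- list(
      groups = as.list(table(cohort$subjects$group)),
      n_vertices = 2L * nrow(cohort$template$left$vertices))

    if ("baseline" %in% config$stages) {
      stage <- "baseline"
      log_msg("baseline stage")
      bva <- baseline_volume_analysis(cohort)
      add(write_csv_stable(
        bva$volumes, file.path(out_dir, "baseline_volumes.csv")))
      btests <- c(
        list(group_rm = bva$rm_anova$group,
             hemisphere_rm = bva$rm_anova$hemisphere,
             group_x_hemisphere_rm = bva$rm_anova$interaction,
             group_adj_sex = bva$ancova_sex,
             group_adj_gray_matter = bva$ancova_gray_matter,
             olz_vs_hal_adj_illness = bva$ancova_illness))
      pcas <- list()
      for (h in c("left", "right")) {
        pca <- shape_pca(cohort, h)
        pcas[[h]] <- pca
        status <- factor(ifelse(pca$groups == "CON", "CON", "PSY"))
        btests[[paste0("shape_manova_", h)]] <- shape_manova(pca, status)
        sc <- as.data.frame(pca$scores)
        sc <- cbind(subject_id = pca$subjects, sc)
        add(write_csv_stable(sc, file.path(out_dir,
                                           sprintf("pca_%s_scores.csv", h))))
        add(write_csv_stable(
          data.frame(component = seq_along(pca$explained_variance_fraction),
                     explained_variance_fraction =
                       pca$explained_variance_fraction),
          file.path(out_dir, sprintf("pca_%s_varfrac.csv", h))))
      }
      dmap <- vertex_displacement_map(cohort, "PSY", "CON", q = config$q)
      for (h in c("left", "right")) {
        pth <- file.path(out_dir, sprintf("baseline_map_%s.vtk", h))
        export_displacement_surface(cohort, dmap, h, pth)
        add(pth)
      }
      add(write_csv_stable(tests_to_df(btests),
                           file.path(out_dir, "baseline_tests.csv")))
      summary_info$baseline <- list(
        group_F = bva$rm_anova$group$statistic,
        group_p = bva$rm_anova$group$p_value,
        fdr_significant_vertices = sum(dmap$fdr_mask))
    }

    if ("longitudinal" %in% config$stages) {
      stage <- "longitudinal"
      log_msg("longitudinal stage")
      vsa <- volume_slope_analysis(cohort)
      add(write_csv_stable(vsa$slopes,
                           file.path(out_dir, "volume_slopes.csv")))
      maps <- subject_slope_maps(cohort)
      thr <- control_thresholds(maps, method = config$threshold_method)
      summ <- summarize_slopes(maps, thr)
      add(write_csv_stable(summ,
                           file.path(out_dir, "slope_summaries.csv")))
      cmp <- compare_percentages(summ)
      ptests <- list(
        volume_slope_group = vsa$rm_anova$group,
        volume_slope_hemisphere = vsa$rm_anova$hemisphere,
        volume_slope_interaction = vsa$rm_anova$interaction,
        mixed_time_left = vsa$mixed$left$time,
        mixed_group_time_left = vsa$mixed$left$group_time,
        mixed_time_right = vsa$mixed$right$time,
        mixed_group_time_right = vsa$mixed$right$group_time)
      for (mt in names(cmp)) {
        ptests[[paste0(mt, "_anova")]] <- cmp[[mt]]$anova
        if (!is.null(cmp[[mt]]$rm_anova)) {
          ptests[[paste0(mt, "_rm_group")]] <- cmp[[mt]]$rm_anova$group
          ptests[[paste0(mt, "_rm_interaction")]] <-
            cmp[[mt]]$rm_anova$interaction
        }
      }
      ptdf <- tests_to_df(ptests)
      add(write_csv_stable(ptdf,
                           file.path(out_dir, "percentage_tests.csv")))
      ph <- do.call(rbind, lapply(names(cmp), function(mt) {
        if (is.null(cmp[[mt]]$posthoc)) return(NULL)
        cbind(metric = mt, cmp[[mt]]$posthoc)
      }))
      if (!is.null(ph))
        add(write_csv_stable(ph, file.path(out_dir, "posthoc_tests.csv")))
      add(write_csv_stable(
        data.frame(method = thr$method, mean = thr$mean, sd = thr$sd,
                   lower = thr$lower, upper = thr$upper),
        file.path(out_dir, "thresholds.csv")))
      groups <- unique(maps$subjects$group)
      for (gr in groups) {
        mm <- group_mean_slope_map(maps, maps$subjects$group == gr, gr)
        add(write_csv_stable(slope_cdf(mm),
                             file.path(out_dir, sprintf("cdf_%s.csv", gr))))
        for (h in c("left", "right")) {
          pth <- file.path(out_dir, sprintf("group_mean_%s_%s.vtk", gr, h))
          export_slope_surface(cohort$template, mm, h, pth,
                               config$display_range)
          add(pth)
        }
      }
      if (config$subject_maps) {
        sdir <- file.path(out_dir, "slope_maps")
        dir.create(sdir, showWarnings = FALSE)
        for (i in seq_len(nrow(maps$slopes))) {
          id <- maps$subjects$subject_id[i]
          sm <- structure(maps$slopes[i, ], V_left = maps$V_left,
                          class = "slope_map")
          for (h in c("left", "right")) {
            pth <- file.path(sdir, sprintf("%s_%s.vtk", id, h))
            export_slope_surface(cohort$template, sm, h, pth,
                                 config$display_range)
            add(pth)
          }
        }
      }
      if (all(c("HAL", "OLZ") %in% groups)) {
        vt <- vertexwise_slope_test(maps, "HAL", "OLZ", q = config$q)
        for (h in c("left", "right")) {
          idx <- if (h == "left") seq_len(vt$V_left)
          else (vt$V_left + 1):length(vt$p)
          pth <- file.path(out_dir, sprintf("vertexwise_HAL_vs_OLZ_%s.vtk", h))
          write_surface(cohort$template[[h]], pth,
                        scalars = list(mean_diff = vt$mean_diff[idx],
                                       p = vt$p[idx],
                                       fdr_mask = as.numeric(vt$fdr_mask[idx])),
                        digits = 9)
          add(pth)
        }
        summary_info$longitudinal <- list(
          vertexwise_HAL_OLZ_rejections = sum(vt$fdr_mask),
          pct_very_negative_anova_p = cmp$pct_very_negative$anova$p_value)
      }
    }
    summary_info
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    stop("pipeline stage '", stage, "' failed: ",
         attr(res, "condition")$message)
  }
  manifest <- list(
    package = "hippomorph",
    stages = config$stages,
    q = config$q,
    threshold_method = config$threshold_method,
    seed = if (!is.null(config$cohort)) config$cohort$seed else NA,
    summary = res,
    files = lapply(files, function(f) list(
      path = sub(paste0("^", out_dir, "/?"), "", f),
      md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  unlink(marker)
  log_msg("done: ", length(files), " output files in ", out_dir)
  invisible(manifest)
}

#' Human-readable summary of a pipeline run
#'
#' Renders group demographics, volume and percentage test results and a
#' three-group table of the percentage metrics (mean (SD), 1 decimal) from
#' a run's output directory.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @return the rendered lines, invisibly.
#' @export
report_run <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path)
  out_dir <- dirname(manifest_path)
  for (f in man$files) {
    pth <- file.path(out_dir, f$path)
    if (!file.exists(pth)) stop("manifest references missing file: ", f$path)
  }
  lines <- c("hippomorph run report", strrep("=", 40))
  lines <- c(lines, paste0("stages: ", paste(unlist(man$stages),
                                             collapse = ", ")),
             paste0("groups: ", paste(sprintf("%s=%s",
                                              names(man$summary$groups),
                                              unlist(man$summary$groups)),
                                      collapse = " ")))
  read_if <- function(name) {
    p <- file.path(out_dir, name)
    if (!file.exists(p)) return(NULL)
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    ## a column holding only "F" statistics parses as logical FALSE
    if (is.logical(df$statistic_name))
      df$statistic_name <- ifelse(df$statistic_name, "T", "F")
    df
  }
  bt <- read_if("baseline_tests.csv")
  if (!is.null(bt)) {
    lines <- c(lines, "", "baseline tests:")
    lines <- c(lines, sprintf("  %-24s %s(%g, %g) = %.2f, p = %.3g",
                              bt$test, bt$statistic_name, bt$df1, bt$df2,
                              bt$statistic, bt$p))
  }
  ss <- read_if("slope_summaries.csv")
  if (!is.null(ss)) {
    lines <- c(lines, "", "surface slope percentages (mean (SD)):")
    grp <- sort(unique(ss$group))
    for (mt in c("pct_negative", "pct_very_negative", "pct_very_positive")) {
      for (h in c("left", "right")) {
        col <- paste0(mt, "_", h)
        vals <- vapply(grp, function(g) {
          x <- ss[[col]][ss$group == g]
          sprintf("%.1f (%.1f)", mean(x), stats::sd(x))
        }, "")
        lines <- c(lines, sprintf("  %-28s %s", paste(mt, h),
                                  paste(sprintf("%s=%s", grp, vals),
                                        collapse = "  ")))
      }
    }
  }
  pt <- read_if("percentage_tests.csv")
  if (!is.null(pt)) {
    lines <- c(lines, "", "longitudinal tests:")
    lines <- c(lines, sprintf("  %-28s %s(%g, %g) = %.2f, p = %.3g",
                              pt$test, pt$statistic_name, pt$df1, pt$df2,
                              pt$statistic, pt$p))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
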