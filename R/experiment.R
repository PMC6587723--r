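# Group-level experiment runner: all 16 pipelines x measures over a
# synthetic (or user-supplied) group, with summaries, marginal effects,
# surrogate controls and test-retest variance.

#' Run the full preprocessing experiment on a group
#'
#' Generates (or takes) a multi-subject group, executes all sixteen
#' combinations of the nuisance regressor blocks for every subject, and
#' summarises the group-level statistics per pipeline and measure:
#'
#' * one-sample t maps across subjects (first session) and their GM-masked
#'   mean,
#' * the GM mean of the voxelwise percent change of t relative to the
#'   no-regression pipeline,
#' * test-retest variance across sessions (when the group has two or more)
#'   and its percent change vs no regression,
#' * optionally, the same t-change under phase-randomised surrogate
#'   regressors (averaged over repetitions), the control for "more
#'   regressors help by chance",
#' * a marginal-effect table: for each block, the mean GM t change over the
#'   eight pipeline pairs differing only in that block.
#'
#' @param config a [simulation_config()] or a pre-generated
#'   [generate_group()] result.
#' @param output_dir if non-`NULL`, write `summary.tsv`,
#'   `marginal_effects.tsv`, `report.txt` and `provenance.json` there
#'   (and the group t maps as NIfTI when `write_maps = TRUE`).
#' @param detrend_mode `"polynomial"` or `"exploratory"` detrending used by
#'   the `Detr` block in all pipelines that include it.
#' @param measures subset of `c("alff", "falff", "hfalff")`.
#' @param fwhm_mm smoothing FWHM in mm.
#' @param include_surrogate also run every non-empty pipeline with
#'   phase-randomised regressors (`n_surrogate` repetitions each; slower).
#' @param n_surrogate surrogate repetitions (default 25).
#' @param write_maps write per-pipeline group t maps as NIfTI.
#' @param verbose log one line per pipeline to `message()`.
#' @return An object of class `lff_experiment`: list with `summary` and
#'   `marginal` data frames, `surrogate` data frame (or `NULL`), `t_maps`
#'   (nested list pipeline -> measure), `gm_mask`, `config`.
#' @export
run_experiment <- function(config, output_dir = NULL,
                           detrend_mode = c("polynomial", "exploratory"),
                           measures = c("alff", "falff", "hfalff"),
                           fwhm_mm = 6, include_surrogate = FALSE,
                           n_surrogate = 25L, write_maps = FALSE,
                           verbose = FALSE) {
  detrend_mode <- match.arg(detrend_mode)
  group <- if (inherits(config, "subject_group")) config
           else generate_group(config)
  cfg <- group$config
  n_sub <- cfg$n_subjects
  n_ses <- cfg$n_sessions
  say <- function(...) if (verbose) message(sprintf(...))

  first <- group$subjects[[1]][[1]]
  masks <- first$masks
  brain <- masks$gm | masks$wm | masks$csf
  gm <- masks$gm
  tr <- cfg$tr_seconds
  band <- cfg$lff_band
  vox <- cfg$voxel_size_mm

  # Per-dataset preparation: in-brain time courses and regressor blocks.
  say("preparing %d datasets (%d subjects x %d sessions)", n_sub * n_ses,
      n_sub, n_ses)
  prep <- lapply(seq_len(n_sub), function(i) {
    lapply(seq_len(n_ses), function(r) {
      ds <- group$subjects[[i]][[r]]
      list(tc = .mask_timecourses(ds$bold, brain),
           blocks = prepare_blocks(ds, detrend_mode = detrend_mode))
    })
  })

  specs <- enumerate_pipelines(detrend_mode = detrend_mode,
                               measures = measures)
  labels <- names(specs)

  run_real <- function(spec, i, r) {
    .execute_pipeline(prep[[i]][[r]]$tc, prep[[i]][[r]]$blocks, spec,
                      tr, band, brain, fwhm_mm, vox)
  }

  # --- real pipelines ------------------------------------------------------
  t_maps <- list()
  retest_gm <- list()
  summary_rows <- list()
  session_maps_store <- list()
  for (lab in labels) {
    spec <- specs[[lab]]
    t0 <- Sys.time()
    all_maps <- lapply(seq_len(n_sub), function(i)
      lapply(seq_len(n_ses), function(r) run_real(spec, i, r)))
    t_maps[[lab]] <- lapply(measures, function(m)
      one_sample_t(lapply(all_maps, function(s) s[[1]][[m]]), mask = brain))
    names(t_maps[[lab]]) <- measures
    if (n_ses >= 2L) {
      retest_gm[[lab]] <- vapply(measures, function(m) {
        vm <- test_retest_variance(lapply(all_maps, function(s)
          lapply(s, `[[`, m)), mask = brain)
        masked_mean(vm, gm)$mean
      }, 0)
    }
    say("pipeline %-14s done in %.1f s", lab,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  gm_t <- function(lab, m) masked_mean(t_maps[[lab]][[m]], gm)$mean
  pct_gm <- function(lab, m) {
    if (lab == "none") return(0)
    masked_mean(percent_change(t_maps[[lab]][[m]], t_maps[["none"]][[m]]),
                gm)$mean
  }

  summary <- do.call(rbind, lapply(labels, function(lab) {
    do.call(rbind, lapply(measures, function(m) {
      data.frame(pipeline = lab, measure = m,
                 gm_mean_t = gm_t(lab, m),
                 pct_change_vs_none = pct_gm(lab, m),
                 retest_var_gm = if (n_ses >= 2L) retest_gm[[lab]][[m]]
                                 else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (n_ses >= 2L) {
    base_var <- summary[summary$pipeline == "none", ]
    summary$retest_var_pct_change <- vapply(seq_len(nrow(summary)),
      function(k) {
        b <- base_var$retest_var_gm[base_var$measure == summary$measure[k]]
        100 * (summary$retest_var_gm[k] - b) / b
      }, 0)
  } else {
    summary$retest_var_pct_change <- NA_real_
  }

  # --- marginal effect of each block ---------------------------------------
  marginal <- do.call(rbind, lapply(.BLOCK_NAMES, function(block) {
    flag <- paste0("use_", block)
    without <- labels[!vapply(specs, `[[`, TRUE, flag)]
    do.call(rbind, lapply(measures, function(m) {
      changes <- vapply(without, function(lab0) {
        spec1 <- specs[[lab0]]
        spec1[[flag]] <- TRUE
        lab1 <- pipeline_label(spec1)
        masked_mean(percent_change(t_maps[[lab1]][[m]],
                                   t_maps[[lab0]][[m]]), gm)$mean
      }, 0)
      data.frame(block = block, measure = m,
                 mean_t_pct_change = mean(changes),
                 n_pairs = length(changes), stringsAsFactors = FALSE)
    }))
  }))

  # --- surrogate control ---------------------------------------------------
  surrogate <- NULL
  if (include_surrogate) {
    sur_labels <- setdiff(labels, "none")
    surrogate <- do.call(rbind, lapply(sur_labels, function(lab) {
      spec <- specs[[lab]]
      spec$surrogate <- TRUE
      t0 <- Sys.time()
      per_subj <- lapply(seq_len(n_sub), function(i)
        .execute_pipeline(prep[[i]][[1]]$tc, prep[[i]][[1]]$blocks, spec,
                          tr, band, brain, fwhm_mm, vox,
                          n_surrogate = n_surrogate))
      rows <- do.call(rbind, lapply(measures, function(m) {
        pct_reps <- vapply(seq_len(n_surrogate), function(k) {
          tk <- one_sample_t(lapply(per_subj, function(s) s[[m]][[k]]),
                             mask = brain)
          masked_mean(percent_change(tk, t_maps[["none"]][[m]]), gm)$mean
        }, 0)
        data.frame(pipeline = lab, measure = m,
                   surrogate_pct_change = mean(pct_reps),
                   n_repetitions = n_surrogate, stringsAsFactors = FALSE)
      }))
      say("surrogate %-14s done in %.1f s", lab,
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
      rows
    }))
  }

  result <- structure(list(summary = summary, marginal = marginal,
                           surrogate = surrogate, t_maps = t_maps,
                           gm_mask = gm, brain_mask = brain, config = cfg,
                           detrend_mode = detrend_mode,
                           measures = measures, fwhm_mm = fwhm_mm),
                      class = "lff_experiment")
  if (!is.null(output_dir))
    write_experiment(result, output_dir, write_maps = write_maps)
  result
}

#' @export
print.lff_experiment <- function(x, ...) {
  cat(sprintf("<lff_experiment> %d pipelines x %s, %d subjects (%s detrending)\n",
              length(x$t_maps), paste(x$measures, collapse = "/"),
              x$config$n_subjects, x$detrend_mode))
  full <- x$summary[x$summary$pipeline == "detr+wm+csf+rp", ]
  for (k in seq_len(nrow(full)))
    cat(sprintf("  full regression, %s: GM t change %+.1f%% vs none\n",
                full$measure[k], full$pct_change_vs_none[k]))
  invisible(x)
}

#' Write an experiment's tables, report and (optionally) maps
#'
#' @param experiment an `lff_experiment` from [run_experiment()].
#' @param output_dir directory (created if needed).
#' @param write_maps also write the per-pipeline group t maps as NIfTI.
#' @return `output_dir`, invisibly.
#' @export
write_experiment <- function(experiment, output_dir, write_maps = FALSE) {
  stopifnot(inherits(experiment, "lff_experiment"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) write.table(
    df, file.path(output_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tsv(experiment$summary, "summary.tsv")
  tsv(experiment$marginal, "marginal_effects.tsv")
  if (!is.null(experiment$surrogate))
    tsv(experiment$surrogate, "surrogate_effects.tsv")
  jsonlite::write_json(
    list(package = "lffpipe",
         version = as.character(utils::packageVersion("lffpipe")),
         config = unclass(experiment$config),
         detrend_mode = experiment$detrend_mode,
         fwhm_mm = experiment$fwhm_mm),
    file.path(output_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  lines <- c("Low-frequency fluctuation preprocessing experiment",
             sprintf("%d subjects x %d sessions, N = %d, TR = %g s, seed %d",
                     experiment$config$n_subjects,
                     experiment$config$n_sessions,
                     experiment$config$n_timepoints,
                     experiment$config$tr_seconds,
                     experiment$config$rng_seed),
             sprintf("detrending mode: %s; smoothing %g mm; band %g-%g Hz",
                     experiment$detrend_mode, experiment$fwhm_mm,
                     experiment$config$lff_band[1],
                     experiment$config$lff_band[2]),
             "",
             "GM-mean group t change vs no regression (percent):")
  for (m in experiment$measures) {
    s <- experiment$summary[experiment$summary$measure == m, ]
    lines <- c(lines, sprintf("  %s:", m),
               sprintf("    %-14s %+7.2f%%", s$pipeline,
                       s$pct_change_vs_none))
  }
  lines <- c(lines, "", "Marginal effect of each block (mean over 8 pairs):")
  for (k in seq_len(nrow(experiment$marginal)))
    lines <- c(lines, sprintf("  %-5s on %-6s %+7.2f%%",
                              experiment$marginal$block[k],
                              experiment$marginal$measure[k],
                              experiment$marginal$mean_t_pct_change[k]))
  writeLines(lines, file.path(output_dir, "report.txt"))

  if (write_maps) {
    map_dir <- file.path(output_dir, "t_maps")
    dir.create(map_dir, showWarnings = FALSE)
    for (lab in names(experiment$t_maps)) {
      for (m in names(experiment$t_maps[[lab]])) {
        write_stat_map(experiment$t_maps[[lab]][[m]],
                       file.path(map_dir, sprintf("t_%s_%s.nii",
                                                  gsub("\\+", "_", lab), m)),
                       voxel_size_mm = experiment$config$voxel_size_mm,
                       pipeline = lab)
      }
    }
  }
  invisible(output_dir)
}
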