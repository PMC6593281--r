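#' The 116-region AAL parcellation table
#'
#' Index, name, abbreviation, hemisphere (`L`/`R`/`M` for midline vermis)
#' and division for the 116-region anatomical parcellation: 90 cerebral and
#' 26 cerebellar/vermis regions.
#'
#' @return `data.frame` with 116 rows.
#' @export
aal116_table <- function() {
  utils::read.csv(system.file("extdata", "aal116.csv", package = "fctopo"),
                  stringsAsFactors = FALSE)
}

#' Pipeline run configuration
#'
#' Collects every tunable constant of the pipeline. Defaults are the
#' standard settings for a TR = 2 s resting-state acquisition: drop 10
#' volumes, band-pass 0.01-0.08 Hz, sparsity grid 0.05-0.50 step 0.01,
#' 100 degree-preserving nulls with 10 swaps per edge, Welch tests,
#' Bonferroni within each nodal metric across regions.
#'
#' @param grid_from,grid_to,grid_by sparsity grid bounds and step.
#' @param n_nulls,swaps_per_edge null-ensemble settings.
#' @param band length-2 band-pass edges in Hz (or `NULL` to skip).
#' @param tr repetition time in seconds.
#' @param drop_volumes leading volumes to discard.
#' @param ranking edge ranking (`"signed"` or `"absolute"`).
#' @param covariates manifest columns adjusted for in group comparisons.
#' @param alpha significance level.
#' @param nodal compute nodal metrics and their group tests.
#' @param seed global integer seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(grid_from = 0.05, grid_to = 0.5, grid_by = 0.01,
                       n_nulls = 100L, swaps_per_edge = 10L,
                       band = c(0.01, 0.08), tr = 2, drop_volumes = 10L,
                       ranking = "signed",
                       covariates = c("sex", "age", "education", "bmi"),
                       alpha = 0.05, nodal = TRUE, seed = 1L) {
  grid <- sparsity_grid(grid_from, grid_to, grid_by)
  stopifnot(tr > 0, drop_volumes >= 0, alpha > 0, alpha < 1)
  ranking <- match.arg(ranking, c("signed", "absolute"))
  structure(list(grid = grid, n_nulls = as.integer(n_nulls),
                 swaps_per_edge = swaps_per_edge, band = band, tr = tr,
                 drop_volumes = as.integer(drop_volumes), ranking = ranking,
                 covariates = covariates, alpha = alpha, nodal = nodal,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  vals <- yaml::yaml.load_file(path)
  if (!is.null(vals$band)) vals$band <- as.numeric(vals$band)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config a [run_config].
#' @export
write_run_config <- function(config, path) {
  vals <- unclass(config)
  vals$grid_from <- min(vals$grid)
  vals$grid_to <- max(vals$grid)
  vals$grid_by <- if (length(vals$grid) > 1) vals$grid[2] - vals$grid[1] else 0.01
  vals$grid <- NULL
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Run the whole-brain network analysis pipeline
#'
#' For every subject in the manifest: read the time series, clean it (drop,
#' detrend, band-pass), build the Pearson connectivity matrix, threshold it
#' across the sparsity grid, compute raw/normalized global and nodal
#' metrics and their AUCs. Then compare groups on the 5 global AUCs (gamma,
#' lambda, sigma, e_loc, e_glob) and on each nodal-metric AUC per region
#' — unadjusted Welch tests plus covariate-adjusted linear-model tests with
#' Bonferroni correction — and compute partial correlations between
#' configured score columns and nodal AUCs within the patient group.
#'
#' @param manifest cohort manifest `data.frame` (see [generate_cohort]),
#'   with columns `subject_id`, `group` (`"patient"`/`"control"`), the
#'   covariates named in `config$covariates`, optional score columns, and
#'   `file` paths to the per-subject TSV series.
#' @param config a [run_config].
#' @param out_dir optional directory for the CSV report files.
#' @param score_pairs optional `data.frame` with columns `score` (manifest
#'   column), `region` (abbreviation) and `metric`
#'   (`degree`/`efficiency`/`betweenness`) selecting the partial
#'   correlations to report.
#' @param verbose print per-subject progress.
#' @return list of class `pipeline_run`: `subject_auc`, `global_stats`,
#'   `nodal_stats`, `partial_cor`, `curves`, `nodal_auc`, `config`, `log`.
#' @export
run_pipeline <- function(manifest, config = run_config(), out_dir = NULL,
                         score_pairs = NULL, verbose = FALSE) {
  stopifnot(is.data.frame(manifest))
  need <- c("subject_id", "group", "file")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  groups <- unique(manifest$group)
  if (!all(sort(groups) == c("control", "patient")) ||
      min(table(manifest$group)) < 2) {
    stop("manifest must contain at least 2 subjects in each of the groups ",
         "'patient' and 'control'")
  }
  n_sub <- nrow(manifest)
  sub_seeds <- derive_seeds(config$seed, n_sub)
  log_lines <- c(sprintf("fctopo run: %d subjects, %d sparsity values, %d nulls, seed %d",
                         n_sub, length(config$grid), config$n_nulls,
                         config$seed))

  curves <- vector("list", n_sub)
  names(curves) <- manifest$subject_id
  for (i in seq_len(n_sub)) {
    id <- manifest$subject_id[i]
    ts <- tryCatch(read_subject_ts(manifest$file[i], tr = config$tr,
                                   subject_id = id),
                   error = function(e) stop("subject ", id, ": ",
                                            conditionMessage(e)))
    ts <- preprocess_subject(ts, drop_volumes = config$drop_volumes,
                             band = config$band)
    fc <- pearson_matrix(ts)
    curves[[i]] <- metric_curves(fc, config$grid,
                                 null_config(config$n_nulls,
                                             config$swaps_per_edge,
                                             seed = sub_seeds[i]),
                                 nodal = config$nodal,
                                 ranking = config$ranking)
    n_disc <- sum(curves[[i]]$global$n_inf_pairs > 0)
    if (n_disc > 0) {
      log_lines <- c(log_lines, sprintf(
        "subject %s: disconnected at %d/%d sparsity values (total %d unreachable pairs)",
        id, n_disc, length(config$grid), sum(curves[[i]]$global$n_inf_pairs)))
    }
    if (verbose) message("processed ", id)
  }
  first_n <- ncol(curves[[1]]$nodal$degree %||% matrix(0, 1, 1))

  subject_auc <- cbind(manifest[c("subject_id", "group")],
                       do.call(rbind, lapply(curves, function(mc) mc$auc)))
  rownames(subject_auc) <- NULL

  covars <- manifest[intersect(config$covariates, names(manifest))]
  if (length(covars) == 0) covars <- NULL

  global_stats <- compare_groups_auc(subject_auc, manifest$group, covars,
                                     config$alpha)
  nodal_stats <- partial_cor <- nodal_auc <- NULL
  if (config$nodal) {
    nodal_auc <- lapply(c(degree = "degree", efficiency = "efficiency",
                          betweenness = "betweenness"), function(mn) {
      t(vapply(curves, function(mc) mc$nodal_auc[, mn],
               numeric(nrow(curves[[1]]$nodal_auc))))
    })
    nodal_stats <- lapply(nodal_auc, compare_groups_nodal,
                          group = manifest$group, covariates = covars,
                          alpha = config$alpha)
    if (!is.null(score_pairs)) {
      partial_cor <- score_metric_correlations(manifest, nodal_auc,
                                               score_pairs, covars)
    }
  }
  run <- structure(list(subject_auc = subject_auc,
                        global_stats = global_stats,
                        nodal_stats = nodal_stats,
                        partial_cor = partial_cor, curves = curves,
                        nodal_auc = nodal_auc, config = config,
                        log = log_lines),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_run_reports(run, out_dir)
  run
}

# Welch + covariate-adjusted comparison of the five global AUCs, Bonferroni
# across the five metrics.
compare_groups_auc <- function(subject_auc, group, covariates, alpha) {
  metrics <- c("gamma", "lambda", "sigma", "e_loc", "e_glob")
  pat <- group == "patient"
  rows <- lapply(metrics, function(mn) {
    y <- subject_auc[[mn]]
    raw <- welch_t(y[pat], y[!pat], metric = mn)
    adj <- adjusted_group_compare(y, factor(group,
                                            levels = c("control", "patient")),
                                  covariates, metric = mn)
    data.frame(metric = mn,
               mean_patient = mean(y[pat]), mean_control = mean(y[!pat]),
               t_raw = raw$statistic, p_raw = raw$p_value,
               t_adjusted = adj$statistic, p_adjusted_model = adj$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  bc <- bonferroni(out$p_adjusted_model, alpha)
  out$p_bonferroni <- bc$p_adjusted
  out$significant <- bc$reject
  out
}

# Per-region group comparison of one nodal metric's AUCs; Bonferroni family
# = all regions within the metric.
compare_groups_nodal <- function(auc_mat, group, covariates, alpha) {
  pat <- group == "patient"
  regions <- colnames(auc_mat)
  rows <- lapply(seq_along(regions), function(j) {
    y <- auc_mat[, j]
    if (stats::var(y) == 0) {
      return(data.frame(region = regions[j], mean_patient = mean(y[pat]),
                        mean_control = mean(y[!pat]), t_raw = 0, p_raw = 1,
                        t_adjusted = 0, p_adjusted_model = 1,
                        stringsAsFactors = FALSE))
    }
    raw <- welch_t(y[pat], y[!pat])
    adj <- adjusted_group_compare(y, factor(group,
                                            levels = c("control", "patient")),
                                  covariates)
    data.frame(region = regions[j], mean_patient = mean(y[pat]),
               mean_control = mean(y[!pat]), t_raw = raw$statistic,
               p_raw = raw$p_value, t_adjusted = adj$statistic,
               p_adjusted_model = adj$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  bc <- bonferroni(out$p_adjusted_model, alpha)
  out$p_bonferroni <- bc$p_adjusted
  out$significant <- bc$reject
  out
}

score_metric_correlations <- function(manifest, nodal_auc, score_pairs,
                                      covariates) {
  pat <- manifest$group == "patient"
  rows <- lapply(seq_len(nrow(score_pairs)), function(i) {
    sc <- score_pairs$score[i]
    rg <- score_pairs$region[i]
    mn <- score_pairs$metric[i]
    if (!sc %in% names(manifest)) stop("unknown score column: ", sc)
    mat <- nodal_auc[[mn]]
    if (!rg %in% colnames(mat)) stop("unknown region: ", rg)
    cv <- if (is.null(covariates)) NULL else {
      cc <- covariates[pat, , drop = FALSE]
      cc[vapply(cc, function(col)
        length(unique(col)) > 1, logical(1))]
    }
    pc <- partial_correlation(manifest[[sc]][pat], mat[pat, rg], cv)
    data.frame(score = sc, region = rg, metric = mn, r = pc$r, p = pc$p,
               df = pc$df, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_run_reports <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$subject_auc,
                   file.path(out_dir, "subject_global_auc.csv"),
                   row.names = FALSE)
  utils::write.csv(run$global_stats,
                   file.path(out_dir, "global_auc_stats.csv"),
                   row.names = FALSE)
  curves_long <- do.call(rbind, lapply(names(run$curves), function(id)
    cbind(subject_id = id, run$curves[[id]]$global)))
  utils::write.csv(curves_long, file.path(out_dir, "global_curves.csv"),
                   row.names = FALSE)
  if (!is.null(run$nodal_stats)) {
    for (mn in names(run$nodal_stats)) {
      utils::write.csv(run$nodal_stats[[mn]],
                       file.path(out_dir, sprintf("nodal_%s_stats.csv", mn)),
                       row.names = FALSE)
      utils::write.csv(data.frame(subject_id = rownames(run$nodal_auc[[mn]]),
                                  run$nodal_auc[[mn]], check.names = FALSE),
                       file.path(out_dir, sprintf("subject_nodal_auc_%s.csv", mn)),
                       row.names = FALSE)
    }
  }
  if (!is.null(run$partial_cor)) {
    utils::write.csv(run$partial_cor,
                     file.path(out_dir, "partial_correlations.csv"),
                     row.names = FALSE)
  }
  write_run_config(run$config, file.path(out_dir, "run_config.yaml"))
  writeLines(run$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Summarize a completed pipeline run
#'
#' Counts significant regions per nodal metric, reports effect directions
#' and the top regions by absolute adjusted t.
#'
#' @param run a `pipeline_run` object or a report directory written by
#'   [run_pipeline].
#' @param top number of top regions to list per metric.
#' @return list of class `run_summary`.
#' @export
summarize_run <- function(run, top = 5) {
  if (is.character(run)) run <- read_run_reports(run)
  gs <- run$global_stats
  nodal <- NULL
  if (!is.null(run$nodal_stats)) {
    nodal <- lapply(run$nodal_stats, function(tab) {
      if (nrow(tab) == 0) {
        return(list(n_raw = 0L, n_bonferroni = 0L, top = tab))
      }
      ord <- order(-abs(tab$t_adjusted))
      list(n_raw = sum(tab$p_adjusted_model < 0.05),
           n_bonferroni = sum(tab$significant),
           n_increased = sum(tab$p_adjusted_model < 0.05 & tab$t_adjusted > 0),
           n_decreased = sum(tab$p_adjusted_model < 0.05 & tab$t_adjusted < 0),
           top = tab[utils::head(ord, top),
                     c("region", "t_adjusted", "p_adjusted_model")])
    })
  }
  structure(list(global = gs, nodal = nodal), class = "run_summary")
}

read_run_reports <- function(dir) {
  gs_path <- file.path(dir, "global_auc_stats.csv")
  if (!file.exists(gs_path)) stop("no global_auc_stats.csv under ", dir)
  nodal_files <- list.files(dir, pattern = "^nodal_.*_stats\\.csv$",
                            full.names = TRUE)
  nodal <- NULL
  if (length(nodal_files)) {
    nodal <- lapply(nodal_files, utils::read.csv, stringsAsFactors = FALSE)
    names(nodal) <- sub("^nodal_(.*)_stats\\.csv$", "\\1",
                        basename(nodal_files))
  }
  structure(list(global_stats = utils::read.csv(gs_path),
                 nodal_stats = nodal), class = "pipeline_run")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Global AUC group comparison:\n")
  print(x$global[c("metric", "mean_patient", "mean_control",
                   "p_adjusted_model", "significant")], row.names = FALSE)
  if (!is.null(x$nodal)) {
    for (mn in names(x$nodal)) {
      s <- x$nodal[[mn]]
      cat(sprintf("\nNodal %s: %d regions p<0.05 (%d up, %d down), %d survive Bonferroni\n",
                  mn, s$n_raw, s$n_increased %||% 0, s$n_decreased %||% 0,
                  s$n_bonferroni))
      print(s$top, row.names = FALSE)
    }
  }
  invisible(x)
}
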