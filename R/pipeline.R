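#' Run the conformation pipeline end-to-end
#'
#' For each input territory (a backbone-curve CSV or a z-stack TIFF), the
#' pipeline computes the aspect ratio K (stacks first pass through
#' projection, segmentation and curve extraction), then per condition fits
#' the bimodal Gaussian mixture, derives extended/collapsed percentages and
#' per-territory labels, and compares every pair of conditions with
#' Fisher's exact test on the classified counts. Unreadable or degenerate
#' inputs are collected as per-file errors and the run continues; if every
#' input fails, the run errors.
#'
#' @param config a named list or path to a YAML file with fields:
#'   `inputs` — data frame (or list) with columns `path` and `condition`
#'   (`path` pointing to a curve CSV or a z-stack TIFF written by
#'   [write_zstack_tiff()]); alternatively `k_table` — a data frame or CSV
#'   path with columns `territory_id`, `condition`, `K` of precomputed
#'   aspect ratios, skipping the imaging stage;
#'   `out_dir` — output directory (created if missing);
#'   optional `min_area_px` (default 20), `mixture_method` (default
#'   `"em"`), `seed` (default 1).
#' @return invisibly, the report list (also written to
#'   `out_dir/conformation_report.json`, with `k_values.tsv` and
#'   `labels.tsv` alongside).
#' @export
run_conformation_pipeline <- function(config) {
  cfg <- load_config(config)
  out_dir <- cfg$out_dir %||% stop("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  method <- cfg$mixture_method %||% "em"
  min_area <- as.integer(cfg$min_area_px %||% 20L)

  rows <- list(); errors <- list(); n_inf <- 0L
  if (!is.null(cfg$k_table)) {
    kdf <- if (is.character(cfg$k_table)) utils::read.csv(cfg$k_table) else
      as.data.frame(cfg$k_table)
    need <- c("territory_id", "condition", "K")
    if (!all(need %in% names(kdf)))
      stop("k_table needs columns territory_id, condition, K")
    kdf <- kdf[, need]
    n_inf <- sum(is.infinite(kdf$K))
  } else {
    inputs <- as.data.frame(cfg$inputs)
    if (!nrow(inputs)) stop("no inputs in config")
    for (i in seq_len(nrow(inputs))) {
      path <- inputs$path[i]
      res <- tryCatch({
        crv <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
          read_curve_csv(path)
        } else {
          stack <- read_zstack_tiff(path)
          img <- max_intensity_project(stack)
          mask <- segment_territory(img, min_area_px = min_area)
          if (isTRUE(attr(mask, "empty"))) stop("no territory segmented")
          extract_curve(mask)
        }
        gr <- shape_from_curve(crv)
        if (gr$infinite_K) n_inf <- n_inf + 1L
        data.frame(territory_id = basename(path),
                   condition = inputs$condition[i], K = gr$K)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[path]] <- conditionMessage(res)
        message("skipping ", path, ": ", conditionMessage(res))
      } else rows[[length(rows) + 1L]] <- res
    }
    if (!length(rows))
      stop("all inputs failed: ", paste(unlist(errors), collapse = "; "))
    kdf <- do.call(rbind, rows)
  }
  finite <- kdf[is.finite(kdf$K), , drop = FALSE]

  fits <- list(); labels <- list(); counts <- list()
  for (cond in unique(finite$condition)) {
    kv <- finite$K[finite$condition == cond]
    fit <- tryCatch(
      fit_bimodal(kv, method = method, condition = cond, seed = seed),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      errors[[paste0("fit:", cond)]] <- conditionMessage(fit)
      next
    }
    lab <- classify_territory(kv, fit)
    labels[[cond]] <- data.frame(
      territory_id = finite$territory_id[finite$condition == cond],
      condition = cond, K = kv, label = lab
    )
    counts[[cond]] <- conformation_counts(lab)
    pct <- tryCatch(conformation_percentages(fit), error = function(e) NULL)
    fits[[cond]] <- list(
      n = fit$n, mu_collapsed = fit$mu_c, mu_extended = fit$mu_e,
      sigma_collapsed = fit$sigma_c, sigma_extended = fit$sigma_e,
      w_extended = fit$w_e, converged = fit$converged,
      overlap_flag = fit$overlap_flag,
      assignment_threshold = fit$assignment_threshold,
      pct_extended = if (is.null(pct)) NA else unname(pct["pct_extended"]),
      pct_collapsed = if (is.null(pct)) NA else unname(pct["pct_collapsed"])
    )
  }
  fisher <- list()
  cn <- names(counts)
  if (length(cn) >= 2L) {
    for (i in seq_len(length(cn) - 1L)) for (j in (i + 1L):length(cn)) {
      cmp <- compare_conditions(counts[[cn[i]]], counts[[cn[j]]])
      fisher[[paste(cn[i], "vs", cn[j])]] <-
        list(odds_ratio = cmp$odds_ratio, p_two_sided = cmp$p_two_sided)
    }
  }
  report <- list(
    seed = seed, mixture_method = method, min_area_px = min_area,
    n_territories = nrow(kdf), n_infinite_K = n_inf,
    fits = fits, fisher = fisher, errors = errors,
    package_version = as.character(utils::packageVersion("territoryshape"))
  )
  write_table_sorted(kdf, file.path(out_dir, "k_values.tsv"))
  labdf <- if (length(labels)) do.call(rbind, labels) else
    data.frame(territory_id = character(), condition = character(),
               K = numeric(), label = character())
  write_table_sorted(labdf, file.path(out_dir, "labels.tsv"))
  jsonlite::write_json(report, file.path(out_dir, "conformation_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Run the dynamics pipeline end-to-end
#'
#' Reads trajectory CSVs, drift-corrects each against its nuclear-centroid
#' series when present, computes per-trajectory R_g, D_eff and the
#' power-law (D_app, alpha), and compares every pair of conditions with
#' Welch's t-test on R_g and on D_eff. Trajectories shorter than 4 frames
#' are skipped with a warning.
#'
#' @param config a named list or YAML path with fields: `inputs` (columns
#'   `path`, `condition`), `out_dir`, optional `fit_fraction` (default
#'   0.25), `seed` (default 1, recorded in the report).
#' @return invisibly, the report list (written to
#'   `out_dir/dynamics_report.json`, with `trajectory_stats.tsv`
#'   alongside).
#' @export
run_dynamics_pipeline <- function(config) {
  cfg <- load_config(config)
  inputs <- as.data.frame(cfg$inputs)
  if (!nrow(inputs)) stop("no inputs in config")
  out_dir <- cfg$out_dir %||% stop("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit_fraction <- cfg$fit_fraction %||% 0.25

  rows <- list(); errors <- list()
  for (i in seq_len(nrow(inputs))) {
    path <- inputs$path[i]
    res <- tryCatch({
      traj <- read_trajectory_csv(path)
      if (traj$n + 1L < 4L) {
        warning("skipping ", basename(path), ": fewer than 4 frames")
        NULL
      } else {
        st <- trajectory_stats(traj, fit_fraction = fit_fraction)
        cbind(data.frame(trajectory_id = basename(path),
                         condition = inputs$condition[i]), st)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[path]] <- conditionMessage(res)
      message("skipping ", path, ": ", conditionMessage(res))
    } else if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("no usable trajectories")
  stats_df <- do.call(rbind, rows)

  conds <- unique(stats_df$condition)
  comparisons <- list(); summaries <- list()
  for (cond in conds) {
    sub <- stats_df[stats_df$condition == cond, ]
    summaries[[cond]] <- list(
      n_trajectories = nrow(sub),
      R_g = box_summary(sub$R_g), D_eff = box_summary(sub$D_eff),
      D_app = box_summary(sub$D_app), alpha = box_summary(sub$alpha)
    )
  }
  if (length(conds) >= 2L) {
    for (i in seq_len(length(conds) - 1L)) for (j in (i + 1L):length(conds)) {
      a <- stats_df[stats_df$condition == conds[i], ]
      b <- stats_df[stats_df$condition == conds[j], ]
      key <- paste(conds[i], "vs", conds[j])
      comparisons[[key]] <- list(
        R_g = welch_test(a$R_g, b$R_g),
        D_eff = welch_test(a$D_eff, b$D_eff)
      )
    }
  }
  report <- list(
    seed = as.integer(cfg$seed %||% 1L), fit_fraction = fit_fraction,
    n_trajectories = nrow(stats_df), summaries = summaries,
    welch = comparisons, errors = errors,
    package_version = as.character(utils::packageVersion("territoryshape"))
  )
  write_table_sorted(stats_df, file.path(out_dir, "trajectory_stats.tsv"))
  jsonlite::write_json(report, file.path(out_dir, "dynamics_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

box_summary <- function(x) {
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  list(min = q[1L], q1 = q[2L], median = q[3L], q3 = q[4L], max = q[5L],
       mean = mean(x))
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  config
}

write_table_sorted <- function(df, path) {
  ord <- do.call(order, df[, intersect(c("condition", "territory_id",
                                         "trajectory_id"), names(df)),
                           drop = FALSE])
  utils::write.table(df[ord, , drop = FALSE], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
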