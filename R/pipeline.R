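# Orchestration: generate -> quantify -> normalize -> compare -> model,
# with one top-level seed split per stage by fixed offsets, and plain-file
# outputs so stages can be rerun independently.

#' Configuration for a quantification experiment
#'
#' Defines paired control/experimental groups whose sperm (and the embryos
#' fathered by them) differ by a multiplicative centromeric CenH3 factor.
#'
#' @param groups Named numeric vector of paternal perturbation factors; must
#'   contain `control_group`. E.g. `c(control = 1, depleted = 0.5)`.
#' @param control_group Name of the reference group (factor usually 1).
#' @param n_sperm_scenes,n_embryo_scenes Scenes generated per group.
#' @param sperm_config,embryo_config Base [scene_config()]s for the two
#'   tissues (defaults are compact frames sized for routine runs).
#' @param quant_params A [segment_params()].
#' @param seed Top-level seed; per-stage seeds are derived by fixed offsets.
#' @return Object of class `run_config`.
#' @export
run_config <- function(groups = c(control = 1, experimental = 0.5),
                       control_group = "control",
                       n_sperm_scenes = 2L, n_embryo_scenes = 2L,
                       sperm_config = scene_config("sperm",
                                                   image_size = c(256L, 256L),
                                                   n_nuclei = 9L),
                       embryo_config = scene_config("embryo_metaphase",
                                                    image_size = c(256L, 256L),
                                                    n_nuclei = 4L),
                       quant_params = segment_params(),
                       seed = 1L) {
  if (is.null(names(groups)) || !all(nzchar(names(groups)))) {
    stop_param("config error: groups must be a named factor vector")
  }
  if (!control_group %in% names(groups)) {
    stop_param("config error: missing control group `", control_group, "`")
  }
  if (any(groups <= 0)) {
    stop_param("config error: perturbation factors must be > 0")
  }
  structure(list(groups = groups, control_group = control_group,
                 n_sperm_scenes = as.integer(n_sperm_scenes),
                 n_embryo_scenes = as.integer(n_embryo_scenes),
                 sperm_config = sperm_config, embryo_config = embryo_config,
                 quant_params = quant_params, seed = as.integer(seed)),
            class = "run_config")
}

quantify_nucleus_totals <- function(scene, params) {
  meas <- quantify_scene(scene, params)
  meas <- meas[!is.na(meas$nucleus_id), , drop = FALSE]
  if (!nrow(meas)) {
    return(data.frame(nucleus_id = integer(0), total = numeric(0)))
  }
  agg <- stats::aggregate(corrected ~ nucleus_id, data = meas, FUN = sum)
  names(agg) <- c("nucleus_id", "total")
  agg
}

#' Run a full image-based quantification experiment
#'
#' For every group, generates seeded sperm scenes (per-sperm centromeric
#' signal scaled by the group factor) and embryo scenes fathered by that
#' sperm (paternal half-set scaled, maternal untouched), quantifies them
#' through segmentation and local background correction, normalizes
#' per-nucleus totals to a control mean of 100 a.u., and reports group
#' means, fold changes and Welch t-test p values.
#'
#' @param config A [run_config()].
#' @return List with `sperm` and `embryo` per-nucleus tables (columns
#'   `group`, `scene`, `nucleus_id`, `total`, `normalized_au`), a `summary`
#'   data frame (tissue, group, n, mean/sd in a.u., fold change and p value
#'   versus control), and the `config`.
#' @export
run_quantification_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  groups <- config$groups
  tissues <- list(sperm = NULL, embryo = NULL)
  for (g in seq_along(groups)) {
    gname <- names(groups)[g]
    factor_g <- groups[[g]]
    for (i in seq_len(config$n_sperm_scenes)) {
      cfg <- config$sperm_config
      cfg$base_intensity <- cfg$base_intensity * factor_g
      cfg$seed <- config$seed + 1000L * g + i
      totals <- quantify_nucleus_totals(generate_scene(cfg),
                                        config$quant_params)
      if (nrow(totals)) {
        tissues$sperm <- rbind(tissues$sperm, data.frame(
          group = gname, scene = i, totals, stringsAsFactors = FALSE))
      }
    }
    embryo_cfg <- config$embryo_config
    embryo_cfg$seed <- config$seed + 1000L * g + 500L
    panel <- generate_cross_panel(factor_g, config$n_embryo_scenes,
                                  embryo_cfg)
    for (i in seq_along(panel)) {
      totals <- quantify_nucleus_totals(panel[[i]], config$quant_params)
      if (nrow(totals)) {
        tissues$embryo <- rbind(tissues$embryo, data.frame(
          group = gname, scene = i, totals, stringsAsFactors = FALSE))
      }
    }
  }
  summary_rows <- list()
  for (tis in names(tissues)) {
    tab <- tissues[[tis]]
    if (is.null(tab)) next
    ctrl <- tab$total[tab$group == config$control_group]
    tab$normalized_au <- normalize_to_control(tab$total, ctrl)
    tissues[[tis]] <- tab
    for (gname in names(groups)) {
      vals <- tab$normalized_au[tab$group == gname]
      cmp <- if (gname == config$control_group) {
        list(fold_change = 1, p_value = NA_real_)
      } else {
        compare_groups(tab$normalized_au[tab$group == config$control_group],
                       vals)
      }
      summary_rows[[paste(tis, gname)]] <- data.frame(
        tissue = tis, group = gname, factor = groups[[gname]],
        n = length(vals), mean_au = mean(vals), sd_au = stats::sd(vals),
        fold_change = cmp$fold_change, p_value = cmp$p_value,
        stringsAsFactors = FALSE)
    }
  }
  list(sperm = tissues$sperm, embryo = tissues$embryo,
       summary = do.call(rbind, c(summary_rows, make.row.names = FALSE)),
       config = config)
}

#' Run the transgenerational model and package its report
#'
#' @param params A [germline_params()].
#' @param horizon Generations to iterate.
#' @param perturbation_factors Sperm perturbation factors propagated through
#'   the fertilization mixing arithmetic.
#' @param stochastic If `TRUE`, cross-check the deterministic expectations
#'   against seeded lineage sampling.
#' @param n_lineages Lineages per class for the stochastic check.
#' @param seed Seed for the stochastic check.
#' @return List: `stabilization_generation` (NA with a `non_convergent`
#'   flag rather than an error if the horizon is insufficient),
#'   `final_difference`, `trajectories` (long data frame: generation, class,
#'   level), `perturbations` (factor, sperm level, expected embryo total),
#'   and optionally `stochastic_check`.
#' @export
run_model_report <- function(params = germline_params(), horizon = 12L,
                             perturbation_factors = c(0.33, 0.5, 7),
                             stochastic = TRUE, n_lineages = 10000L,
                             seed = 1L) {
  traj <- autosome_trajectory(params, horizon)
  ys <- y_trajectory(params, horizon)
  xs <- x_expected_trajectory(params, horizon)
  long <- rbind(
    data.frame(generation = traj$generation, class = "autosome_paternal",
               level = traj$P),
    data.frame(generation = traj$generation, class = "autosome_maternal",
               level = traj$M),
    data.frame(generation = 1:horizon, class = "Y", level = ys),
    data.frame(generation = 1:horizon, class = "X_expected", level = xs))
  stab <- tryCatch(stabilization_generation(params, horizon),
                   error = function(e) NA_integer_)
  pert <- data.frame(
    factor = perturbation_factors,
    sperm_relative = perturbation_factors,
    embryo_total_relative = embryo_mix(perturbation_factors, 1))
  out <- list(stabilization_generation = stab,
              non_convergent = is.na(stab),
              final_difference = traj$difference[horizon + 1],
              trajectories = long, perturbations = pert,
              params = params)
  if (stochastic) {
    checks <- lapply(c(autosome = "autosome", X = "X", Y = "Y"),
                     function(cl) {
      draws <- sample_lineages(params, horizon, n_lineages, cl, seed = seed)
      final <- draws[, horizon]
      expected <- switch(cl,
                         autosome = traj$mean[horizon + 1],
                         X = xs[horizon],
                         Y = ys[horizon])
      se <- stats::sd(final) / sqrt(length(final))
      list(expected = expected, sampled_mean = mean(final), se = se,
           within_3se = abs(mean(final) - expected) <= 3 * se ||
             stats::sd(final) == 0)
    })
    out$stochastic_check <- checks
  }
  out
}

#' Write pipeline results to plain files
#'
#' Emits CSV tables, a JSON summary and a plain-text run log (parameters,
#' seed, package version; no timestamps, so reruns with the same seed are
#' byte-identical).
#'
#' @param results Output of [run_quantification_experiment()] and/or
#'   [run_model_report()] (a list; recognized elements are written).
#' @param dir Output directory, created if needed.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit_csv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  for (nm in c("sperm", "embryo", "summary", "trajectories",
               "perturbations")) {
    if (!is.null(results[[nm]]) && is.data.frame(results[[nm]])) {
      emit_csv(results[[nm]], paste0(nm, ".csv"))
    } else if (nm %in% c("sperm", "embryo", "summary") &&
               !is.null(results$config)) {
      # declared table absent: still emit an empty table with headers
      emit_csv(data.frame(group = character(0), scene = integer(0),
                          nucleus_id = integer(0), total = numeric(0),
                          normalized_au = numeric(0)), paste0(nm, ".csv"))
    }
  }
  json <- list()
  if (!is.null(results$summary)) json$summary <- results$summary
  if (!is.null(results$stabilization_generation)) {
    json$model <- list(
      stabilization_generation = results$stabilization_generation,
      non_convergent = results$non_convergent,
      final_difference = results$final_difference)
  }
  if (length(json)) {
    path <- file.path(dir, "summary.json")
    jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    written <- c(written, path)
  }
  seed <- results$config$seed %||% NA
  log_lines <- c(
    "cenherit run log",
    paste0("package_version: ",
           as.character(utils::packageVersion("cenherit"))),
    paste0("seed: ", seed),
    paste0("r_version: ", R.version$major, ".", R.version$minor))
  if (!is.null(results$config)) {
    log_lines <- c(log_lines,
      paste0("groups: ", paste(names(results$config$groups),
                               results$config$groups,
                               sep = "=", collapse = ", ")),
      paste0("quant_params: ",
             paste(names(results$config$quant_params),
                   unlist(results$config$quant_params),
                   sep = "=", collapse = ", ")))
  }
  if (!is.null(results$params) && inherits(results$params,
                                           "germline_params")) {
    p <- results$params
    log_lines <- c(log_lines,
      paste0("model: mode=", p$mode, " L0=", p$L0, " a_m=", p$a_m,
             " a_f=", p$a_f))
  }
  log_path <- file.path(dir, "run_log.txt")
  writeLines(log_lines, log_path)
  invisible(c(written, log_path))
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) {
      stop_param("cli error: unexpected argument `", a, "`")
    }
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      val <- args[[i + 1L]]
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (!is.na(num)) num else val
      i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write seeded scenes),
#' `quantify` (measure a written scene), `model` (transgenerational model
#' report), `report` (full quantification experiment). Common flags:
#' `--seed`, `--out`; see the README for examples. Returns 0 on success,
#' nonzero after logging the failure reason.
#'
#' @param args Character vector of CLI arguments (default: the process
#'   command line).
#' @return Integer exit status, invisibly.
#' @export
cen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) {
      stop_param("cli error: usage: cenherit <simulate|quantify|model|",
                 "report> [--flags]")
    }
    cmd <- args[[1]]
    opt <- parse_cli_args(args[-1])
    out_dir <- opt$out %||% "."
    seed <- as.integer(opt$seed %||% 1)
    if (cmd == "simulate") {
      cfg <- scene_config(stage = opt$stage %||% "sperm",
                          n_nuclei = opt$n_nuclei,
                          noise_sd = opt$noise_sd %||% 8,
                          seed = seed)
      scene <- generate_scene(cfg)
      paths <- write_scene(scene, out_dir, prefix = opt$prefix %||% "scene")
      message("wrote ", length(paths), " files to ", out_dir)
    } else if (cmd == "quantify") {
      scene <- read_scene(opt$dir %||% ".", prefix = opt$prefix %||% "scene")
      meas <- quantify_scene(scene)
      meas <- tryCatch(normalize_within_cell(meas), error = function(e) meas)
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      path <- file.path(out_dir, "measurements.csv")
      utils::write.csv(meas, path, row.names = FALSE)
      message("wrote ", path, " (", nrow(meas), " spots)")
    } else if (cmd == "model") {
      params <- if (!is.null(opt$config)) {
        cfgl <- read_config(opt$config)
        germline_params(L0 = cfgl$L0 %||% 100, a_m = cfgl$a_m %||% 10,
                        a_f = cfgl$a_f %||% 10,
                        mode = cfgl$mode %||% "additive")
      } else {
        germline_params()
      }
      rep <- run_model_report(params, seed = seed)
      write_report(rep, out_dir)
      cat(jsonlite::toJSON(list(
        stabilization_generation = rep$stabilization_generation,
        final_difference = rep$final_difference),
        auto_unbox = TRUE, digits = NA), "\n")
    } else if (cmd == "report") {
      cfg <- run_config(groups = c(control = 1,
                                   experimental = opt$factor %||% 0.5),
                        seed = seed)
      res <- run_quantification_experiment(cfg)
      write_report(res, out_dir)
      message("wrote report to ", out_dir)
    } else {
      stop_param("cli error: unknown subcommand `", cmd, "`")
    }
    0L
  }, error = function(e) {
    message("cenherit: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
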