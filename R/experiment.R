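## End-to-end experiment driver -------------------------------------------

#' Default experiment configuration
#'
#' Nested list accepted by [run_experiment()]; any subset of it can be
#' overridden via a YAML file or an R list. Sections: `simulate` (canopy
#' generator overrides and the angle list), `partition`, `vis`
#' (published-index names), `optimize` (two-band search), `plsr`, `bpnn`
#' and `report`.
#'
#' @return Nested configuration list.
#' @export
default_experiment_config <- function() {
  list(
    simulate = list(n_samples = 221, vzas = seq(-60, 60, by = 10)),
    partition = list(n_train = 176, k = 5, shared = TRUE),
    vis = list(names = "all"),
    optimize = list(types = c("ND", "SR", "DVI"), step = 2),
    plsr = list(a_max = 15, scale = FALSE),
    bpnn = list(enabled = TRUE, hidden = c(10, 30), repeats = 5,
                epochs = 150, vzas = NULL),
    report = list(write_data = FALSE, surfaces = TRUE, loading_components = 3)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

vza_tag <- function(v) sprintf("%+d", as.integer(v))

#' Run the full multi-angular comparison experiment
#'
#' Simulates a multi-angular dataset (or loads one from CSV paths given in
#' the config), computes the published vegetation indices, optimizes
#' two-band indices per angle, fits PLSR and the BPNN, evaluates
#' everything on a shared calibration/validation split, and writes the
#' report tables to `out_dir`:
#'
#' * `optimal_pairs.csv` — the selected two-band combination per angle and
#'   index form, with calibration R^2 and the fitted line;
#' * `vi_results.csv` — calibration/validation R^2 and RMSE for every
#'   published index at every angle;
#' * `method_profiles.csv` — the per-method angular profile;
#' * `decline.csv` — relative R^2 decline versus nadir (only when more
#'   than one angle, including nadir, was evaluated);
#' * `surfaces/surface_<type>_vza<angle>.csv` — long-format R^2 surfaces;
#' * `plsr_rmse_curve.csv`, `plsr_loadings.csv` — latent-variable
#'   selection curves and loading spectra per angle;
#' * `lai.csv`, `spectra_vza<angle>.csv` — the simulated data, when
#'   `report$write_data` is TRUE;
#' * `run_log.txt` — seed, configuration and versions.
#'
#' All randomness derives from `seed` (stage seeds are `seed`, `seed + 1`
#' and `seed + 2` for simulation, partitioning and the BPNN), so a rerun
#' with the same seed reproduces every numeric output byte for byte.
#'
#' @param config `NULL` (defaults), a nested list, or a path to a YAML
#'   file; merged over [default_experiment_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed.
#' @return Invisibly, a list with the in-memory tables (`data` excluded
#'   unless requested): `optimal_pairs`, `vi_results`, `profiles`,
#'   `decline`, `plsr_curves`, `plsr_loadings`, `out_dir`.
#' @export
run_experiment <- function(config = NULL, out_dir, seed = 1) {
  cfg <- default_experiment_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) cfg <- merge_config(cfg, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("experiment stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## --- data -------------------------------------------------------------
  vzas <- sort(unlist(cfg$simulate$vzas))
  data <- stage("simulate", {
    if (!is.null(cfg$simulate$spectra_paths)) {
      lai_path <- cfg$simulate$lai_path
      dplyr::bind_rows(lapply(cfg$simulate$spectra_paths,
                              read_dataset, lai_path = lai_path))
    } else {
      sim_args <- cfg$simulate
      sim_args$vzas <- NULL
      sim_args$seed <- seed
      generate_canopy(do.call(canopy_config, sim_args), vzas = vzas)
    }
  })
  vzas <- sort(unique(data$vza))

  ## --- partition --------------------------------------------------------
  partition <- stage("partition", {
    if (isTRUE(cfg$partition$shared)) {
      make_partition(data, cfg$partition$n_train, cfg$partition$k, seed + 1)
    } else {
      stats::setNames(lapply(seq_along(vzas), function(i) {
        make_partition(data[data$vza == vzas[i], ], cfg$partition$n_train,
                       cfg$partition$k, seed + 1 + i)
      }), as.character(vzas))
    }
  })
  part_for <- function(v) if (is.data.frame(partition)) partition else partition[[as.character(v)]]

  ## --- published indices ------------------------------------------------
  vi_names <- cfg$vis$names
  if (identical(vi_names, "all")) vi_names <- vi_catalog()$name
  vi_results <- stage("indices", dplyr::bind_rows(lapply(vzas, function(v) {
    dv <- data[data$vza == v, ]
    part <- part_for(v)
    cal <- partition_subset(dv, part, "train")
    val <- partition_subset(dv, part, "test")
    dplyr::bind_rows(lapply(vi_names, function(nm) {
      icall <- compute_vi(cal, nm)
      fit <- try(fit_linear(icall, cal$lai), silent = TRUE)
      if (inherits(fit, "try-error")) return(NULL)
      pv <- predict(fit, compute_vi(val, nm))
      dplyr::bind_rows(
        method_row(nm, v, "calibration", cal$lai, predict(fit, icall), NULL),
        method_row(nm, v, "validation", val$lai, pv, NULL)
      )[, c("method", "vza", "set", "r2", "rmse", "n")]
    })) |> dplyr::rename(index = "method")
  })))

  ## --- two-band optimization -------------------------------------------
  surf_dir <- file.path(out_dir, "surfaces")
  if (isTRUE(cfg$report$surfaces)) dir.create(surf_dir, showWarnings = FALSE)
  optimal_pairs <- stage("optimize", dplyr::bind_rows(lapply(vzas, function(v) {
    dv <- data[data$vza == v, ]
    part <- part_for(v)
    cal <- partition_subset(dv, part, "train")
    dplyr::bind_rows(lapply(cfg$optimize$types, function(tp) {
      surf <- r2_surface(cal, tp, step = cfg$optimize$step)
      if (isTRUE(cfg$report$surfaces)) {
        export_surface(surf, file.path(surf_dir,
          sprintf("surface_%s_vza%s.csv", tp, vza_tag(v))))
      }
      best <- select_optimum(surf, cal)
      names(best)[names(best) == "r2"] <- "r2_cal"
      best
    }))
  })))

  ## --- method comparison ------------------------------------------------
  methods <- c("vi", "optimal_vi", "plsr")
  if (isTRUE(cfg$bpnn$enabled)) methods <- c(methods, "bpnn")
  bpnn_vzas <- cfg$bpnn$vzas %||% vzas
  bpnn_args <- cfg$bpnn[intersect(names(cfg$bpnn),
                                  c("hidden", "repeats", "epochs",
                                    "learn_rate", "patience"))]
  profiles <- stage("evaluate", {
    base <- evaluate_vza(data, partition, methods = setdiff(methods, "bpnn"),
                         vzas = vzas, opt_step = cfg$optimize$step,
                         plsr_max = cfg$plsr$a_max, plsr_scale = cfg$plsr$scale,
                         seed = seed + 2)
    if ("bpnn" %in% methods) {
      bp <- evaluate_vza(data, partition, methods = "bpnn",
                         vzas = intersect(bpnn_vzas, vzas),
                         bpnn = bpnn_args, seed = seed + 2)
      base <- dplyr::bind_rows(base, bp)
    }
    dplyr::arrange(base, .data$method, .data$vza, .data$set)
  })

  decline <- NULL
  if (length(vzas) > 1 && 0 %in% vzas) {
    decline <- decline_vs_nadir(profiles)[, c("method", "set", "vza", "decline_pct")]
  }

  ## --- PLSR diagnostics -------------------------------------------------
  plsr_rows <- stage("plsr-diagnostics", lapply(vzas, function(v) {
    dv <- data[data$vza == v, ]
    part <- part_for(v)
    cal <- partition_subset(dv, part, "train")
    folds <- partition_folds(cal, part)
    sel <- select_components(cal, a_max = cfg$plsr$a_max, folds = folds,
                             scale = cfg$plsr$scale)
    fit <- fit_plsr(cal, ncomp = sel$chosen, scale = cfg$plsr$scale)
    k <- min(cfg$report$loading_components, fit$ncomp)
    list(curve = dplyr::mutate(tidy.plsr_selection(sel), vza = v,
                               .before = 1),
         loadings = dplyr::mutate(plsr_loadings(fit, seq_len(k)), vza = v,
                                  .before = 1))
  }))
  plsr_curves <- dplyr::bind_rows(lapply(plsr_rows, `[[`, "curve"))
  plsr_load <- dplyr::bind_rows(lapply(plsr_rows, `[[`, "loadings"))

  ## --- write report -----------------------------------------------------
  stage("report", {
    readr::write_csv(optimal_pairs, file.path(out_dir, "optimal_pairs.csv"), progress = FALSE)
    readr::write_csv(vi_results, file.path(out_dir, "vi_results.csv"), progress = FALSE)
    readr::write_csv(profiles[, c("method", "vza", "set", "r2", "rmse", "n")],
                     file.path(out_dir, "method_profiles.csv"), progress = FALSE)
    if (!is.null(decline)) {
      readr::write_csv(decline, file.path(out_dir, "decline.csv"), progress = FALSE)
    }
    readr::write_csv(plsr_curves, file.path(out_dir, "plsr_rmse_curve.csv"), progress = FALSE)
    readr::write_csv(plsr_load, file.path(out_dir, "plsr_loadings.csv"), progress = FALSE)
    if (isTRUE(cfg$report$write_data)) {
      write_dataset(data, file.path(out_dir, "spectra.csv"),
                    file.path(out_dir, "lai.csv"))
    }
    writeLines(c(
      sprintf("angulai %s | R %s", as.character(utils::packageVersion("angulai")),
              paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("master seed: %d (stages: simulate %d, partition %d, fit %d)",
              seed, seed, seed + 1, seed + 2),
      sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
      "config:",
      yaml::as.yaml(cfg)
    ), file.path(out_dir, "run_log.txt"))
  })

  invisible(list(optimal_pairs = optimal_pairs, vi_results = vi_results,
                 profiles = profiles, decline = decline,
                 plsr_curves = plsr_curves, plsr_loadings = plsr_load,
                 partition = partition, out_dir = out_dir))
}
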