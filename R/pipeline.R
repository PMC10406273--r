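#' Pipeline configuration
#'
#' Bundles everything needed for an end-to-end run: the synthetic study (or
#' a manifest of existing volumes), the model and training settings, the
#' dFNC window, and the statistical options. Seeds for every stochastic
#' stage derive from `seed`.
#'
#' @param synth A [synth_config()].
#' @param out_dir Output directory.
#' @param model A [model_spec()].
#' @param train A [train_config()].
#' @param window A [window_spec()].
#' @param fdr_q FDR level of the FNC group test.
#' @param mask_level Template-support threshold defining the analysis mask.
#' @param networks Integer vector of networks to train/predict (default
#'   all).
#' @param use_truth_maps Run the statistics on the generator's ground-truth
#'   maps instead of model predictions (skips training/prediction; useful
#'   for testing the statistical stages in isolation).
#' @param seed Master seed.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(synth, out_dir, model = model_spec(),
                            train = train_config(), window = window_spec(),
                            fdr_q = 0.05, mask_level = 0.05, networks = NULL,
                            use_truth_maps = FALSE, seed = 1L,
                            log_level = c("info", "quiet")) {
  stopifnot(inherits(synth, "synth_config"), inherits(model, "model_spec"),
            inherits(train, "train_config"), inherits(window, "window_spec"))
  structure(list(synth = synth, out_dir = out_dir, model = model,
                 train = train, window = window, fdr_q = fdr_q,
                 mask_level = mask_level,
                 networks = networks %||% seq_len(synth$n_networks),
                 use_truth_maps = isTRUE(use_truth_maps),
                 seed = as.integer(seed), log_level = match.arg(log_level)),
            class = "pipeline_config")
}

pipeline_hash <- function(cfg, stage) {
  keep <- cfg[setdiff(names(cfg), c("out_dir", "log_level"))]
  rlang::hash(list(stage = stage, cfg = lapply(keep, unclass)))
}

stage_marker_path <- function(cfg, stage) {
  file.path(cfg$out_dir, sprintf("stage_%s.json", stage))
}

stage_done <- function(cfg, stage) {
  p <- stage_marker_path(cfg, stage)
  file.exists(p) &&
    identical(jsonlite::read_json(p)$hash, pipeline_hash(cfg, stage))
}

mark_stage <- function(cfg, stage, elapsed) {
  jsonlite::write_json(
    list(stage = stage, hash = pipeline_hash(cfg, stage),
         elapsed_s = round(elapsed, 3), seed = cfg$seed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    stage_marker_path(cfg, stage), auto_unbox = TRUE)
}

plog <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  msg <- sprintf(fmt, ...)
  message("[spatiodyn] ", msg)
  cat(format(Sys.time(), "%H:%M:%S "), msg, "\n", sep = "",
      file = file.path(cfg$out_dir, "log.txt"), append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (write the synthetic study), train (one
#' model per requested network), predict (per-subject 4D score maps), stats
#' (time-mean and temporal-deviation maps, group means, voxel-wise t-maps,
#' difference maps and peak tables) and fnc (per-subject static FNC, the
#' FDR-controlled group test, dFNC windows, k-means states and occupancy
#' ratios). Completed stages whose configuration hash matches their marker
#' file are skipped, so an interrupted run resumes where it stopped. Every
#' stage logs its timing and seed, and a machine-readable run manifest is
#' written at the end.
#'
#' @param cfg A [pipeline_config()].
#' @param stages Subset of stages to run (prerequisites are always
#'   satisfied first).
#' @return A `study_result` list of output locations and key tables.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "train", "predict",
                                         "stats", "fnc")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  result <- list(out_dir = cfg$out_dir)
  synth <- cfg$synth
  K <- synth$n_networks

  run_stage <- function(stage, fn) {
    if (stage_done(cfg, stage)) {
      plog(cfg, "stage %-8s skipped (up to date)", stage)
      fn(skip_io = TRUE)
    } else {
      t0 <- proc.time()[3]
      out <- fn(skip_io = FALSE)
      mark_stage(cfg, stage, proc.time()[3] - t0)
      plog(cfg, "stage %-8s done in %.1fs", stage, proc.time()[3] - t0)
      out
    }
  }

  # -- simulate ------------------------------------------------------------
  data_dir <- file.path(cfg$out_dir, "data")
  study <- run_stage("simulate", function(skip_io) {
    if (skip_io) {
      simulate_study(synth)
    } else {
      attr(make_group_study(synth, data_dir), "study")
    }
  })
  mask <- study_mask(study$templates, cfg$mask_level)
  result$manifest <- study$manifest
  result$manifest_path <- file.path(data_dir, "manifest.csv")

  truth_maps_of <- function(s) {
    setNames(s$truth$score_maps, paste0("net", seq_len(K)))
  }

  # -- train ---------------------------------------------------------------
  models <- NULL
  if (!cfg$use_truth_maps && any(c("train", "predict", "stats", "fnc") %in% stages)) {
    model_dir <- file.path(cfg$out_dir, "models")
    if (!dir.exists(model_dir)) dir.create(model_dir)
    models <- run_stage("train", function(skip_io) {
      lapply(cfg$networks, function(k) {
        ckpt <- file.path(model_dir, sprintf("net%02d.rds", k))
        if (skip_io && file.exists(ckpt)) return(load_checkpoint(ckpt))
        plog(cfg, "training network %d", k)
        data <- make_volume_dataset(study, k, seed = derive_seed(cfg$seed, k))
        m <- build_model(cfg$model, synth$grid_dims,
                         init_seed = derive_seed(cfg$seed, k, 7L),
                         network_id = k)
        m <- train_model(m, data, cfg$train)
        save_checkpoint(m, ckpt)
        utils::write.csv(as.data.frame(attr(m, "history")),
                         file.path(model_dir, sprintf("net%02d_history.csv", k)),
                         row.names = FALSE)
        m
      })
    })
    result$model_dir <- model_dir
  }

  # -- predict -------------------------------------------------------------
  get_subject_maps <- function(s) {
    if (cfg$use_truth_maps) {
      truth_maps_of(s)[cfg$networks]
    } else {
      setNames(predict_subject(models, s$volume, cfg$train$batch_size),
               paste0("net", cfg$networks))
    }
  }
  map_dir <- file.path(cfg$out_dir, "maps")
  if (!cfg$use_truth_maps && any(c("predict", "stats", "fnc") %in% stages)) {
    if (!dir.exists(map_dir)) dir.create(map_dir)
    run_stage("predict", function(skip_io) {
      if (skip_io) return(invisible())
      for (s in study$subjects) {
        maps <- get_subject_maps(s)
        for (nm in names(maps)) {
          write_nifti_vol(maps[[nm]],
                          file.path(map_dir, sprintf("%s_%s_score.nii.gz",
                                                     s$subject_id, nm)))
        }
      }
    })
    result$map_dir <- map_dir
  }

  if (!any(c("stats", "fnc") %in% stages)) {
    class(result) <- "study_result"
    return(result)
  }

  # per-subject maps for the analysis stages (one pass, reused)
  subject_maps <- lapply(study$subjects, get_subject_maps)
  groups <- vapply(study$subjects, `[[`, "", "group")
  ids <- vapply(study$subjects, `[[`, "", "subject_id")
  domains <- study$cfg$domains[cfg$networks]

  # -- stats ---------------------------------------------------------------
  if ("stats" %in% stages) {
    stats_dir <- file.path(cfg$out_dir, "stats")
    if (!dir.exists(stats_dir)) dir.create(stats_dir)
    result$stats <- run_stage("stats", function(skip_io) {
      out <- list()
      for (j in seq_along(cfg$networks)) {
        k <- cfg$networks[j]
        tm <- lapply(subject_maps, function(m) time_mean(m[[j]]))
        td <- lapply(subject_maps, function(m) temporal_deviation(m[[j]]))
        res_k <- list()
        for (kindset in list(list(tag = "mean", maps = tm),
                             list(tag = "deviation", maps = td))) {
          gc_maps <- kindset$maps[groups == "control"]
          gs_maps <- kindset$maps[groups == "patient"]
          gmc <- subject_mean(gc_maps)
          gms <- subject_mean(gs_maps)
          tt <- voxelwise_ttest(gc_maps, gs_maps, mask = mask)
          dm <- difference_map(gmc, gms)
          peaks <- collect_peak_values(
            select_peaks(dm, mask),
            tibble(subject_id = ids, group = groups, map = kindset$maps))
          if (!skip_io) {
            base <- file.path(stats_dir, sprintf("net%02d_%s", k, kindset$tag))
            write_nifti_vol(unclass(gmc), paste0(base, "_control.nii.gz"))
            write_nifti_vol(unclass(gms), paste0(base, "_patient.nii.gz"))
            write_nifti_vol(unclass(tt$t), paste0(base, "_tmap.nii.gz"))
            write_nifti_vol(unclass(dm), paste0(base, "_diff.nii.gz"))
            if (!is.null(peaks$values)) {
              utils::write.csv(as.data.frame(peaks$values),
                               paste0(base, "_peaks.csv"), row.names = FALSE)
            }
          }
          res_k[[kindset$tag]] <- list(group_control = gmc, group_patient = gms,
                                       ttest = tt, difference = dm,
                                       peaks = peaks)
        }
        out[[paste0("net", k)]] <- res_k
      }
      out
    })
    result$stats_dir <- file.path(cfg$out_dir, "stats")
  }

  # -- fnc -----------------------------------------------------------------
  if ("fnc" %in% stages) {
    fnc_dir <- file.path(cfg$out_dir, "fnc")
    if (!dir.exists(fnc_dir)) dir.create(fnc_dir)
    result$fnc <- run_stage("fnc", function(skip_io) {
      sfnc <- lapply(seq_along(subject_maps), function(i) {
        sfnc_matrix(subject_maps[[i]], mask = mask, domains = domains,
                    subject_id = ids[i])
      })
      test <- fnc_group_test(sfnc[groups == "control"],
                             sfnc[groups == "patient"], q = cfg$fdr_q)
      dfnc <- lapply(seq_along(subject_maps), function(i) {
        dfnc_windows(subject_maps[[i]], cfg$window, mask = mask,
                     domains = domains, subject_id = ids[i])
      })
      states <- fit_states(dfnc, seed = derive_seed(cfg$seed, 99L))
      occupancy <- dplyr::bind_rows(lapply(seq_along(dfnc), function(i) {
        or <- occupancy_ratio(assign_states(dfnc[[i]], states),
                              states$k_states)
        dplyr::bind_cols(tibble(subject_id = ids[i], group = groups[i]),
                         as_tibble(setNames(as.list(or),
                                            paste0("state_", seq_along(or)))))
      }))
      if (!skip_io) {
        for (i in seq_along(sfnc)) {
          write_fnc_csv(sfnc[[i]], file.path(fnc_dir,
                                             paste0(ids[i], "_sfnc.csv")))
        }
        utils::write.csv(as.data.frame(tidy(test)),
                         file.path(fnc_dir, "fnc_group_test.csv"),
                         row.names = FALSE)
        write_state_model(states, file.path(fnc_dir, "states.json"))
        utils::write.csv(as.data.frame(occupancy),
                         file.path(fnc_dir, "occupancy.csv"),
                         row.names = FALSE)
      }
      list(sfnc = sfnc, group_test = test, states = states,
           occupancy = occupancy)
    })
    result$fnc_dir <- file.path(cfg$out_dir, "fnc")
  }

  # run manifest: enough to re-run deterministic stages bit-identically
  jsonlite::write_json(
    list(seed = cfg$seed,
         config_hash = pipeline_hash(cfg, "all"),
         stages = stages,
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("spatiodyn"))),
    file.path(cfg$out_dir, "run_manifest.json"), auto_unbox = TRUE)
  result$run_manifest <- file.path(cfg$out_dir, "run_manifest.json")
  class(result) <- "study_result"
  result
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Sections `synth`, `model`, `train`, `window` map onto the corresponding
#' constructors; remaining top-level fields are passed to
#' [pipeline_config()].
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @param out_dir,seed Optional overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist", path))
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$synth$grid_dims)) raw$synth$grid_dims <- unlist(raw$synth$grid_dims)
  synth <- do.call(synth_config, raw$synth %||% list())
  args <- list(
    synth = synth,
    out_dir = out_dir %||% raw$out_dir %||% abort("config needs an out_dir"),
    model = do.call(model_spec, raw$model %||% list()),
    train = do.call(train_config, raw$train %||% list()),
    window = do.call(window_spec, raw$window %||% list())
  )
  for (f in c("fdr_q", "mask_level", "networks", "use_truth_maps", "log_level")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  args$seed <- seed %||% raw$seed %||% 1L
  do.call(pipeline_config, args)
}
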