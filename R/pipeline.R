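# Pipeline driver: one entry point chaining simulate -> preprocess -> train
# -> predict/fuse -> evaluate -> extract, with a validated configuration, a
# global seed, and a manifest recording everything needed to reproduce a
# run.  A thin command-line wrapper around run_pipeline() is installed at
# inst/cli/sbfseg.R.

#' Default pipeline configuration
#'
#' Nested parameter blocks for every stage.  `demo` scale (the default) runs
#' the whole loop on small synthetic volumes in minutes on a laptop CPU;
#' acquisition scale uses 256-cubes and the full-width network.
#'
#' @return A named list of parameter blocks.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "sbfseg-run",
    simulate = list(n_phantoms = 5L, cube_side = 64L, stages = 1:5,
                    anisotropy_factor = 2L),
    preprocess = list(side = 64L, sigma_spatial = 2, sigma_range = NULL),
    network = list(base_channels = 8L, depth = 4L, input_side = 64L,
                   attention = TRUE, batch_norm = TRUE,
                   upsample = "transposed"),
    train = list(base_lr = 1e-5, lr_decay_per_epoch = 0.95, epochs = 5L,
                 batch_size = 8L, tversky_alpha = 0.3, tversky_beta = 0.7,
                 weight_decay = 0.01, section_step = 4L),
    predict = list(directions = 3L, denoise_radius = 1L),
    extract = list(n_cells = 3L, scene_shape = c(64L, 96L, 96L),
                   min_gap = 6L, cell_radius = 11L,
                   min_seed_distance = 10, margin = 4L)
  )
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML configuration and merges it over the defaults.  Unknown keys
#' (at block or leaf level) are rejected with a field-level message so typos
#' never silently fall back to defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A validated configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  validate_keys(user, cfg, "config")
  modifyList(cfg, user)
}

validate_keys <- function(user, template, where) {
  unknown <- setdiff(names(user), names(template))
  if (length(unknown))
    stop(sprintf("unknown %s key(s): %s", where,
                 paste(unknown, collapse = ", ")))
  for (nm in names(user))
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])))
      validate_keys(as.list(user[[nm]]), template[[nm]],
                    paste0(where, "$", nm))
  invisible(TRUE)
}

#' Run a pipeline stage
#'
#' Commands: `"simulate"` (phantom volumes + labels + manifest),
#' `"train"` (simulate, preprocess, train; writes a checkpoint),
#' `"predict"` (multi-directional inference + fusion on a held-out phantom),
#' `"evaluate"` (per-class IoU of the prediction), `"extract"` (multi-cell
#' scene -> per-cell crops), and `"demo"` (all of the above in sequence).
#' Every stage is deterministic given the config seed; a manifest recording
#' the configuration, package version, per-stage timings and output file
#' hashes is written to the output directory.
#'
#' @param command One of simulate, train, predict, evaluate, extract, demo.
#' @param config A configuration list from [read_pipeline_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(command = c("demo", "simulate", "train", "predict",
                                     "evaluate", "extract"),
                         config = default_pipeline_config()) {
  command <- match.arg(command)
  validate_keys(config, default_pipeline_config(), "config")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(command = command, config = config,
                   package_version = as.character(utils::packageVersion("sbfseg")),
                   r_version = R.version.string,
                   timings = list(), outputs = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- force(expr)
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    r
  }

  stages <- switch(command,
    demo = c("simulate", "train", "predict", "evaluate", "extract"),
    command)
  env <- new.env()

  if ("simulate" %in% stages) {
    t_stage("simulate", {
      sim <- config$simulate
      env$phantoms <- lapply(seq_len(sim$n_phantoms), function(i) {
        st <- sim$stages[((i - 1L) %% length(sim$stages)) + 1L]
        ph <- generate_phantom(phantom_spec(stage = st,
                                            cube_side = sim$cube_side,
                                            seed = config$seed + i))
        pth <- file.path(out_dir, sprintf("phantom_%02d.tif", i))
        write_stack(ph$raw, pth)
        write_stack(ph$labels, file.path(out_dir,
                                         sprintf("phantom_%02d_labels.tif", i)))
        c(ph, list(stage = st, path = pth))
      })
      manifest$outputs$phantoms <- vapply(env$phantoms, `[[`, "", "path")
    })
  }
  if ("train" %in% stages) {
    t_stage("train", {
      if (is.null(env$phantoms)) stop("train requires simulated phantoms")
      tr <- config$train
      nw <- config$network
      pairs <- lapply(env$phantoms, function(ph)
        list(raw = normalize_volume(resize_to_cube(ph$raw, nw$input_side)),
             labels = resize_to_cube(ph$labels, nw$input_side)))
      sections <- augment_training_set(pairs, step = tr$section_step)
      net <- build_network(network_config(
        input_side = nw$input_side, base_channels = nw$base_channels,
        depth = nw$depth, attention = nw$attention,
        batch_norm = nw$batch_norm, upsample = nw$upsample),
        seed = config$seed)
      tc <- train_config(base_lr = tr$base_lr,
                         lr_decay_per_epoch = tr$lr_decay_per_epoch,
                         epochs = tr$epochs, batch_size = tr$batch_size,
                         tversky_alpha = tr$tversky_alpha,
                         tversky_beta = tr$tversky_beta,
                         weight_decay = tr$weight_decay, seed = config$seed)
      fit <- train_network(net, sections, config = tc)
      env$network <- fit$network
      ckpt <- file.path(out_dir, "network.rds")
      save_network(fit$network, ckpt)
      utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                       row.names = FALSE)
      manifest$outputs$checkpoint <- ckpt
    })
  }
  if ("predict" %in% stages) {
    t_stage("predict", {
      if (is.null(env$network)) stop("predict requires a trained network")
      pd <- config$predict
      held <- generate_phantom(phantom_spec(
        stage = 3L, cube_side = config$simulate$cube_side,
        seed = config$seed + 1000L))
      v <- normalize_volume(resize_to_cube(held$raw,
                                           config$network$input_side))
      env$truth <- resize_to_cube(held$labels, config$network$input_side)
      if (pd$directions >= 3L) {
        fused <- fuse_directions(infer_direction(env$network, v, "z"),
                                 infer_direction(env$network, v, "y"),
                                 infer_direction(env$network, v, "x"))
      } else {
        pz <- infer_direction(env$network, v, "z")
        fused <- fuse_directions(pz, pz, pz)
      }
      if (pd$denoise_radius >= 1L)
        fused <- denoise_labels(fused, pd$denoise_radius)
      env$prediction <- fused
      pth <- file.path(out_dir, "prediction.tif")
      write_stack(fused, pth)
      manifest$outputs$prediction <- pth
    })
  }
  if ("evaluate" %in% stages) {
    t_stage("evaluate", {
      if (is.null(env$prediction)) stop("evaluate requires a prediction")
      metrics <- evaluate_volume(env$prediction, env$truth)
      pth <- file.path(out_dir, "metrics.csv")
      utils::write.csv(metrics, pth, row.names = FALSE)
      manifest$outputs$metrics <- pth
      manifest$mean_foreground_iou <- mean_iou(metrics)
    })
  }
  if ("extract" %in% stages) {
    t_stage("extract", {
      ex <- config$extract
      scene <- generate_scene(scene_spec(
        n_cells = ex$n_cells, volume_shape = ex$scene_shape,
        min_gap = ex$min_gap, cell_radius = ex$cell_radius,
        seed = config$seed + 2000L))
      res <- extract_pipeline(scene$raw,
                              min_seed_distance = ex$min_seed_distance,
                              margin = ex$margin)
      for (cr in res$crops)
        write_stack(cr$volume,
                    file.path(out_dir, sprintf("cell_%02d.tif", cr$instance)))
      manifest$outputs$cells <- sprintf("cell_%02d.tif",
                                        seq_along(res$crops))
      manifest$extract <- res$manifest[c("n_cells", "params", "masker")]
    })
  }

  tifs <- list.files(out_dir, pattern = "\\.(tif|csv|rds)$", full.names = TRUE)
  manifest$hashes <- as.list(tools::md5sum(tifs))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
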