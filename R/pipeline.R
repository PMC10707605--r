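#' Pipeline configuration
#'
#' One nested configuration drives the whole workflow (generate -> train ->
#' assign -> validate -> select -> map).  Two profiles are shipped:
#'
#' * `"full"` — the full-scale recipe: 64 px patches (15000 of them), 3000
#'   epochs, Adadelta at learning rate 0.003, batch 100, loss weights
#'   `(0.1, 0.03, 0.03)`, cluster-count sweep 8-18.
#' * `"desk"` — a laptop-scale profile with the same objective: 600 patches
#'   of 32 px from 4 classes, the reduced model, 300 epochs, unit Adadelta
#'   step, sweep 3-5.  This is the configuration exercised by the test
#'   suite.
#'
#' @param profile `"desk"` (default) or `"full"`.
#' @param seed global integer seed; all stage seeds derive from it.
#' @return A `pipeline_config` nested list.
#' @export
pipeline_config <- function(profile = c("desk", "full"), seed = 1L) {
  profile <- match.arg(profile)
  desk <- profile == "desk"
  structure(list(
    profile = profile,
    seed = as.integer(seed),
    synthdata = list(
      n_classes = 4L,
      n_patches = if (desk) 600L else 15000L,
      patch_size = if (desk) 32L else 64L,
      n_stains = 5L,
      separation = 1,
      noise_sd = 0.05
    ),
    model = list(
      input_rescale = if (desk) 8L else NULL,
      channel_plan = if (desk) c(8L, 16L) else c(45L, 128L, 128L),
      upper_dim = if (desk) 32L else 196L,
      classifier_hidden = if (desk) 32L else 128L,
      leaky_slope = 0.1
    ),
    losses = list(lambda_me = 0.1, lambda_ce = 0.03, lambda_af = 0.03),
    affine = list(angle_deg = c(-30, 30), shift_frac = c(-0.1, 0.1),
                  scale = c(0.9, 1.1)),
    training = list(
      epochs = if (desk) 300L else 3000L,
      batch_size = 100L,
      learning_rate = if (desk) 1.0 else 0.003,
      rho = 0.95,
      epsilon = 1e-6
    ),
    validation = list(
      cluster_sets = if (desk) 3:5 else 8:18,
      feature_space = "upper"
    ),
    wsi = list(height_px = if (desk) 256L else 15000L,
               width_px = if (desk) 256L else 20000L,
               tile_size = if (desk) 32L else 128L),
    viz = list(px_per_tile = 4L, embed_max_n = 600L)
  ), class = "pipeline_config")
}

# Recursively check that `cfg` introduces no keys outside `ref`.
check_config_keys <- function(cfg, ref, path = "") {
  for (k in names(cfg)) {
    here <- if (path == "") k else paste0(path, "$", k)
    if (!k %in% names(ref))
      abort(sprintf("unknown configuration key: %s", here))
    if (is.list(cfg[[k]]) && is.list(ref[[k]]))
      check_config_keys(cfg[[k]], ref[[k]], here)
  }
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys fail fast with the offending path; missing keys take their
#' profile defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  profile <- raw$profile %||% "desk"
  base <- pipeline_config(profile, seed = raw$seed %||% 1L)
  check_config_keys(raw, base)
  out <- utils::modifyList(base, raw)
  structure(out, class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#'
#' `read_pipeline_config(write_pipeline_config(cfg, path))` restores the
#' configuration exactly.
#'
#' @param config a `pipeline_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_model_config <- function(config, n_clusters) {
  m <- config$model
  model_config(n_clusters,
               in_channels = 3L * config$synthdata$n_stains,
               input_size = config$synthdata$patch_size,
               input_rescale = m$input_rescale,
               channel_plan = m$channel_plan, upper_dim = m$upper_dim,
               classifier_hidden = m$classifier_hidden,
               leaky_slope = m$leaky_slope)
}

pipeline_train_config <- function(config, n_clusters, seed) {
  t <- config$training
  train_config(n_clusters, epochs = t$epochs, batch_size = t$batch_size,
               learning_rate = t$learning_rate, rho = t$rho,
               epsilon = t$epsilon,
               weights = do.call(loss_weights, config$losses),
               affine = do.call(affine_ranges, config$affine),
               seed = seed)
}

#' Run the full pipeline
#'
#' Generates the synthetic dataset, trains one model per candidate cluster
#' count, assigns clusters, scores the six validity indices per candidate,
#' selects the optimum per index, aggregates by vote, embeds the winning
#' model's features in 2-D, and renders a cluster map of a synthetic tiled
#' slide.  Every artifact lands under `out_dir`; a manifest records seeds
#' and versions.  Re-running with an identical configuration reproduces the
#' validity table byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print stage progress.
#' @return A `pipeline_result`: list with `vote`, `selection`, `validity`,
#'   `fits` (glance tibble per candidate), and `paths` of the artifacts.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  sd <- config$synthdata
  spec <- synth_spec(sd$n_classes, sd$n_patches, sd$patch_size, sd$n_stains,
                     sd$separation, sd$noise_sd, seed = config$seed)
  say("generating %d synthetic patches", sd$n_patches)
  dataset <- generate_patch_dataset(spec)
  paths <- list(dataset = file.path(out_dir, "dataset.tiff"))
  write_patchset(dataset, paths$dataset)

  validity <- list()
  glances <- list()
  states <- list()
  embeddings <- list()
  assigns <- list()
  for (nc in config$validation$cluster_sets) {
    say("training with n_c = %d", nc)
    tc <- pipeline_train_config(config, nc, seed = config$seed)
    fit <- train_imclust(dataset, tc,
                         model = pipeline_model_config(config, nc))
    ckpt <- file.path(out_dir, sprintf("model_nc%02d.rds", nc))
    save_network(fit$state, ckpt)
    utils::write.csv(fit$history,
                     file.path(out_dir, sprintf("history_nc%02d.csv", nc)),
                     row.names = FALSE)
    asg <- assign_clusters(fit$state, dataset)
    emb <- encode(dataset, fit$state)
    feats <- if (config$validation$feature_space == "lower") asg$soft else emb
    # indices require every id in [0, K) non-empty; score the realized
    # partition (consecutively relabelled) under this candidate's tag
    realized <- match(asg$labels, sort(unique(asg$labels))) - 1L
    validity[[as.character(nc)]] <-
      compute_validity(feats, realized, cluster_set = nc,
                       dataset = config$profile)
    glances[[as.character(nc)]] <- glance(fit)
    states[[as.character(nc)]] <- fit$state
    embeddings[[as.character(nc)]] <- emb
    assigns[[as.character(nc)]] <- asg
  }
  validity <- bind_rows(validity)
  paths$validity <- file.path(out_dir, "validity_table.csv")
  write_validity_table(validity, paths$validity)

  selection <- select_optimal(validity)
  vote <- vote_optimal(selection)
  paths$selection <- file.path(out_dir, "selection.csv")
  utils::write.csv(selection, paths$selection, row.names = FALSE)
  say("vote: K = %d with %d votes", vote$mode_k, vote$n_votes)

  best <- as.character(vote$mode_k)
  emb <- embeddings[[best]]
  n_embed <- min(nrow(emb), config$viz$embed_max_n)
  coords <- embed_2d(emb[seq_len(n_embed), , drop = FALSE],
                     seed = config$seed)
  paths$embedding <- file.path(out_dir, "embedding_2d.csv")
  utils::write.csv(
    data.frame(x = coords[, 1], y = coords[, 2],
               cluster = assigns[[best]]$labels[seq_len(n_embed)]),
    paths$embedding, row.names = FALSE)

  say("rendering synthetic slide map")
  wspec <- synth_wsi_spec(config$wsi$height_px, config$wsi$width_px,
                          config$wsi$tile_size)
  wsi <- generate_synthetic_wsi(wspec, spec)
  tiles <- cut_tiles(wsi$image, wsi$tile_size)
  grid <- tile_grid(config$wsi$height_px, config$wsi$width_px,
                    config$wsi$tile_size)
  map <- build_cluster_map(grid,
                           assign_clusters(states[[best]], tiles)$labels)
  paths$map <- file.path(out_dir, "cluster_map.png")
  write_cluster_map_png(map, paths$map, config$viz$px_per_tile)
  paths$histogram <- file.path(out_dir, "cluster_histogram.csv")
  utils::write.csv(map$histogram, paths$histogram, row.names = FALSE)

  paths$config <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, paths$config)
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(seed = config$seed, profile = config$profile,
         cluster_sets = config$validation$cluster_sets,
         selected_k = vote$mode_k,
         package_version = as.character(utils::packageVersion("stainclust")),
         r_version = R.version.string),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE)

  structure(list(vote = vote, selection = selection, validity = validity,
                 fits = bind_rows(glances), map = map, paths = paths),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> selected K = %d (%d of %d votes); %d artifacts\n",
              x$vote$mode_k, x$vote$n_votes, sum(x$vote$votes$n),
              length(x$paths)))
  invisible(x)
}
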