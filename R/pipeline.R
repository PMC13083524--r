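#' Desk-scale backbone specification
#'
#' A small instance of the same architecture family as
#' [reference_backbone_spec()] (stem, strided UIBs, one removable block,
#' 1x1 head) sized for 64-pixel patches and a 32-dimensional feature
#' space, used for synthetic-cohort experiments.
#'
#' @param feature_dim head width / output feature dimension.
#' @param input_size square patch side in pixels.
#' @return A [backbone_spec()].
#' @export
tiny_backbone_spec <- function(feature_dim = 32L, input_size = 64L) {
  backbone_spec(8L, list(
    uib_spec(8L, 16L, 2, 2L, pre_dw = TRUE, mid_dw = TRUE),
    uib_spec(16L, 32L, 2, 2L, pre_dw = FALSE, mid_dw = TRUE),
    uib_spec(32L, 32L, 2, 1L, pre_dw = FALSE, mid_dw = TRUE)
  ), feature_dim, input_size = input_size)
}

pipeline_defaults <- function() {
  list(
    out = NULL,
    seed = 1L,
    cohort = list(),
    inputs = list(),
    tiling = list(patch_size = 256L, min_tissue = 0.90, max_budget = 64L,
                  policy = "top_tissue"),
    genes = list(alpha = 0.01, latent_dim = 32L, pseudocount = 1,
                 epochs = 80L, lr = 1e-2, hidden = 64L),
    model = list(feature_dim = 32L, heads = 2L, landmarks = 8L,
                 self_only = FALSE),
    backbone = list(preset = "tiny"),
    training = list(epochs = 12L, lr = 1e-3, weight_decay = 1e-2,
                    test_frac = 0.2, freeze_backbone = FALSE),
    analysis = list(alpha = 0.01, n_perm = 999L, mechanism = "self_gene")
  )
}

merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(defaults)) {
      stop(sprintf("unknown configuration key: %s%s", path, k))
    }
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], as.list(user[[k]]),
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML run configuration, applies defaults, rejects unknown keys
#' (listing each) and checks that any referenced input files exist.
#'
#' @param path YAML file path, or a list already in memory.
#' @return A fully populated `run_config`.
#' @export
validate_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(user)) user <- list()
  cfg <- merge_config(pipeline_defaults(), user)
  # free-form sections validated by their constructors
  cfg$cohort <- do.call(synthetic_cohort_config,
                        c(cfg$cohort,
                          if (!"seed" %in% names(cfg$cohort))
                            list(seed = cfg$seed)))
  missing <- character(0)
  for (k in names(cfg$inputs)) {
    if (!file.exists(cfg$inputs[[k]])) missing <- c(missing, cfg$inputs[[k]])
  }
  if (length(missing) > 0L) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

# polynomial rolling hash (exact in doubles below 2^53)
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

config_hash <- function(cfg) {
  fnv1a(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                         force = TRUE))
}

log_jsonl <- function(path, event, ...) {
  rec <- c(list(event = event), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = path, append = TRUE)
}

write_num_csv <- function(df, path) {
  # fixed significant-digit formatting so determinism-mode reruns are
  # byte-identical
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- sprintf("%.10g", df[[j]])
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

stage_done <- function(run_dir, stage) {
  file.exists(file.path(run_dir, paste0(".done_", stage)))
}

mark_done <- function(run_dir, stage) {
  file.create(file.path(run_dir, paste0(".done_", stage)))
}

#' Run the full pipeline behind one configuration
#'
#' Stages: `simulate` (synthetic cohort), `tile` (bags), `genes`
#' (latents), `train` (end-to-end fit on the train split), `eval`
#' (metrics CSV on the held-out split) and `explain` (gene-set attention
#' significance CSV plus spatial attention heatmap and top-patch PNGs for
#' one held-out patient per class). Completed stages are skipped on rerun unless
#' `force = TRUE`; a provenance manifest (config hash, seed, package
#' version) and a JSONL log are written into the run directory. With an
#' identical configuration and seed, reruns produce byte-identical metrics
#' and significance CSVs.
#'
#' @param config a [validate_config()] result (or a path to one).
#' @param stages subset of stages to run (dependencies must already be
#'   satisfied on disk or included earlier in the vector).
#' @param force rerun stages whose outputs already exist.
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "tile", "genes", "train",
                                    "eval", "explain"),
                         force = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  if (is.null(config$out)) stop("config$out (run directory) is required")
  run_dir <- config$out
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(run_dir, "run_log.jsonl")
  state_path <- file.path(run_dir, "state.rds")
  state <- if (file.exists(state_path)) readRDS(state_path) else list()
  all_stages <- c("simulate", "tile", "genes", "train", "eval", "explain")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  deps <- list(simulate = character(0), tile = "simulate",
               genes = "simulate", train = c("tile", "genes"),
               eval = "train", explain = "train")
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("dualmil")))
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (st in all_stages[all_stages %in% stages]) {
    for (d in deps[[st]]) {
      if (!stage_done(run_dir, d)) {
        stop(sprintf("stage '%s' requires completed stage '%s'", st, d))
      }
    }
    if (stage_done(run_dir, st) && !force) {
      log_jsonl(logf, "skip", stage = st)
      next
    }
    log_jsonl(logf, "start", stage = st)
    state <- run_stage(st, config, state, run_dir)
    saveRDS(state, state_path)
    mark_done(run_dir, st)
    log_jsonl(logf, "done", stage = st)
  }
  invisible(run_dir)
}

run_stage <- function(stage, config, state, run_dir) {
  seed <- config$seed
  if (stage == "simulate") {
    state$cohort <- simulate_cohort(config$cohort,
                                    dir = file.path(run_dir, "cohort"))
  } else if (stage == "tile") {
    tl <- config$tiling
    state$bagging <- build_patch_bags(state$cohort$slides,
                                      state$cohort$labels,
                                      patch_size = tl$patch_size,
                                      min_tissue = tl$min_tissue,
                                      max_budget = tl$max_budget,
                                      policy = tl$policy,
                                      seed = seed_mix(seed, 2))
    manifest <- do.call(rbind, lapply(state$bagging$bags, function(b) {
      data.frame(patient_id = b$patient_id,
                 row = vapply(b$patches, function(p) p$row_index, integer(1)),
                 col = vapply(b$patches, function(p) p$col_index, integer(1)),
                 tissue_fraction = vapply(b$patches,
                                          function(p) p$tissue_fraction,
                                          numeric(1)))
    }))
    write_num_csv(manifest, file.path(run_dir, "bag_manifest.csv"))
  } else if (stage == "genes") {
    g <- config$genes
    state$genes <- gene_branch(state$cohort$counts,
                               state$cohort$gene_lengths,
                               state$cohort$gene_sets,
                               alpha = g$alpha, latent_dim = g$latent_dim,
                               epochs = g$epochs, lr = g$lr,
                               hidden = g$hidden,
                               seed = seed_mix(seed, 3))
  } else if (stage == "train") {
    m <- config$model
    bspec <- if (identical(config$backbone$preset, "tiny")) {
      tiny_backbone_spec(m$feature_dim, config$tiling$patch_size)
    } else if (identical(config$backbone$preset, "reference_reduced")) {
      reference_backbone_spec("reduced")
    } else {
      stop("unknown backbone preset: ", config$backbone$preset)
    }
    backbone <- build_backbone(bspec, seed = seed_mix(seed, 4))
    model <- mil_model(mil_config(m$feature_dim, m$heads, m$landmarks,
                                  m$self_only), seed = seed_mix(seed, 5))
    state$split <- make_splits(state$cohort$labels,
                               seed = seed_mix(seed, 6),
                               test_frac = config$training$test_frac)
    tr <- config$training
    fit <- train_model(model, backbone, state$bagging$bags,
                       state$genes$latents, state$cohort$labels,
                       patient_ids = state$split$train_ids,
                       epochs = tr$epochs, lr = tr$lr,
                       weight_decay = tr$weight_decay,
                       seed = seed_mix(seed, 7),
                       freeze_backbone = tr$freeze_backbone)
    state$model <- fit$model
    state$backbone <- fit$backbone
    state$loss_trace <- fit$loss_trace
    write_num_csv(data.frame(epoch = seq_along(fit$loss_trace),
                             loss = fit$loss_trace),
                  file.path(run_dir, "loss_trace.csv"))
  } else if (stage == "eval") {
    pred <- predict_model(state$model, state$backbone, state$bagging$bags,
                          state$genes$latents, state$split$test_ids)
    y <- unname(state$cohort$labels[pred$patient_id])
    mets <- evaluate_predictions(y, pred$prob1)
    write_num_csv(pred, file.path(run_dir, "predictions.csv"))
    write_num_csv(data.frame(metric = names(mets),
                             value = unlist(mets)),
                  file.path(run_dir, "metrics.csv"))
    state$metrics <- mets
  } else if (stage == "explain") {
    an <- config$analysis
    tab <- collect_attention(state$model, state$backbone,
                             state$bagging$bags, state$genes$latents,
                             state$cohort$labels,
                             patient_ids = state$split$test_ids,
                             mechanism = an$mechanism)
    sig <- significance_analysis(tab, alpha = an$alpha, n_perm = an$n_perm,
                                 seed = seed_mix(seed, 8))
    write_num_csv(sig, file.path(run_dir, "significance.csv"))
    state$significance <- sig
    state$attention <- tab
    # spatial attention rendering for one patient per class
    hm_dir <- file.path(run_dir, "heatmaps")
    dir.create(hm_dir, showWarnings = FALSE)
    labs <- state$cohort$labels[state$split$test_ids]
    show_ids <- c(state$split$test_ids[match(0L, labs)],
                  state$split$test_ids[match(1L, labs)])
    for (p in show_ids[!is.na(show_ids)]) {
      bag <- state$bagging$bags[[p]]
      feats <- backbone_forward(state$backbone,
                                ag_const(bag_to_array(bag)))$value
      out <- forward_patient(state$model, feats,
                             state$genes$latents[[p]]$features)
      for (mech in c("self_image", "cross_img_query_gene")) {
        rec <- Find(function(r) r$mechanism == mech, out$attention)
        hm <- render_heatmap(bag, rec,
                             c(state$cohort$config$slide_height,
                               state$cohort$config$slide_width))
        png::writePNG(hm$heatmap,
                      file.path(hm_dir, sprintf("%s_%s.png", p, mech)))
        top <- hm$top_patch
        tp <- Find(function(q) q$row_index == top[1] &&
                     q$col_index == top[2], bag$patches)
        png::writePNG(tp$image / 255,
                      file.path(hm_dir,
                                sprintf("%s_%s_top_patch.png", p, mech)))
      }
    }
  }
  state
}
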