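## Pipeline orchestration: one YAML config drives synth -> enhance ->
## augment -> train -> evaluate -> plan-edges -> simulate-loop, with
## per-stage seeds derived from one global seed.

pipeline_defaults <- function() {
  list(
    seed = 0L,
    out_dir = NULL,
    generator = list(n_cobra = 30L, n_other = 30L, size = 64L),
    preprocess = list(a = -0.3293, b = 1.1258, mu = 0.5),
    augment = list(rotate = TRUE, zoom = c(0.5, 1.0), mirror = FALSE, enabled = FALSE),
    train = list(epochs = 100L, lr = 0.001, epsilon = 1e-10, batch = 64L,
                 backbone = "tiny", split = c(0.8, 0.1, 0.1), input_side = 64L),
    planner = list(n_states = 5L, K = 20L, cost_per_node = 0.005,
                   method = "qpso", s = 30L, iterations = 60L, alpha = 0.7,
                   omega = 0.7, c1 = 1.5, c2 = 1.5),
    loop = list(rounds = 3L, cases_per_round = 6L, n_edges = 3L,
                init_per_class = 30L, test_per_class = 20L, image_size = 32L,
                epochs_init = 4L, epochs_round = 3L)
  )
}

merge_config <- function(defaults, user, path = character()) {
  fm_assert(is.list(user) || is.null(user), "config",
            "config section '%s' must be a mapping", paste(path, collapse = "."))
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      fm_stop("config", "unknown configuration key '%s'", full)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_pipeline_config <- function(cfg) {
  chk <- function(ok, key, why) {
    if (!isTRUE(ok)) fm_stop("config", "invalid value for '%s': %s", key, why)
  }
  chk(cfg$generator$n_cobra >= 0, "generator.n_cobra", "must be >= 0")
  chk(cfg$generator$n_other >= 0, "generator.n_other", "must be >= 0")
  chk(cfg$generator$size >= 32, "generator.size", "must be >= 32")
  chk(cfg$train$epochs >= 1, "train.epochs", "must be >= 1")
  chk(cfg$train$lr > 0 && cfg$train$lr < 1, "train.lr", "must lie in (0, 1)")
  chk(cfg$train$batch >= 1, "train.batch", "must be >= 1")
  chk(abs(sum(cfg$train$split) - 1) < 1e-8, "train.split", "fractions must sum to 1")
  chk(cfg$planner$K >= 1, "planner.K", "must be >= 1")
  chk(cfg$planner$alpha > 0 && cfg$planner$alpha <= 1, "planner.alpha",
      "must lie in (0, 1]")
  chk(cfg$loop$rounds >= 1, "loop.rounds", "must be >= 1")
  cfg
}

#' Load, default and validate a pipeline configuration
#'
#' The file is YAML; missing keys take the package defaults (training epochs
#' 100, learning rate 0.001, epsilon 1e-10, batch 64, QPSO
#' contraction-expansion alpha 0.7; augmentation rotation 90 degrees, zoom
#' 0.5-1.0); unknown keys are rejected by name. An empty file yields the
#' all-defaults configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
load_pipeline_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    fm_assert(file.exists(path), "config", "config file not found: %s", path)
    user <- tryCatch(yaml::read_yaml(path), error = function(e) {
      fm_stop("config", "cannot parse config '%s': %s", path, conditionMessage(e))
    })
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  validate_pipeline_config(cfg)
}

#' Run the full pipeline
#'
#' Executes all stages in order — synthesise, enhance, (optionally) augment,
#' train, evaluate, plan edge nodes, simulate the feedback loop — with
#' per-stage seeds derived from the global seed. Any stage failure aborts
#' with the stage name. When `config$out_dir` is set, metrics.json,
#' plan.json, rounds.csv and report.json are written there.
#'
#' @param config configuration from [load_pipeline_config()].
#' @return report list: `config`, `stages` (metrics, plan, rounds, ...).
#' @export
run_pipeline <- function(config = load_pipeline_config()) {
  config <- validate_pipeline_config(config)
  report <- list(config = config, stages = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      fm_stop("stage", "pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  g <- config$generator
  gcfg <- generator_config(size = g$size)
  dataset <- run_stage("synth",
    generate_dataset(g$n_cobra, g$n_other, gcfg, seed = stage_seed(config$seed, "synth")))
  epi <- run_stage("synth",
    generate_state_table(config$planner$n_states, seed = stage_seed(config$seed, "epi")))
  report$stages$synth <- list(n_images = length(dataset), n_states = nrow(epi))

  ecfg <- enhance_config(a = config$preprocess$a, b = config$preprocess$b,
                         mu = config$preprocess$mu)
  dataset <- run_stage("enhance", lapply(dataset, function(img) {
    img$pixels <- enhance(img$pixels, ecfg)
    img
  }))
  report$stages$enhance <- list(n_images = length(dataset))

  if (isTRUE(config$augment$enabled)) {
    acfg <- augment_config(rotate = config$augment$rotate, zoom = config$augment$zoom,
                           mirror = config$augment$mirror,
                           seed = stage_seed(config$seed, "augment"))
    dataset <- run_stage("augment", augment_dataset(dataset, acfg))
  }
  report$stages$augment <- list(enabled = isTRUE(config$augment$enabled),
                                n_images = length(dataset))

  t <- config$train
  tcfg <- train_config(epochs = t$epochs, lr = t$lr, epsilon = t$epsilon,
                       batch = t$batch, backbone = t$backbone,
                       seed = stage_seed(config$seed, "train") %% 100000L,
                       split = t$split, input_side = t$input_side)
  model <- run_stage("train", train_classifier(build_model(tcfg), dataset, tcfg))
  report$stages$train <- list(history = model$history)

  test_idx <- model$splits$test
  metrics <- run_stage("evaluate", {
    eval_set <- if (length(test_idx) >= 2) dataset[test_idx] else dataset
    evaluate_model(model, eval_set)
  })
  report$stages$metrics <- metrics

  p <- config$planner
  scfg <- swarm_config(s = p$s, iterations = p$iterations, omega = p$omega,
                       c1 = p$c1, c2 = p$c2, alpha = p$alpha,
                       seed = stage_seed(config$seed, "planner"))
  plan <- run_stage("plan-edges",
    plan_edges(epi, K = p$K, cost = p$cost_per_node, config = scfg,
               method = p$method))
  report$stages$plan <- plan

  l <- config$loop
  lcfg <- loop_config(rounds = l$rounds, cases_per_round = l$cases_per_round,
                      n_edges = l$n_edges, init_per_class = l$init_per_class,
                      test_per_class = l$test_per_class, image_size = l$image_size,
                      epochs_init = l$epochs_init, epochs_round = l$epochs_round,
                      seed = stage_seed(config$seed, "loop"))
  loop <- run_stage("simulate-loop", run_feedback_loop(lcfg))
  report$stages$rounds <- loop$rounds

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(lapply(plan, function(x) x[c("k_star", "profit", "delay")]),
                         file.path(config$out_dir, "plan.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(loop$rounds, file.path(config$out_dir, "rounds.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_summary(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

## presentation layer: percentages with one decimal, as in clinical reporting
report_summary <- function(report) {
  m <- report$stages$metrics
  list(
    seed = report$config$seed,
    n_images = report$stages$augment$n_images,
    metrics_percent = lapply(m[c("sensitivity", "specificity", "accuracy", "auc")],
                             function(v) round(100 * v, 1)),
    confusion = m[c("tp", "fn", "fp", "tn")],
    plan = lapply(report$stages$plan, function(x) x$k_star),
    final_accuracy = utils::tail(report$stages$rounds$accuracy, 1)
  )
}
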