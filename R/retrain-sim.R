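## Cloud-edge feedback-retraining loop.
##
## Edge nodes run the deployed classifier on incoming cases; predictions whose
## later-confirmed ground truth disagrees are sent back to the cloud, appended
## to the training dataset, and the model is retrained (warm start) and
## redeployed. The simulator tracks per-round misclassification counts,
## dataset growth, held-out accuracy, and mean hop delay.

#' Feedback-loop configuration
#'
#' @param rounds number of feedback rounds, >= 1.
#' @param cases_per_round new cases arriving at each edge per round, >= 0.
#' @param n_edges number of edge nodes, >= 1.
#' @param init_per_class initial cloud training images per class.
#' @param test_per_class held-out test images per class (disjoint seed stream
#'   from all feedback cases).
#' @param image_size generated image side for the simulation (desk scale).
#' @param epochs_init epochs for the initial cloud training.
#' @param epochs_round warm-start epochs per retraining round.
#' @param retrain if `FALSE` the model is frozen (isolates the feedback
#'   effect; the accuracy trajectory is then constant).
#' @param delay_constant hop-delay scale for the reported mean delay.
#' @param seed integer master seed.
#' @return a `loop_config`.
#' @export
loop_config <- function(rounds = 5L, cases_per_round = 10L, n_edges = 3L,
                        init_per_class = 40L, test_per_class = 40L,
                        image_size = 32L, epochs_init = 2L, epochs_round = 5L,
                        retrain = TRUE, delay_constant = 1, seed = 0L) {
  fm_assert(rounds >= 1, "config", "loop.rounds must be >= 1")
  fm_assert(cases_per_round >= 0, "config", "loop.cases_per_round must be >= 0")
  fm_assert(n_edges >= 1, "config", "loop.n_edges must be >= 1")
  structure(list(rounds = as.integer(rounds),
                 cases_per_round = as.integer(cases_per_round),
                 n_edges = as.integer(n_edges),
                 init_per_class = as.integer(init_per_class),
                 test_per_class = as.integer(test_per_class),
                 image_size = as.integer(image_size),
                 epochs_init = as.integer(epochs_init),
                 epochs_round = as.integer(epochs_round),
                 retrain = isTRUE(retrain), delay_constant = delay_constant,
                 seed = as.integer(seed)),
            class = "loop_config")
}

#' Classify one round of edge traffic and collect the misclassified cases
#'
#' Each case in the stream is classified by the deployed model; cases whose
#' confirmed true label differs from the prediction are returned with their
#' true labels (the paper's feedback rule: only wrong predictions travel back
#' to the cloud).
#'
#' @param model a trained `fang_model`.
#' @param stream list of `labeled_image` cases.
#' @return list with `predictions` (data.frame) and `misclassified` (list of
#'   `labeled_image` with confirmed labels).
#' @export
simulate_round <- function(model, stream) {
  fm_assert(isTRUE(model$trained), "loop", "model is untrained")
  if (length(stream) == 0) {
    return(list(predictions = data.frame(label = character(), score = numeric()),
                misclassified = list()))
  }
  pred <- predict(model, stream)
  truth <- vapply(stream, function(d) d$label, character(1))
  wrong <- which(pred$label != truth)
  list(predictions = pred, misclassified = stream[wrong])
}

#' Append confirmed misclassified cases to the cloud dataset
#'
#' Pure bookkeeping: the updated dataset is the old one plus every
#' misclassified case (with its confirmed true label); nothing is removed.
#'
#' @param cloud_dataset list of `labeled_image`.
#' @param misclassified list of `labeled_image` from [simulate_round()].
#' @return the grown dataset.
#' @export
feedback_update <- function(cloud_dataset, misclassified) {
  c(cloud_dataset, misclassified)
}

#' Run the cloud-edge feedback-retraining loop
#'
#' Trains an initial model on the cloud dataset, then alternates: each edge
#' classifies its round of fresh cases, misclassified cases (with confirmed
#' labels) are appended to the cloud dataset, and the model is retrained with
#' a warm start. Case streams, the held-out test set and the initial dataset
#' use disjoint seed streams, so the test set never contains feedback cases.
#'
#' @param config a [loop_config()].
#' @return list with `rounds` (data.frame: `round`, `edge_errors`,
#'   `dataset_size`, `accuracy`, `mean_delay`; round 0 is the pre-feedback
#'   baseline), the final `model`, and `config`.
#' @export
run_feedback_loop <- function(config = loop_config()) {
  fm_assert(inherits(config, "loop_config"), "config", "config must be a loop_config")
  gcfg <- generator_config(size = config$image_size)
  cloud <- generate_dataset(config$init_per_class, config$init_per_class, gcfg,
                            seed = stage_seed(config$seed, "loop-init"))
  test_set <- generate_dataset(config$test_per_class, config$test_per_class, gcfg,
                               seed = stage_seed(config$seed, "loop-test"))
  tcfg <- train_config(epochs = config$epochs_init, batch = 16L,
                       seed = stage_seed(config$seed, "loop-train") %% 100000L,
                       split = c(0.9, 0.1, 0.0), input_side = config$image_size)
  model <- build_model(tcfg)
  model <- train_classifier(model, cloud, tcfg)
  test_truth <- vapply(test_set, function(d) d$label, character(1))
  held_acc <- function(m) {
    accuracy(confusion(test_truth, predict(m, test_set)$label))
  }
  mean_delay <- delay(config$n_edges, config$delay_constant)
  logs <- list(data.frame(round = 0L, edge_errors = NA_integer_,
                          dataset_size = length(cloud), accuracy = held_acc(model),
                          mean_delay = mean_delay))
  for (r in seq_len(config$rounds)) {
    errors <- 0L
    wrong_all <- list()
    for (e in seq_len(config$n_edges)) {
      half <- config$cases_per_round %/% 2L
      stream <- generate_dataset(half, config$cases_per_round - half, gcfg,
                                 seed = stage_seed(config$seed,
                                                   sprintf("round%d-edge%d", r, e)))
      res <- simulate_round(model, stream)
      errors <- errors + length(res$misclassified)
      wrong_all <- c(wrong_all, res$misclassified)
    }
    cloud <- feedback_update(cloud, wrong_all)
    if (config$retrain && length(wrong_all) > 0) {
      rcfg <- tcfg
      rcfg$epochs <- config$epochs_round
      rcfg$seed <- stage_seed(config$seed, paste0("retrain", r)) %% 100000L
      model <- train_classifier(model, cloud, rcfg)   # warm start
    }
    logs[[r + 1L]] <- data.frame(round = r, edge_errors = errors,
                                 dataset_size = length(cloud),
                                 accuracy = held_acc(model),
                                 mean_delay = mean_delay)
  }
  list(rounds = do.call(rbind, logs), model = model, config = config)
}
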