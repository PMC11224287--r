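#' Partition samples into 10 folds with rotating roles
#'
#' Samples are shuffled with the given seed and dealt round-robin into 10
#' folds, so fold sizes differ by at most one.  Rotation r (r = 0..9) uses
#' fold r as the test fold, fold (r + 1) mod 10 as the early-stopping fold,
#' and the remaining eight folds for training; every fold is therefore the
#' test fold exactly once.
#'
#' @param n_samples Number of samples; must be at least `n_folds`.
#' @param seed Integer seed for the shuffle.
#' @param n_folds Number of folds (default 10).
#' @return A `fold_plan`: list with `n_samples`, `n_folds`, `fold_of`
#'   (integer vector mapping sample index to fold id 0..9), `rotations`
#'   (list of `train`/`earlystop`/`test` fold-id sets) and `seed`.
#' @examples
#' plan <- make_fold_plan(100, seed = 1)
#' table(plan$fold_of)
#' @export
make_fold_plan <- function(n_samples, seed, n_folds = 10L) {
  n_samples <- as.integer(n_samples)
  n_folds <- as.integer(n_folds)
  if (n_samples < n_folds) {
    stop(sprintf("need at least %d samples for %d-fold cross-validation, got %d",
                 n_folds, n_folds, n_samples), call. = FALSE)
  }
  set.seed(seed)
  shuffled <- sample.int(n_samples)
  fold_of <- integer(n_samples)
  fold_of[shuffled] <- (seq_len(n_samples) - 1L) %% n_folds
  rotations <- lapply(seq_len(n_folds) - 1L, function(r) {
    es <- (r + 1L) %% n_folds
    list(train = setdiff(seq_len(n_folds) - 1L, c(r, es)),
         earlystop = es,
         test = r)
  })
  structure(list(n_samples = n_samples, n_folds = n_folds,
                 fold_of = fold_of, rotations = rotations,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan: %d samples, %d folds, seed %d>\n",
              x$n_samples, x$n_folds, x$seed))
  print(table(fold = x$fold_of))
  invisible(x)
}

fold_indices <- function(plan, fold_ids) {
  which(plan$fold_of %in% fold_ids)
}

#' Train a model on one train/early-stop split
#'
#' Minimizes binary cross-entropy with Adam at the configuration's exact
#' hyperparameters, monitoring the loss on the held-out early-stopping set
#' after every epoch.  Training halts once that loss has failed to improve
#' by at least `min_delta` for `patience` consecutive epochs, and the
#' returned model carries the weights from the best early-stopping epoch
#' (never from a later one).
#'
#' @param model An untrained (or previously trained) `dsc_model`.
#' @param train An `encoded_dataset` for gradient updates.
#' @param earlystop An `encoded_dataset` monitored for early stopping;
#'   must be disjoint from `train`.
#' @param max_epochs Epoch budget.
#' @param batch_size Minibatch size (default 64).
#' @param patience Consecutive non-improving epochs tolerated (default 10).
#' @param min_delta Minimum loss improvement that resets patience
#'   (default 1e-4).
#' @param seed Integer seed driving minibatch shuffling and dropout masks.
#' @return A list with `model` (weights restored to the best epoch) and
#'   `history` (per-epoch `train_loss`, `train_acc`, `earlystop_loss`,
#'   plus `stopped_epoch`, `best_epoch` and `max_epochs`).
#' @export
train_fold <- function(model, train, earlystop, max_epochs = 10L,
                       batch_size = 64L, patience = 10L, min_delta = 1e-4,
                       seed = 1L) {
  stopifnot(inherits(model, "dsc_model"))
  if (length(train$y) == 0L) stop("empty training set", call. = FALSE)
  if (length(earlystop$y) == 0L) {
    stop("empty early-stopping set", call. = FALSE)
  }
  if (length(intersect(train$event_id, earlystop$event_id)) > 0L) {
    stop("train and early-stopping sets overlap", call. = FALSE)
  }
  cfg <- model$config
  opts <- list(max_epochs = as.integer(max_epochs),
               batch_size = as.integer(batch_size),
               patience = as.integer(patience),
               min_delta = min_delta,
               seed = as.double(seed),
               learning_rate = cfg$learning_rate,
               beta1 = cfg$beta1, beta2 = cfg$beta2,
               epsilon = cfg$epsilon, decay = cfg$decay)
  res <- cpp_train(cfg, model$weights,
                   train$x1, train$x2, as.matrix(train$x3),
                   as.double(train$y),
                   earlystop$x1, earlystop$x2, as.matrix(earlystop$x3),
                   as.double(earlystop$y), opts)
  model$weights <- res$weights
  model$trained <- TRUE
  history <- list(train_loss = as.numeric(res$train_loss),
                  train_acc = as.numeric(res$train_acc),
                  earlystop_loss = as.numeric(res$earlystop_loss),
                  stopped_epoch = res$stopped_epoch,
                  best_epoch = res$best_epoch,
                  max_epochs = as.integer(max_epochs))
  list(model = model, history = history)
}

#' 10-fold cross-validation with an early-stopping fold
#'
#' Runs the full evaluation protocol: the dataset is split into 10 folds;
#' in each of the 10 rotations a fresh model is built, trained on 8 folds
#' with 1 fold monitored for early stopping, and scored by AUC-ROC on the
#' held-out test fold.
#'
#' @param records A splice-event data.frame ([read_dataset()] /
#'   [generate_dataset()]).
#' @param config A [dsc_config()]; for `build_baseline` pass `NULL` to use
#'   the builder's own default stack.
#' @param max_epochs Epoch budget per rotation.
#' @param seed Single integer seed; drives the fold shuffle, per-rotation
#'   weight initialization, minibatch order and dropout.
#' @param model_builder [build_dsc] or [build_baseline].
#' @param batch_size,patience,min_delta Passed to [train_fold()].
#' @param verbose Print per-rotation progress to stderr.
#' @return An `evaluation_report` with 10 per-fold AUCs, their mean, and a
#'   `histories` attribute holding each rotation's training history.
#' @export
run_cv <- function(records, config = dsc_config(), max_epochs = 10L,
                   seed = 1L, model_builder = build_dsc, batch_size = 64L,
                   patience = 10L, min_delta = 1e-4, verbose = FALSE) {
  data <- if (inherits(records, "encoded_dataset")) records
          else encode_dataset(records)
  n <- length(data$y)
  plan <- make_fold_plan(n, seed = seed)
  fold_aucs <- numeric(plan$n_folds)
  histories <- vector("list", plan$n_folds)
  builder_name <- if (identical(model_builder, build_baseline)) "baseline"
                  else "dsc"
  for (r in seq_len(plan$n_folds)) {
    rot <- plan$rotations[[r]]
    tr <- subset_encoded(data, fold_indices(plan, rot$train))
    es <- subset_encoded(data, fold_indices(plan, rot$earlystop))
    te <- subset_encoded(data, fold_indices(plan, rot$test))
    rot_seed <- (seed * 131L + r) %% .Machine$integer.max
    model <- if (is.null(config)) model_builder(seed = rot_seed)
             else model_builder(config = config, seed = rot_seed)
    fit <- tryCatch(
      train_fold(model, tr, es, max_epochs = max_epochs,
                 batch_size = batch_size, patience = patience,
                 min_delta = min_delta, seed = rot_seed),
      error = function(e) {
        stop(sprintf("rotation %d: %s", r - 1L, conditionMessage(e)),
             call. = FALSE)
      })
    scores <- predict(fit$model, te)
    fold_aucs[r] <- tryCatch(
      auc_roc(te$y, scores),
      error = function(e) {
        stop(sprintf("rotation %d: %s", r - 1L, conditionMessage(e)),
             call. = FALSE)
      })
    histories[[r]] <- fit$history
    if (verbose) {
      message(sprintf("rotation %d/%d: test AUC %.4f (best epoch %d/%d)",
                      r, plan$n_folds, fold_aucs[r],
                      fit$history$best_epoch, fit$history$stopped_epoch))
    }
  }
  report <- summarize_folds(fold_aucs, model_name = builder_name,
                            epoch_budget = as.integer(max_epochs),
                            seed = as.integer(seed))
  attr(report, "histories") <- histories
  report
}

#' Compare model variants across epoch budgets
#'
#' Runs [run_cv()] once per epoch budget for both the DSC network and the
#' 6-hidden-layer reference network, and tabulates the mean cross-validated
#' AUC of each — the same comparison layout as the published epoch sweep
#' (10/50/100/150/200 epochs).
#'
#' @param records Splice-event records.
#' @param config A [dsc_config()] for the DSC variant; the baseline uses
#'   its own reference stack.
#' @param epochs_list Integer vector of epoch budgets.
#' @param seed Integer seed shared by all runs.
#' @param ... Passed on to [run_cv()].
#' @return A data.frame with columns `epochs`, `auc_baseline`, `auc_dsc`
#'   and a `reports` attribute holding the underlying
#'   `evaluation_report`s.
#' @export
epoch_sweep <- function(records, config = dsc_config(),
                        epochs_list = c(10L, 50L, 100L, 150L, 200L),
                        seed = 1L, ...) {
  if (length(epochs_list) == 0L) {
    stop("`epochs_list` must be non-empty", call. = FALSE)
  }
  data <- if (inherits(records, "encoded_dataset")) records
          else encode_dataset(records)
  reports <- list()
  rows <- lapply(epochs_list, function(ep) {
    base <- run_cv(data, config = NULL, max_epochs = ep, seed = seed,
                   model_builder = build_baseline, ...)
    dsc <- run_cv(data, config = config, max_epochs = ep, seed = seed,
                  model_builder = build_dsc, ...)
    reports[[as.character(ep)]] <<- list(baseline = base, dsc = dsc)
    data.frame(epochs = as.integer(ep),
               auc_baseline = base$mean_auc,
               auc_dsc = dsc$mean_auc)
  })
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}
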