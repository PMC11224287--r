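#' @useDynLib spliceDSC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm predict
NULL

# Temporal sizes along one branch: valid-padding stride-1 convolutions
# (L - k + 1) alternating with max pooling ((L - pool) %/% stride + 1).
# Errors name the first layer whose output would collapse below length 1.
branch_temporal_sizes <- function(cfg) {
  L <- cfg$seq_len
  sizes <- list()
  for (l in seq_along(cfg$branch_kernels)) {
    L_conv <- L - cfg$branch_kernels[l] + 1L
    if (L_conv < 1L) {
      stop(sprintf(
        "conv layer %d (kernel %d) reduces the temporal dimension to %d",
        l, cfg$branch_kernels[l], L_conv), call. = FALSE)
    }
    L_pool <- (L_conv - cfg$pool_size) %/% cfg$pool_stride + 1L
    if (L_pool < 1L) {
      stop(sprintf(
        "max-pooling after conv layer %d reduces the temporal dimension to %d",
        l, L_pool), call. = FALSE)
    }
    sizes[[l]] <- c(conv = L_conv, pool = L_pool)
    L <- L_pool
  }
  sizes
}

glorot_uniform <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

init_weights <- function(cfg) {
  w <- list()
  for (br in 1:2) {
    C_in <- cfg$n_channels
    for (l in seq_along(cfg$branch_filters)) {
      k <- cfg$branch_kernels[l]
      f <- cfg$branch_filters[l]
      w[[length(w) + 1L]] <- glorot_uniform(k * C_in, f, k * C_in, k * f)
      w[[length(w) + 1L]] <- numeric(f)
      C_in <- f
    }
  }
  sizes <- branch_temporal_sizes(cfg)
  T_final <- sizes[[length(sizes)]][["pool"]]
  F_final <- cfg$branch_filters[length(cfg$branch_filters)]
  D <- T_final * 2L * F_final + cfg$n_extra_features
  w[[length(w) + 1L]] <- glorot_uniform(D, cfg$dense_units, D, cfg$dense_units)
  w[[length(w) + 1L]] <- numeric(cfg$dense_units)
  w[[length(w) + 1L]] <- glorot_uniform(cfg$dense_units, 1L, cfg$dense_units, 1L)
  w[[length(w) + 1L]] <- numeric(1L)
  w
}

new_dsc_model <- function(cfg, variant, seed = NULL) {
  cfg <- validate_dsc_config(cfg)
  sizes <- branch_temporal_sizes(cfg)  # also validates the cascade
  if (!is.null(seed)) set.seed(seed)
  model <- list(
    variant = variant,
    config = cfg,
    temporal_sizes = sizes,
    weights = init_weights(cfg),
    trained = FALSE
  )
  class(model) <- "dsc_model"
  model
}

#' Build the dual-branch DSC classifier
#'
#' Constructs the 8-hidden-layer dual-branch convolutional network.  Each
#' branch processes one 140 x 4 one-hot sequence window through four blocks
#' of convolution (valid padding, stride 1), dropout, ReLU activation, and
#' max pooling — in exactly that order.  The two branch outputs are
#' concatenated along channels, flattened, joined with the three length
#' features, passed through a 1,024-unit ReLU dense layer with dropout 0.5,
#' and finally through a single sigmoid unit.
#'
#' With the default [dsc_config()] the per-layer output shapes and trainable
#' parameter counts are, per branch: conv layers with 232, 528, 1,568 and
#' 4,160 parameters and temporal lengths 134, 64, 30 and 14 (pooled to 67,
#' 32, 15 and 7); a flattened merge of length 896; 899 features after adding
#' the length inputs; and dense layers with 921,600 and 1,025 parameters.
#'
#' @param config A [dsc_config()] object.
#' @param seed Optional integer seed for weight initialization
#'   (Glorot-style uniform).
#' @return A `dsc_model` object holding the configuration, initialized
#'   weights and layer geometry.  Use [model_summary()] to inspect it,
#'   [train_fold()] or [run_cv()] to train it, and [predict()][
#'   predict.dsc_model] to score encoded events.
#' @examples
#' m <- build_dsc()
#' model_summary(m)
#' @seealso [build_baseline()] for the 6-hidden-layer reference network.
#' @export
build_dsc <- function(config = dsc_config(), seed = NULL) {
  new_dsc_model(config, variant = "dsc", seed = seed)
}

#' Build the 6-hidden-layer reference classifier
#'
#' Same dual-branch topology as [build_dsc()] but with three convolutional
#' layers per branch — filters 32, 8 and 8 with kernel widths 7, 4 and 3 —
#' dropout 0.2, and max pooling of size and stride 2, matching the earlier
#' architecture the DSC network is benchmarked against.
#'
#' @param config A [dsc_config()]; defaults to the reference stack.  Passing
#'   a config with different conv stacks overrides the reference layout.
#' @param seed Optional integer seed for weight initialization.
#' @return A `dsc_model` object with `variant = "baseline"`.
#' @examples
#' model_summary(build_baseline())
#' @export
build_baseline <- function(config = dsc_config(branch_filters = c(32L, 8L, 8L),
                                               branch_kernels = c(7L, 4L, 3L),
                                               conv_dropout = 0.2),
                           seed = NULL) {
  new_dsc_model(config, variant = "baseline", seed = seed)
}

#' Per-layer summary of a model
#'
#' One row per layer in construction order, mirroring the usual deep
#' learning model summary: layer name, output shape and trainable parameter
#' count.  Convolution parameters follow `kernel * in_channels * filters +
#' filters`; dense layers `in_features * units + units`; dropout, activation,
#' pooling, concatenation and flatten layers carry no weights.
#'
#' @param model A `dsc_model` from [build_dsc()] or [build_baseline()].
#' @return A `data.frame` with columns `layer`, `output_shape` (string) and
#'   `params` (integer), plus a `total_params` attribute.
#' @examples
#' s <- model_summary(build_dsc())
#' sum(s$params)
#' @export
model_summary <- function(model) {
  stopifnot(inherits(model, "dsc_model"))
  cfg <- model$config
  sizes <- model$temporal_sizes
  rows <- list()
  add <- function(layer, shape, params) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = layer,
      output_shape = paste0("(", paste(shape, collapse = ", "), ")"),
      params = as.integer(params),
      stringsAsFactors = FALSE)
  }
  for (br in 1:2) {
    add(sprintf("input_seq%d (InputLayer)", br),
        c(cfg$seq_len, cfg$n_channels), 0L)
  }
  add("input_lengths (InputLayer)", cfg$n_extra_features, 0L)
  for (l in seq_along(cfg$branch_filters)) {
    k <- cfg$branch_kernels[l]
    f <- cfg$branch_filters[l]
    C_in <- if (l == 1L) cfg$n_channels else cfg$branch_filters[l - 1L]
    for (br in 1:2) {
      add(sprintf("conv1d_b%d_%d (Conv1D)", br, l),
          c(sizes[[l]][["conv"]], f), k * C_in * f + f)
    }
    for (br in 1:2) {
      add(sprintf("dropout_b%d_%d (Dropout)", br, l),
          c(sizes[[l]][["conv"]], f), 0L)
    }
    for (br in 1:2) {
      add(sprintf("activation_b%d_%d (Activation)", br, l),
          c(sizes[[l]][["conv"]], f), 0L)
    }
    for (br in 1:2) {
      add(sprintf("max_pooling1d_b%d_%d (MaxPooling1D)", br, l),
          c(sizes[[l]][["pool"]], f), 0L)
    }
  }
  T_final <- sizes[[length(sizes)]][["pool"]]
  F_final <- cfg$branch_filters[length(cfg$branch_filters)]
  flat <- T_final * 2L * F_final
  D <- flat + cfg$n_extra_features
  add("concatenate_branches (Concatenate)", c(T_final, 2L * F_final), 0L)
  add("flatten (Flatten)", flat, 0L)
  add("concatenate_features (Concatenate)", D, 0L)
  add("dense (Dense)", cfg$dense_units, D * cfg$dense_units + cfg$dense_units)
  add("dropout_dense (Dropout)", cfg$dense_units, 0L)
  add("dense_out (Dense)", 1L, cfg$dense_units + 1L)
  out <- do.call(rbind, rows)
  attr(out, "total_params") <- sum(out$params)
  out
}

#' Export a model summary as TSV
#'
#' @param model A `dsc_model`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_model_summary <- function(model, path) {
  utils::write.table(model_summary(model), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.dsc_model <- function(x, ...) {
  s <- model_summary(x)
  cat(sprintf("<dsc_model variant=%s, %s>\n", x$variant,
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  %d conv layers per branch; %s total trainable parameters\n",
              length(x$config$branch_filters),
              format(attr(s, "total_params"), big.mark = ",")))
  invisible(x)
}

#' Score encoded splice events
#'
#' Runs the forward pass in inference mode (dropout disabled) and returns
#' the sigmoid probability of the high-inclusion class for each event.
#'
#' @param object A `dsc_model`.
#' @param newdata An `encoded_dataset` from [encode_dataset()], or a list
#'   with elements `x1`, `x2` (arrays `seq_len x 4 x n`) and `x3`
#'   (matrix `n x 3`).
#' @param ... Unused.
#' @return Numeric vector of probabilities, strictly inside (0, 1).
#' @export
predict.dsc_model <- function(object, newdata, ...) {
  x <- as_encoded_arrays(newdata, object$config)
  as.numeric(cpp_predict(object$config, object$weights, x$x1, x$x2, x$x3))
}

as_encoded_arrays <- function(data, cfg) {
  if (!is.list(data) || is.null(data$x1) || is.null(data$x2) ||
      is.null(data$x3)) {
    stop("`newdata` must contain elements x1, x2 and x3 ",
         "(see encode_dataset())", call. = FALSE)
  }
  x1 <- data$x1; x2 <- data$x2; x3 <- data$x3
  if (length(dim(x1)) != 3L || dim(x1)[1] != cfg$seq_len ||
      dim(x1)[2] != cfg$n_channels) {
    stop(sprintf("x1 must be a %d x %d x n array", cfg$seq_len,
                 cfg$n_channels), call. = FALSE)
  }
  if (!identical(dim(x1), dim(x2))) {
    stop("x1 and x2 must have identical dimensions", call. = FALSE)
  }
  x3 <- as.matrix(x3)
  if (nrow(x3) != dim(x1)[3] || ncol(x3) != cfg$n_extra_features) {
    stop(sprintf("x3 must be an n x %d matrix", cfg$n_extra_features),
         call. = FALSE)
  }
  list(x1 = x1, x2 = x2, x3 = x3)
}

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood of Bernoulli labels under predicted
#' probabilities, using natural logarithms:
#' `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))`.
#' Each log argument is clipped below at `eps` so a hard 0/1 prediction on
#' the wrong label yields the large finite loss `-log(eps)` rather than
#' infinity, while a prediction exactly equal to its label contributes
#' exactly zero.
#'
#' @param y_true Binary vector of 0/1 labels.
#' @param y_score Predicted probabilities in `[0, 1]`, same length.
#' @param eps Clipping constant, default `1e-7`.
#' @return A single non-negative number; 0 exactly when every clipped score
#'   equals its label.
#' @examples
#' binary_cross_entropy(1, 0.5)  # log(2)
#' @export
binary_cross_entropy <- function(y_true, y_score, eps = 1e-7) {
  if (length(y_true) != length(y_score)) {
    stop("`y_true` and `y_score` must have equal length", call. = FALSE)
  }
  if (length(y_true) == 0L) stop("empty input", call. = FALSE)
  if (!all(y_true %in% c(0, 1))) {
    stop("`y_true` must be binary 0/1", call. = FALSE)
  }
  if (any(y_score < 0 | y_score > 1)) {
    stop("`y_score` must lie in [0, 1]", call. = FALSE)
  }
  -mean(y_true * log(pmax(y_score, eps)) +
          (1 - y_true) * log(pmax(1 - y_score, eps)))
}
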