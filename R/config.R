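#' Architecture and optimizer configuration for the DSC network
#'
#' Collects every hyperparameter of the dual-branch convolutional
#' classifier: per-branch convolution stacks, pooling, dropout, the dense
#' head, and the Adam optimizer settings.  The defaults reproduce the
#' published 8-hidden-layer DSC architecture: four convolutional layers per
#' branch with filters 8/16/32/64 and kernels 7/4/3/2, max pooling of size 2
#' and stride 2 after each block, a 1,024-unit dense layer with dropout 0.5,
#' and Adam with learning rate 5e-4, betas 0.9/0.999, epsilon 1e-8 and no
#' decay.
#'
#' @param branch_filters Integer vector, number of filters per conv layer in
#'   each branch (both branches are identical in shape).
#' @param branch_kernels Integer vector, kernel width per conv layer; must
#'   have the same length as `branch_filters`.
#' @param pool_size,pool_stride Max-pooling window and stride after every
#'   conv block.
#' @param conv_dropout Dropout rate applied inside each conv block (between
#'   the convolution and its ReLU).
#' @param dense_units Width of the fully connected layer after the merge.
#' @param dense_dropout Dropout rate after the dense layer.
#' @param learning_rate,beta1,beta2,epsilon,decay Adam optimizer settings.
#' @param seq_len Sequence window length in nucleotides.
#' @param n_channels Number of one-hot channels (A, C, G, T).
#' @param n_extra_features Number of auxiliary length features.
#'
#' @return An object of class `dsc_config` (a validated named list).
#' @examples
#' cfg <- dsc_config()
#' cfg$branch_filters
#' @export
dsc_config <- function(branch_filters = c(8L, 16L, 32L, 64L),
                       branch_kernels = c(7L, 4L, 3L, 2L),
                       pool_size = 2L,
                       pool_stride = 2L,
                       conv_dropout = 0.2,
                       dense_units = 1024L,
                       dense_dropout = 0.5,
                       learning_rate = 0.0005,
                       beta1 = 0.9,
                       beta2 = 0.999,
                       epsilon = 1e-8,
                       decay = 0,
                       seq_len = 140L,
                       n_channels = 4L,
                       n_extra_features = 3L) {
  cfg <- list(
    branch_filters = as.integer(branch_filters),
    branch_kernels = as.integer(branch_kernels),
    pool_size = as.integer(pool_size),
    pool_stride = as.integer(pool_stride),
    conv_dropout = conv_dropout,
    dense_units = as.integer(dense_units),
    dense_dropout = dense_dropout,
    learning_rate = learning_rate,
    beta1 = beta1,
    beta2 = beta2,
    epsilon = epsilon,
    decay = decay,
    seq_len = as.integer(seq_len),
    n_channels = as.integer(n_channels),
    n_extra_features = as.integer(n_extra_features)
  )
  class(cfg) <- "dsc_config"
  validate_dsc_config(cfg)
}

validate_dsc_config <- function(cfg) {
  if (length(cfg$branch_filters) != length(cfg$branch_kernels)) {
    stop("`branch_filters` and `branch_kernels` must have the same length ",
         "(one entry per conv layer)", call. = FALSE)
  }
  if (length(cfg$branch_filters) < 1L) {
    stop("at least one conv layer per branch is required", call. = FALSE)
  }
  ints <- c(cfg$branch_filters, cfg$branch_kernels, cfg$pool_size,
            cfg$pool_stride, cfg$dense_units, cfg$seq_len, cfg$n_channels,
            cfg$n_extra_features)
  if (any(!is.finite(ints)) || any(ints < 1L)) {
    stop("filters, kernels, pooling, unit counts and input sizes must all ",
         "be positive integers", call. = FALSE)
  }
  for (nm in c("conv_dropout", "dense_dropout")) {
    r <- cfg[[nm]]
    if (!is.numeric(r) || length(r) != 1L || r < 0 || r >= 1) {
      stop(sprintf("`%s` must be a rate in [0, 1)", nm), call. = FALSE)
    }
  }
  if (cfg$learning_rate <= 0) {
    stop("`learning_rate` must be positive", call. = FALSE)
  }
  cfg
}

#' @export
print.dsc_config <- function(x, ...) {
  cat("<dsc_config>\n")
  cat("  conv layers/branch :", length(x$branch_filters), "\n")
  cat("  filters            :", paste(x$branch_filters, collapse = ", "), "\n")
  cat("  kernels            :", paste(x$branch_kernels, collapse = ", "), "\n")
  cat("  pooling            : size", x$pool_size, "stride", x$pool_stride, "\n")
  cat("  dense              :", x$dense_units, "units, dropout",
      x$dense_dropout, "\n")
  cat("  Adam               : lr", x$learning_rate, "betas", x$beta1, "/",
      x$beta2, "\n")
  invisible(x)
}
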