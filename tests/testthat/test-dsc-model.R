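# Independent geometry oracle: valid-padding conv shrinks L to L - k + 1,
# pooling to (L - pool) %/% stride + 1; conv params k*C_in*F + F, dense
# params D*units + units.
oracle_branch <- function(L, kernels, filters, C0 = 4L, pool = 2L,
                          stride = 2L) {
  rows <- list()
  C <- C0
  for (l in seq_along(kernels)) {
    L <- L - kernels[l] + 1L
    rows[[l]] <- list(L_conv = L, params = kernels[l] * C * filters[l] +
                        filters[l])
    L <- (L - pool) %/% stride + 1L
    rows[[l]]$L_pool <- L
    C <- filters[l]
  }
  rows
}

conv_rows <- function(s, branch) {
  s[grepl(sprintf("conv1d_b%d", branch), s$layer), ]
}

test_that("default DSC model reproduces the published layer table exactly", {
  m <- build_dsc()
  s <- model_summary(m)
  for (br in 1:2) {
    cr <- conv_rows(s, br)
    expect_equal(cr$params, c(232L, 528L, 1568L, 4160L))
    expect_equal(cr$output_shape,
                 c("(134, 8)", "(64, 16)", "(30, 32)", "(14, 64)"))
  }
  pools <- s[grepl("max_pooling1d_b1", s$layer), ]
  expect_equal(pools$output_shape,
               c("(67, 8)", "(32, 16)", "(15, 32)", "(7, 64)"))
  expect_equal(s$output_shape[s$layer == "flatten (Flatten)"], "(896)")
  expect_equal(s$output_shape[s$layer == "concatenate_features (Concatenate)"],
               "(899)")
  expect_equal(s$params[s$layer == "dense (Dense)"], 921600L)
  expect_equal(s$params[s$layer == "dense_out (Dense)"], 1025L)
  expect_equal(s$params[grepl("Dropout|MaxPooling|Activation|Flatten|Concatenate|Input",
                              s$layer)],
               rep(0L, sum(grepl("Dropout|MaxPooling|Activation|Flatten|Concatenate|Input",
                                 s$layer))))
  expect_equal(attr(s, "total_params"), sum(s$params))
})

test_that("layer geometry matches the closed-form oracle for varied configs", {
  set.seed(42)
  for (i in 1:10) {
    n_layers <- sample(1:3, 1)
    kernels <- sample(2:7, n_layers, replace = TRUE)
    filters <- sample(c(4L, 8L, 16L), n_layers, replace = TRUE)
    cfg <- dsc_config(branch_filters = filters, branch_kernels = kernels,
                      dense_units = 32L)
    m <- build_dsc(cfg)
    s <- model_summary(m)
    expected <- oracle_branch(140L, kernels, filters)
    cr <- conv_rows(s, 1)
    for (l in seq_len(n_layers)) {
      expect_equal(cr$params[l], expected[[l]]$params)
      expect_equal(cr$output_shape[l],
                   sprintf("(%d, %d)", expected[[l]]$L_conv, filters[l]))
    }
    # branch symmetry
    expect_equal(conv_rows(s, 2)$params, cr$params)
    expect_equal(conv_rows(s, 2)$output_shape, cr$output_shape)
    # dense parameter oracle
    T_final <- expected[[n_layers]]$L_pool
    D <- T_final * 2L * filters[n_layers] + 3L
    expect_equal(s$params[s$layer == "dense (Dense)"], D * 32L + 32L)
  }
})

test_that("single-filter single-kernel conv has the minimal count", {
  m <- build_dsc(dsc_config(branch_filters = 1L, branch_kernels = 1L,
                            dense_units = 4L))
  s <- model_summary(m)
  expect_equal(conv_rows(s, 1)$params, 5L)  # 1*4*1 + 1
})

test_that("a collapsing temporal cascade raises an architecture error", {
  expect_error(build_dsc(dsc_config(branch_filters = c(8L, 8L),
                                    branch_kernels = c(141L, 2L))),
               "conv layer 1")
  expect_error(
    build_dsc(dsc_config(branch_filters = rep(8L, 8),
                         branch_kernels = rep(7L, 8))),
    "temporal dimension")
})

test_that("config validation rejects inconsistent settings", {
  expect_error(dsc_config(branch_filters = c(8L, 16L), branch_kernels = 7L),
               "same length")
  expect_error(dsc_config(conv_dropout = 1), "rate")
  expect_error(dsc_config(dense_units = 0L), "positive")
})

test_that("baseline variant has the 6-hidden-layer reference structure", {
  m <- build_baseline()
  s <- model_summary(m)
  cr1 <- conv_rows(s, 1)
  expect_equal(nrow(cr1), 3L)                 # 3 conv layers x 2 branches = 6
  expect_equal(cr1$params[1], 928L)           # 7*4*32 + 32
  expect_equal(cr1$output_shape[1], "(134, 32)")
  expect_equal(m$config$branch_filters, c(32L, 8L, 8L))
  expect_equal(m$config$branch_kernels, c(7L, 4L, 3L))
  expect_equal(m$config$conv_dropout, 0.2)
})

test_that("predictions are probabilities strictly inside (0, 1)", {
  cfg <- dsc_config(branch_filters = c(4L, 4L), branch_kernels = c(5L, 3L),
                    dense_units = 16L)
  m <- build_dsc(cfg, seed = 9)
  set.seed(3)
  d <- generate_dataset(synthetic_config(n_per_class = 10, seed = 5))
  p <- predict(m, encode_dataset(d))
  expect_length(p, 20L)
  expect_true(all(p > 0 & p < 1))
})

test_that("binary cross-entropy matches hand-computed values", {
  expect_equal(binary_cross_entropy(1, 1), 0, tolerance = 1e-9)
  expect_equal(binary_cross_entropy(1, 0.5), log(2), tolerance = 1e-9)
  expect_equal(binary_cross_entropy(c(0, 1), c(0.25, 0.75)), -log(0.75),
               tolerance = 1e-9)
})

test_that("binary cross-entropy is permutation-invariant, clipped, validated", {
  set.seed(5)
  y <- rbinom(50, 1, 0.5)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(binary_cross_entropy(y, p),
               binary_cross_entropy(y[perm], p[perm]))
  expect_true(is.finite(binary_cross_entropy(1, 0)))  # clipped, not Inf
  expect_equal(binary_cross_entropy(1, 0), -log(1e-7))
  expect_error(binary_cross_entropy(c(0, 1), 0.5), "equal length")
  # minimized when scores equal labels
  expect_lt(binary_cross_entropy(y, ifelse(y == 1, 0.999, 0.001)),
            binary_cross_entropy(y, p))
})

test_that("model summary exports as TSV mirroring its columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model_summary(build_dsc(), path)
  tab <- read.delim(path)
  expect_equal(names(tab), c("layer", "output_shape", "params"))
  expect_equal(sum(tab$params), 935601L)
})
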