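test_that("fold plans are disjoint, covering and balanced", {
  plan <- make_fold_plan(100, seed = 1)
  sizes <- as.integer(table(plan$fold_of))
  expect_equal(sizes, rep(10L, 10L))
  expect_equal(sort(unique(plan$fold_of)), 0:9)
  expect_length(plan$fold_of, 100L)

  plan105 <- make_fold_plan(105, seed = 2)
  sizes105 <- sort(as.integer(table(plan105$fold_of)))
  expect_equal(sizes105, c(rep(10L, 5), rep(11L, 5)))

  # ragged n: sizes never differ by more than 1
  for (n in c(10, 23, 57, 1001)) {
    p <- make_fold_plan(n, seed = 3)
    expect_lte(diff(range(table(p$fold_of))), 1)
    expect_equal(sum(table(p$fold_of)), n)
  }
})

test_that("every rotation has disjoint roles and each fold tests once", {
  plan <- make_fold_plan(73, seed = 9)
  test_folds <- integer(0)
  for (rot in plan$rotations) {
    roles <- c(rot$train, rot$earlystop, rot$test)
    expect_equal(sort(roles), 0:9)         # disjoint and exhaustive
    expect_length(rot$train, 8L)
    test_folds <- c(test_folds, rot$test)
    # no index-level leakage
    tr <- which(plan$fold_of %in% rot$train)
    es <- which(plan$fold_of == rot$earlystop)
    te <- which(plan$fold_of == rot$test)
    expect_length(intersect(tr, te), 0L)
    expect_length(intersect(tr, es), 0L)
    expect_length(intersect(es, te), 0L)
  }
  expect_equal(sort(test_folds), 0:9)
})

test_that("fold assignment is deterministic in the seed", {
  expect_identical(make_fold_plan(57, seed = 5)$fold_of,
                   make_fold_plan(57, seed = 5)$fold_of)
  expect_false(identical(make_fold_plan(57, seed = 5)$fold_of,
                         make_fold_plan(57, seed = 6)$fold_of))
  expect_error(make_fold_plan(9, seed = 1), "at least 10")
})

# -- training ---------------------------------------------------------------

enc_split <- function(records, n_train, n_es, seed = 2) {
  enc <- encode_dataset(records)
  set.seed(seed)
  idx <- sample(length(enc$y))
  list(train = spliceDSC:::subset_encoded(enc, idx[seq_len(n_train)]),
       es = spliceDSC:::subset_encoded(enc,
                                       idx[(n_train + 1):(n_train + n_es)]),
       rest = spliceDSC:::subset_encoded(
         enc, idx[(n_train + n_es + 1):length(idx)]))
}

test_that("training reduces loss on planted-signal data", {
  d <- small_signal_records(n_per_class = 150, seed = 11)
  sp <- enc_split(d, 220, 40)
  fit <- train_fold(build_dsc(seed = 3), sp$train, sp$es, max_epochs = 8,
                    seed = 5)
  h <- fit$history
  expect_lt(h$train_loss[length(h$train_loss)], h$train_loss[1])
  expect_true(all(is.finite(h$train_loss)) && all(h$train_loss >= 0))
  expect_true(all(is.finite(h$earlystop_loss)))
  expect_lte(h$stopped_epoch, h$max_epochs)
  # the trained model separates held-out classes better than chance
  expect_gt(auc_roc(sp$rest$y, predict(fit$model, sp$rest)), 0.6)
})

test_that("training is deterministic for a fixed seed", {
  d <- small_signal_records(n_per_class = 40, seed = 21)
  sp <- enc_split(d, 60, 10)
  f1 <- train_fold(build_dsc(seed = 4), sp$train, sp$es, max_epochs = 3,
                   seed = 8)
  f2 <- train_fold(build_dsc(seed = 4), sp$train, sp$es, max_epochs = 3,
                   seed = 8)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$history$earlystop_loss, f2$history$earlystop_loss)
  expect_identical(predict(f1$model, sp$es), predict(f2$model, sp$es))
})

test_that("early stopping halts on a plateau and keeps the best weights", {
  d <- small_signal_records(n_per_class = 40, seed = 31)
  sp <- enc_split(d, 60, 10)
  # an absurd min_delta means no epoch ever counts as an improvement
  fit <- train_fold(build_dsc(seed = 4), sp$train, sp$es, max_epochs = 20,
                    patience = 2, min_delta = 10, seed = 8)
  h <- fit$history
  expect_lte(h$stopped_epoch, 3L)  # best-so-far epoch 1 + 2 patience epochs
  expect_lte(h$best_epoch, h$stopped_epoch)
  expect_length(h$train_loss, h$stopped_epoch)

  # returned weights come from the best early-stop epoch, never later
  fit2 <- train_fold(build_dsc(seed = 4), sp$train, sp$es, max_epochs = 6,
                     patience = 3, min_delta = 1e-4, seed = 8)
  h2 <- fit2$history
  expect_equal(min(h2$earlystop_loss), h2$earlystop_loss[h2$best_epoch],
               tolerance = 1e-12)
})

test_that("training rejects invalid splits", {
  d <- small_signal_records(n_per_class = 20, seed = 41)
  enc <- encode_dataset(d)
  a <- spliceDSC:::subset_encoded(enc, 1:30)
  overlap <- spliceDSC:::subset_encoded(enc, 25:40)
  expect_error(train_fold(build_dsc(seed = 1), a, overlap, max_epochs = 1),
               "overlap")
  empty <- spliceDSC:::subset_encoded(enc, integer(0))
  expect_error(train_fold(build_dsc(seed = 1), empty, a, max_epochs = 1),
               "empty train")
})

test_that("label-permuted data plateaus near the entropy of a fair coin", {
  d <- small_signal_records(n_per_class = 100, seed = 51)
  d <- permute_labels(d, seed = 52)
  sp <- enc_split(d, 150, 30)
  fit <- train_fold(build_dsc(seed = 6), sp$train, sp$es, max_epochs = 6,
                    seed = 9)
  final <- tail(fit$history$earlystop_loss, 1)
  expect_gt(final, log(2) - 0.12)   # cannot beat ln 2 on null labels
  expect_lt(final, log(2) + 0.25)
})

test_that("cross-validation produces one AUC per rotation", {
  d <- small_signal_records(n_per_class = 30, seed = 61)
  r <- run_cv(d, config = dsc_config(branch_filters = c(4L, 8L),
                                     branch_kernels = c(7L, 4L),
                                     dense_units = 32L),
              max_epochs = 2, seed = 13)
  expect_s3_class(r, "evaluation_report")
  expect_length(r$fold_aucs, 10L)
  expect_true(all(r$fold_aucs >= 0 & r$fold_aucs <= 1))
  expect_equal(r$mean_auc, mean(r$fold_aucs))
  expect_equal(r$seed, 13L)
  expect_length(attr(r, "histories"), 10L)
})

test_that("the epoch sweep tabulates both variants per budget", {
  d <- small_signal_records(n_per_class = 40, seed = 71)
  cfg <- dsc_config(branch_filters = c(4L, 8L), branch_kernels = c(7L, 4L),
                    dense_units = 16L)
  tab <- epoch_sweep(d, config = cfg, epochs_list = c(1L, 2L), seed = 17)
  expect_equal(nrow(tab), 2L)
  expect_equal(names(tab), c("epochs", "auc_baseline", "auc_dsc"))
  expect_true(all(tab$auc_baseline >= 0 & tab$auc_baseline <= 1))
  expect_true(all(tab$auc_dsc >= 0 & tab$auc_dsc <= 1))
  expect_error(epoch_sweep(d, epochs_list = integer(0)), "non-empty")
})
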