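test_that("one epoch of training records a finite history row", {
  ds <- quick_patchset(n = 30, side = 16, k = 3, n_stains = 2)
  fit <- train_imclust(ds, train_config(3L, epochs = 1L, seed = 1))
  expect_s3_class(fit, "imclust_fit")
  expect_equal(nrow(fit$history), 1)
  expect_true(all(is.finite(unlist(fit$history))))
  expect_error(train_config(3L, epochs = 0L), "epochs")
  expect_error(train_config(3L, batch_size = 1L), "batch_size")
})

test_that("training is reproducible under a fixed seed", {
  ds <- quick_patchset(n = 40, side = 16, k = 3, n_stains = 2)
  tc <- train_config(3L, epochs = 8L, learning_rate = 1.0, seed = 6)
  f1 <- train_imclust(ds, tc)
  f2 <- train_imclust(ds, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(encode(ds, f1$state), encode(ds, f2$state))
  f3 <- train_imclust(ds, train_config(3L, epochs = 8L, learning_rate = 1.0,
                                       seed = 7))
  expect_false(identical(f1$history$total, f3$history$total))
})

test_that("mutual information grows over training on separable data", {
  ds <- quick_patchset(n = 160, side = 16, k = 4, n_stains = 5,
                       separation = 1, seed = 12)
  fit <- train_imclust(ds, train_config(4L, epochs = 200L,
                                        learning_rate = 1.0, seed = 1))
  h <- fit$history
  expect_gt(h$mutual_info[nrow(h)], h$mutual_info[1])
})

test_that("recorded totals recompose from components via the loss identity", {
  ds <- quick_patchset(n = 30, side = 16, k = 3, n_stains = 2)
  w <- loss_weights()
  fit <- train_imclust(ds, train_config(3L, epochs = 5L, weights = w, seed = 2))
  h <- fit$history
  expect_equal(h$total,
               h$recon - (w$lambda_me * h$marginal_entropy -
                          w$lambda_ce * h$conditional_entropy) +
                 w$lambda_af * h$affine_kl,
               tolerance = 1e-10)
  expect_equal(h$mutual_info, h$marginal_entropy - h$conditional_entropy,
               tolerance = 1e-10)
})

test_that("hard assignment is the row argmax with ties to the lowest index", {
  expect_equal(stainclust:::hard_assign(rbind(c(0.1, 0.7, 0.2))), 1L)
  expect_equal(stainclust:::hard_assign(rbind(c(0.5, 0.5))), 0L)
  expect_equal(stainclust:::hard_assign(rbind(c(0.2, 0.4, 0.4))), 1L)
  ds <- quick_patchset(n = 20, side = 16, k = 2, n_stains = 2)
  fit <- train_imclust(ds, train_config(2L, epochs = 2L, seed = 3))
  asg <- assign_clusters(fit, ds)
  expect_equal(asg$labels, apply(asg$soft, 1, which.max) - 1L)
  expect_true(all(asg$labels >= 0 & asg$labels < 2))
  tb <- tibble::as_tibble(asg)
  expect_equal(nrow(tb), 20)
})

test_that("tidy and glance summarise a fit", {
  ds <- quick_patchset(n = 24, side = 16, k = 2, n_stains = 2)
  fit <- train_imclust(ds, train_config(2L, epochs = 3L, seed = 4))
  expect_identical(tidy(fit), fit$history)
  g <- glance(fit)
  expect_equal(g$epochs, 3)
  expect_equal(g$n_clusters, 2)
  expect_equal(g$mi_gain,
               fit$history$mutual_info[3] - fit$history$mutual_info[1])
})

test_that("checkpoints are written at the requested cadence", {
  ds <- quick_patchset(n = 20, side = 16, k = 2, n_stains = 2)
  dirp <- withr::local_tempdir()
  fit <- train_imclust(ds, train_config(2L, epochs = 4L, seed = 5,
                                        checkpoint_every = 2L,
                                        checkpoint_dir = dirp))
  expect_setequal(list.files(dirp, pattern = "\\.rds$"),
                  c("epoch0002.rds", "epoch0004.rds"))
  ck <- load_network(file.path(dirp, "epoch0004.rds"))
  expect_identical(encode(ds, ck), encode(ds, fit$state))
})
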