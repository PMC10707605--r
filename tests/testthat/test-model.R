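test_that("the default architecture meets its shape contracts", {
  cfg <- model_config(14L)
  state <- init_network(cfg, seed = 1)
  x <- array(runif(64 * 64 * 15), dim = c(64, 64, 15, 1))
  emb <- encode(x, state)
  expect_equal(dim(emb), c(1, 196))
  soft <- classify(emb, state)
  expect_equal(dim(soft), c(1, 14))
  rec <- decode(emb, soft, state)
  expect_equal(dim(rec), c(64, 64, 15, 1))
})

test_that("config validation catches inconsistent architectures", {
  expect_error(model_config(1L), "n_clusters")
  expect_error(model_config(5L, upper_dim = 3L), "upper_dim")
  expect_error(model_config(3L, input_size = 30L), "divisible")
  cfg <- tiny_config()
  state <- init_network(cfg, seed = 1)
  bad <- array(0.1, dim = c(8, 8, 9, 2))
  expect_error(encode(bad, state), "channels")
  expect_error(classify(matrix(0.1, 2, 5), state), "columns")
})

test_that("encode/classify/decode are deterministic and per-sample", {
  cfg <- tiny_config()
  state <- init_network(cfg, seed = 2)
  x <- random_batch(cfg, n = 3)
  expect_identical(encode(x, state), encode(x, state))
  # doubling the batch duplicates rows: samples do not interact
  xx <- array(c(x, x), dim = c(8, 8, 6, 6))
  e1 <- encode(x, state)
  e2 <- encode(xx, state)
  expect_equal(e2[1:3, ], e1, tolerance = 1e-12)
  expect_equal(e2[4:6, ], e1, tolerance = 1e-12)
  soft <- classify(e1, state)
  expect_equal(rowSums(soft), rep(1, 3), tolerance = 1e-6)
  expect_true(all(soft >= 0))
  expect_true(all(apply(soft, 1, function(p) -sum(p * log(p))) <=
                    log(cfg$n_clusters) + 1e-9))
  rec <- decode(e1, soft, state)
  expect_identical(rec, decode(e1, soft, state))
  expect_true(min(rec) >= 0 && max(rec) <= 1)
  expect_equal(dim(rec)[1:2], c(8, 8))
  expect_error(decode(e1, soft[1:2, ], state), "row counts")
})

test_that("inputs above the working size are rescaled before encoding", {
  cfg <- model_config(3L, in_channels = 6L, input_size = 16L,
                      input_rescale = 8L, channel_plan = c(4L),
                      upper_dim = 8L, classifier_hidden = 6L)
  state <- init_network(cfg, seed = 3)
  x <- stainclust:::with_seed(1, array(runif(16 * 16 * 6 * 2),
                                       dim = c(16, 16, 6, 2)))
  emb <- encode(x, state)
  expect_equal(dim(emb), c(2, 8))
  rec <- decode(emb, classify(emb, state), state)
  expect_equal(dim(rec)[1:2], c(8, 8))  # reconstruction at the working size
})

test_that("a saved network reloads bit-exactly", {
  cfg <- tiny_config()
  state <- init_network(cfg, seed = 4)
  x <- random_batch(cfg, n = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_network(state, path)
  back <- load_network(path)
  expect_identical(encode(x, back), encode(x, state))
  expect_true(file.exists(paste0(path, ".json")))
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$n_clusters, cfg$n_clusters)
})

test_that("every learnable parameter receives gradient on a synthetic batch", {
  cfg <- tiny_config()
  state <- init_network(cfg, seed = 5)
  x <- random_batch(cfg, n = 6, seed = 1)
  xa <- random_batch(cfg, n = 6, seed = 2)
  step <- stainclust:::imclust_step(state, x, xa, loss_weights())
  for (part in c("encoder", "classifier", "decoder")) {
    for (i in seq_along(state[[part]])) {
      if (is.null(state[[part]][[i]]$w)) next
      g <- step$grads[[part]][[i]]
      expect_true(any(g$dw != 0), label = sprintf("%s layer %d dw", part, i))
      expect_true(any(g$db != 0), label = sprintf("%s layer %d db", part, i))
    }
  }
})
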