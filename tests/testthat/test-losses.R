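test_that("entropy matches closed forms and bounds", {
  expect_equal(entropy(rep(1 / 14, 14)), log(14))
  expect_equal(entropy(c(1, 0, 0)), 0)
  expect_equal(entropy(c(0.5, 0.25, 0.25)), 1.039721, tolerance = 1e-6)
  expect_error(entropy(c(0.7, 0.4)), "sum")
  expect_error(entropy(c(1.2, -0.2)), "non-negative")
})

test_that("conditional and marginal entropies match hand computations", {
  onehot <- diag(4)
  expect_equal(conditional_entropy(onehot), 0, tolerance = 1e-10)
  expect_equal(conditional_entropy(matrix(0.25, 5, 4)), log(4))
  expect_equal(conditional_entropy(rbind(c(1, 0), c(0.5, 0.5))), log(2) / 2)
  expect_equal(marginal_entropy(matrix(c(1, 0), 6, 2, byrow = TRUE)), 0)
  expect_equal(marginal_entropy(diag(5)), log(5))
  expect_equal(marginal_entropy(rbind(c(1, 0), c(0, 1))), log(2))
  expect_error(conditional_entropy(matrix(numeric(), 0, 2)), "non-empty")
})

test_that("plug-in mutual information is an entropy difference and >= 0", {
  p <- matrix(c(0.9, 0.1), 8, 2, byrow = TRUE)
  expect_equal(mutual_information(p), 0, tolerance = 1e-12)
  expect_equal(mutual_information(rbind(c(1, 0), c(0, 1))), log(2))
  stainclust:::with_seed(1, {
    p <- random_assignment(100, 5)
    # independent recomputation: entropy of column means minus mean row entropy
    expected <- naive_entropy(colMeans(p)) - mean(apply(p, 1, naive_entropy))
    expect_equal(mutual_information(p), expected, tolerance = 1e-10)
    expect_gte(mutual_information(p), 0)
  })
})

test_that("reconstruction MSE matches a brute-force loop", {
  x <- array(runif(24), dim = c(2, 3, 4))
  expect_equal(reconstruction_mse(x, x), 0)
  expect_equal(reconstruction_mse(x, x + 0.1), 0.01, tolerance = 1e-12)
  y <- array(runif(24), dim = c(2, 3, 4))
  acc <- 0
  for (i in seq_along(x)) acc <- acc + (x[i] - y[i])^2
  expect_equal(reconstruction_mse(x, y), acc / 24)
  expect_error(reconstruction_mse(x, array(0, c(3, 2, 4))), "differ")
})

test_that("affine KL satisfies Gibbs' inequality and closed forms", {
  p <- random_assignment(10, 3)
  expect_equal(affine_kl(p, p), 0, tolerance = 1e-9)
  expect_equal(affine_kl(rbind(c(1, 0)), rbind(c(0.5, 0.5))), log(2))
  stainclust:::with_seed(2, {
    for (rep in 1:20) {
      a <- random_assignment(6, 4); b <- random_assignment(6, 4)
      manual <- mean(sapply(1:6, function(i)
        sum(a[i, ] * (log(a[i, ]) - log(b[i, ])))))
      expect_equal(affine_kl(a, b), manual, tolerance = 1e-9)
      expect_gte(affine_kl(a, b), 0)
    }
  })
})

test_that("the combined loss assembles exactly from its components", {
  w <- loss_weights()
  expect_equal(c(w$lambda_me, w$lambda_ce, w$lambda_af), c(0.1, 0.03, 0.03))
  expect_equal(total_loss(0, 0, 0, 0, w)$total, 0)
  expect_equal(total_loss(1, log(2), 0, 0, w)$total, 1 - 0.1 * log(2))
  stainclust:::with_seed(3, {
    for (rep in 1:25) {
      r <- runif(1); hy <- runif(1, 0, 2); hyx <- runif(1, 0, 2); af <- runif(1)
      bl <- total_loss(r, hy, hyx, af, w)
      expect_equal(bl$total,
                   r - (w$lambda_me * hy - w$lambda_ce * hyx) +
                     w$lambda_af * af, tolerance = 1e-12)
      expect_equal(bl$mutual_info, hy - hyx)
    }
  })
  expect_error(total_loss(-1, 0, 0, 0, w), "non-negative")
  expect_error(loss_weights(lambda_me = -0.1), "non-negative")
})

test_that("with equal entropy weights the loss is penalty minus weighted MI", {
  # the split-weight objective reduces to the single-trade-off form
  # R - lambda * I(X;Y) when lambda_me = lambda_ce = lambda
  lam <- 0.07
  w <- loss_weights(lam, lam, 0.03)
  stainclust:::with_seed(4, {
    p <- random_assignment(40, 6); q <- random_assignment(40, 6)
    r <- 0.42
    bl <- total_loss(r, marginal_entropy(p), conditional_entropy(p),
                     affine_kl(p, q), w)
    penalty <- r + w$lambda_af * affine_kl(p, q)
    expect_equal(bl$total, penalty - lam * mutual_information(p),
                 tolerance = 1e-12)
  })
})

test_that("entropy estimates respect their bounds on random inputs", {
  stainclust:::with_seed(5, {
    for (rep in 1:200) {
      k <- sample(2:10, 1)
      p <- random_assignment(sample(2:30, 1), k)
      hy <- marginal_entropy(p); hyx <- conditional_entropy(p)
      expect_true(hy >= 0 && hy <= log(k) + 1e-9)
      expect_true(hyx >= 0 && hyx <= log(k) + 1e-9)
      expect_gte(hy - hyx, -1e-9)
    }
  })
})
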