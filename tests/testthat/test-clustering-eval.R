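# 1-D toy: two tight pairs far apart, all quantities known in closed form.
toy_x <- matrix(c(0, 1, 10, 11), ncol = 1)
toy_l <- c(0L, 0L, 1L, 1L)

test_that("all six indices match closed forms on the two-pair toy", {
  expect_equal(xie_beni(toy_x, toy_l), 1 / (4 * 100))
  expect_equal(calinski_harabasz(toy_x, toy_l), 200)
  expect_equal(c_index(toy_x, toy_l), 0)
  expect_equal(hartigan(toy_x, toy_l), log(100))
  expect_equal(dunn(toy_x, toy_l), 9)
  expect_equal(mclain_rao(toy_x, toy_l), 0.1)
})

test_that("degenerate clusterings are signalled as errors", {
  same <- matrix(c(1, 1, 5, 5), ncol = 1)
  expect_error(calinski_harabasz(same, toy_l), "scatter")
  expect_error(hartigan(same, toy_l), "scatter")
  expect_equal(xie_beni(same, toy_l), 0)  # zero compactness is legitimate
  expect_error(dunn(matrix(1:4, ncol = 1), c(0L, 1L, 2L, 3L)), "cluster")
  expect_error(xie_beni(toy_x, c(0L, 0L, 0L, 0L)), "2 clusters")
  expect_error(c_index(toy_x, c(0L, 1L, 1L, 3L)), "non-empty")
  # a duplicated point split across clusters drives Dunn to zero
  dup <- matrix(c(0, 5, 5, 9), ncol = 1)
  expect_equal(dunn(dup, c(0L, 0L, 1L, 1L)), 0)
})

test_that("an adversarial labeling drives the C-index to its upper bound", {
  # within-pair (0,2) is the single largest distance among three points
  x <- matrix(c(0, 1, 2), ncol = 1)
  expect_equal(c_index(x, c(0L, 1L, 0L)), 1)
  stainclust:::with_seed(8, {
    for (rep in 1:20) {
      inst <- random_instance(20, 2, 3)
      ci <- c_index(inst$x, inst$labels)
      expect_true(ci >= 0 && ci <= 1)
    }
  })
})

test_that("indices are invariant to isometries and CH to scaling", {
  stainclust:::with_seed(9, {
    inst <- random_instance(30, 3, 3)
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))          # random rotation
    xr <- sweep(inst$x %*% q, 2, c(3, -2, 7), "+") # rotate + translate
    for (f in list(xie_beni, calinski_harabasz, c_index, hartigan, dunn,
                   mclain_rao)) {
      expect_equal(f(xr, inst$labels), f(inst$x, inst$labels),
                   tolerance = 1e-9)
    }
    expect_equal(calinski_harabasz(inst$x * 3.7, inst$labels),
                 calinski_harabasz(inst$x, inst$labels), tolerance = 1e-9)
    expect_equal(xie_beni(-inst$x, inst$labels), xie_beni(inst$x, inst$labels),
                 tolerance = 1e-12)
  })
})

test_that("every index matches the naive all-pairs oracle on random instances", {
  stainclust:::with_seed(10, {
    for (rep in 1:50) {
      inst <- random_instance(n = sample(12:60, 1), d = sample(1:5, 1),
                              k = sample(2:5, 1))
      got <- compute_validity(inst$x, inst$labels)
      want <- naive_indices(inst$x, inst$labels)
      for (nm in names(want)) {
        expect_equal(got$value[got$index == nm], want[[nm]],
                     tolerance = 1e-9, label = nm)
      }
    }
  })
})

test_that("the fuzzy Xie-Beni variant responds to membership sharpness", {
  stainclust:::with_seed(11, {
    inst <- random_instance(30, 2, 3)
    onehot <- diag(3)[inst$labels + 1, ]
    expect_equal(xie_beni(inst$x, inst$labels, soft = onehot),
                 xie_beni(inst$x, inst$labels), tolerance = 1e-9)
    soft <- 0.7 * onehot + 0.3 / 3
    expect_false(isTRUE(all.equal(xie_beni(inst$x, inst$labels, soft = soft),
                                  xie_beni(inst$x, inst$labels))))
  })
})

test_that("selection on the reference grid reproduces every published choice", {
  grid <- reference_validity_grid()
  expect_equal(nrow(grid), 132)
  sel <- select_optimal(grid)
  pick <- function(ds, ix) sel$optimal_k[sel$dataset == ds & sel$index == ix]
  expect_equal(pick("128x128", "xie_beni"), 14)
  expect_equal(pick("128x128", "calinski_harabasz"), 14)
  expect_equal(pick("128x128", "c_index"), 14)
  expect_equal(pick("128x128", "hartigan"), 15)
  expect_equal(pick("128x128", "dunn"), 13)
  expect_equal(pick("128x128", "mclain_rao"), 15)
  expect_equal(pick("64x64", "xie_beni"), 13)
  expect_equal(pick("64x64", "calinski_harabasz"), 11)
  expect_equal(pick("64x64", "c_index"), 17)
  expect_equal(pick("64x64", "hartigan"), 14)
  expect_equal(pick("64x64", "dunn"), 14)
  expect_equal(pick("64x64", "mclain_rao"), 14)
  expect_false(any(sel$tied))
})

test_that("the vote aggregates optima with conservation and tie reporting", {
  sel <- select_optimal(reference_validity_grid())
  v <- vote_optimal(sel)
  expect_equal(v$mode_k, 14)
  expect_equal(v$n_votes, 6)
  expect_equal(sum(v$votes$n), 12)
  expect_false(v$tied)
  # single-row table selects that row everywhere; unanimous vote
  one <- tibble::tibble(dataset = "d", cluster_set = 9L,
                        index = names(index_directions()),
                        value = c(1, 2, 0.5, 1, 0.3, 0.4))
  sel1 <- select_optimal(one)
  expect_true(all(sel1$optimal_k == 9L))
  v1 <- vote_optimal(sel1)
  expect_equal(v1$mode_k, 9L)
  expect_equal(v1$n_votes, 6)
  # ties break toward the smallest cluster count and are flagged
  tied <- tibble::tibble(dataset = "d", cluster_set = c(4L, 5L),
                         index = "dunn", value = c(0.5, 0.5))
  st <- select_optimal(tied)
  expect_equal(st$optimal_k, 4L)
  expect_true(st$tied)
  expect_error(select_optimal(tibble::tibble(dataset = "d", cluster_set = 2L,
                                             index = "bogus", value = 1)),
               "unknown index")
})

test_that("agreement scores behave like ARI/NMI should", {
  a <- rep(0:3, each = 25)
  expect_equal(agreement(a, a)$ari, 1)
  expect_equal(agreement(a, a)$nmi, 1)
  perm <- c(2L, 0L, 3L, 1L)[a + 1]   # relabelled clusters
  expect_equal(agreement(perm, a)$ari, 1)
  expect_equal(agreement(perm, a)$nmi, 1)
  stainclust:::with_seed(12, {
    r1 <- sample(0:4, 2000, replace = TRUE)
    r2 <- sample(0:4, 2000, replace = TRUE)
    expect_lt(abs(agreement(r1, r2)$ari), 0.05)
  })
  # NMI against a direct contingency-table oracle
  stainclust:::with_seed(13, {
    u <- sample(0:2, 60, replace = TRUE); v <- sample(0:3, 60, replace = TRUE)
    tab <- table(u, v) / 60
    mi <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0)
        mi <- mi + tab[i, j] * log(tab[i, j] / (sum(tab[i, ]) * sum(tab[, j])))
    }
    want <- mi / ((naive_entropy(rowSums(tab)) + naive_entropy(colSums(tab))) / 2)
    expect_equal(nmi(u, v), want, tolerance = 1e-10)
  })
})

test_that("validity tables survive a CSV round trip", {
  grid <- reference_validity_grid()
  path <- withr::local_tempfile(fileext = ".csv")
  write_validity_table(grid, path)
  back <- read_validity_table(path)
  expect_equal(as.data.frame(back), as.data.frame(grid))
  expect_error(read_validity_table({
    p <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), p, row.names = FALSE); p
  }), "columns")
})
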