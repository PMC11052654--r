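test_that("cluster statistics have their degenerate closed forms", {
  cells <- cell_frame(matrix(rnorm(100 * 2), 100, 2))
  cells$cluster_id <- rep(1L, 100)
  st <- cluster_stats(cells, 4)
  expect_equal(st$percentages, c(100, 0, 0, 0))
  expect_equal(st$counts, c(100L, 0L, 0L, 0L))
  expect_true(all(is.na(st$medians[2:4, ])))  # empty nodes are NA, not 0

  cells3 <- cell_frame(matrix(c(1, 2, 3, 9, 9, 9), 3, 2))
  cells3$cluster_id <- rep(1L, 3)
  expect_equal(unname(cluster_stats(cells3, 1)$medians[1, 1]), 2)
})

test_that("cluster medians match a brute-force per-group recomputation", {
  set.seed(31)
  cells <- cell_frame(matrix(rnorm(2000 * 3), 2000, 3))
  cells$cluster_id <- sample(1:12, 2000, replace = TRUE)
  st <- cluster_stats(cells, 12)
  expect_equal(sum(st$counts), 2000)
  expect_lt(abs(sum(st$percentages) - 100), 1e-9)
  for (j in 1:12) {
    idx <- which(cells$cluster_id == j)
    for (c in 1:3)
      expect_equal(unname(st$medians[j, c]), median(cells$X[idx, c]))
  }
})

test_that("mean F1 is 1 for any bijective relabeling of the truth", {
  set.seed(32)
  truth <- sample(letters[1:5], 500, replace = TRUE)
  relab <- c(a = "x3", b = "x1", c = "x5", d = "x2", e = "x4")
  f1 <- mean_f1(truth, unname(relab[truth]))
  expect_equal(f1$mean, 1)
  expect_equal(purity(truth, unname(relab[truth])), 1)
})

test_that("a population split across two pure groups scores F1 = 2/3", {
  # 10 events of one population split 5/5 over two predicted groups:
  # the best single match has precision 1, recall 0.5 -> F1 = 2/3
  truth <- rep("A", 10)
  pred <- rep(c("g1", "g2"), each = 5)
  f1 <- mean_f1(truth, pred)
  expect_equal(f1$mean, 2 / 3)
  expect_equal(f1$per_population$recall, 0.5)
  expect_equal(f1$per_population$precision, 1)

  # purity of a single 3A + 1B group
  expect_equal(purity(c("A", "A", "A", "B"), rep("g", 4)), 0.75)
})

test_that("the matching equals exhaustive assignment on random instances", {
  for (i in 1:10) {
    set.seed(200 + i)
    truth <- sample(paste0("P", 1:5), 400, replace = TRUE)
    pred <- sample(paste0("g", 1:8), 400, replace = TRUE)
    got <- mean_f1(truth, pred)
    tab <- table(truth, pred)
    f1m <- cytosom:::f1_matrix(tab)
    expect_equal(got$mean * nrow(tab), exhaustive_total_f1(f1m),
                 tolerance = 1e-10)
    expect_equal(purity(truth, pred), brute_purity(truth, pred))
    # one-to-one: no predicted group matched twice
    mg <- got$per_population$matched_group
    expect_false(anyDuplicated(mg[!is.na(mg)]) > 0)
  }
})

test_that("unassigned truth labels are excluded from scoring", {
  truth <- c(rep("A", 4), rep("unassigned", 4))
  pred <- c(rep("g1", 4), rep("g2", 4))
  expect_equal(mean_f1(truth, pred)$mean, 1)
  expect_equal(purity(truth, pred), 1)
  expect_error(mean_f1(rep("unassigned", 3), c("a", "b", "c")),
               "no events remain")
  expect_error(mean_f1(c("A", "A"), "g"), "length")
})

test_that("scores are invariant to relabeling either argument", {
  set.seed(33)
  truth <- sample(c("A", "B", "C"), 300, replace = TRUE)
  pred <- sample(1:4, 300, replace = TRUE)
  base <- mean_f1(truth, pred)$mean
  expect_equal(mean_f1(truth, c(9, 7, 5, 3)[pred])$mean, base)
  relab <- c(A = "Z", B = "Y", C = "X")
  expect_equal(mean_f1(unname(relab[truth]), pred)$mean, base)
  expect_unit_interval(base)
})

test_that("mapping the training data reproduces the training labels", {
  sr <- small_result()
  mapped <- map_new_data(sr$result, cell_frame(sr$result$cells$X))
  expect_identical(mapped$cluster_id, sr$result$cells$cluster_id)
  expect_identical(mapped$metacluster_id, sr$result$cells$metacluster_id)

  lacking <- cell_frame(sr$result$cells$X[, 1:2],
                        channel_names = c("M1", "M2"))
  expect_error(map_new_data(sr$result, lacking), "M3")
})

test_that("a held-out half maps with F1 close to the training half", {
  sim <- make_mixture(k = 4, d = 6, n = 8000, sep = 6, seed = 77)
  idx <- seq_len(4000)
  train <- cell_frame(sim$frame$X[idx, ])
  test <- cell_frame(sim$frame$X[-idx, ])
  res <- flowsom(train, n_meta = 4, xdim = 5, ydim = 5, rlen = 5, seed = 3)
  f1_train <- mean_f1(sim$truth[idx], res$cells$metacluster_id)$mean
  mapped <- map_new_data(res, test)
  f1_test <- mean_f1(sim$truth[-idx], mapped$metacluster_id)$mean
  expect_lt(abs(f1_train - f1_test), 0.05)
})

test_that("transforms recorded at training are replayed when mapping", {
  sim <- make_mixture(k = 3, d = 4, n = 3000, sep = 6, seed = 55)
  raw <- cell_frame(exp(sim$frame$X))  # strictly positive, skewed
  res <- flowsom(raw, n_meta = 3, xdim = 3, ydim = 3, rlen = 5, seed = 2,
                 arcsinh_cofactor = 5)
  expect_length(res$params$transforms, 1)
  mapped <- map_new_data(res, cell_frame(exp(sim$frame$X)))
  expect_identical(mapped$cluster_id, res$cells$cluster_id)
  expect_length(mapped$transform_log, 1)
})
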