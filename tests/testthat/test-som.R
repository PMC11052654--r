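test_that("code initialization is seeded, samples real events, and guards n", {
  sim <- make_mixture(k = 2, d = 3, n = 1000, seed = 2)
  p <- som_params(xdim = 3, ydim = 3, seed = 42)
  cb1 <- initialize_codes(sim$frame, p)
  cb2 <- initialize_codes(sim$frame, p)
  expect_identical(cb1$codes, cb2$codes)
  expect_equal(nrow(cb1$codes), 9)
  # every initial code is an observed event
  key <- apply(sim$frame$X, 1, paste, collapse = "|")
  expect_true(all(apply(cb1$codes, 1, paste, collapse = "|") %in% key))

  small <- cell_frame(sim$frame$X[1:99, ])
  expect_error(initialize_codes(small, som_params(10, 10, seed = 1)),
               "smaller grid")
})

test_that("training is a fixed point on repeated identical events", {
  v <- c(2, -1, 3)
  frame <- cell_frame(matrix(rep(v, each = 500), 500, 3))
  p <- som_params(xdim = 2, ydim = 2, rlen = 10, seed = 1)
  cb <- train_som(frame, p)
  expect_lt(quantization_error(cb, frame$X), 1e-6)
})

test_that("seeded training is bit-identical across runs", {
  sim <- make_mixture(k = 3, d = 4, n = 2000, seed = 6)
  p <- som_params(xdim = 4, ydim = 4, rlen = 3, seed = 9)
  expect_identical(train_som(sim$frame, p)$codes,
                   train_som(sim$frame, p)$codes)
})

test_that("a lightly over-clustered SOM covers all well-separated blobs", {
  # 3x3 grid on 4 planted blobs: every blob mean must attract at least one
  # code to within 3 within-blob sds (sd = 1), for 5 seeds
  for (seed in 0:4) {
    sim <- gen_mixture(mixture_spec(k = 4, d = 4, n = 4000, separation = 12,
                                    seed = 50 + seed))
    p <- som_params(xdim = 3, ydim = 3, rlen = 10, seed = seed)
    cb <- train_som(sim$frame, p)
    means <- mixture_spec(k = 4, d = 4, n = 1, separation = 12)$means
    D <- as.matrix(dist(rbind(cb$codes, means)))[1:9, 10:13]
    expect_true(all(apply(D, 2, min) < 3))
  }
})

test_that("training rejects non-finite input", {
  X <- matrix(rnorm(30), 10, 3)
  X[3, 2] <- NaN
  expect_error(train_som(cell_frame(X), som_params(2, 2, seed = 1)),
               "NaN/Inf")
})

test_that("BMU assignment is exact, tie-breaks low, and checks dimensions", {
  sim <- make_mixture(k = 2, d = 5, n = 200, seed = 3)
  p <- som_params(xdim = 3, ydim = 3, rlen = 2, seed = 3)
  cb <- train_som(sim$frame, p)
  asg <- assign_bmu(cb, cb$codes[5, , drop = FALSE])
  expect_equal(asg$cluster_id, 5L)
  expect_equal(asg$distance, 0)

  # two equidistant codes at node indices 2 and 7 -> assignment 2
  codes <- matrix(100, 9, 2)
  codes[2, ] <- c(1, 0); codes[7, ] <- c(-1, 0)
  cb$codes <- codes
  expect_equal(assign_bmu(cb, matrix(c(0, 5), 1, 2))$cluster_id, 2L)

  expect_error(assign_bmu(cb, matrix(0, 1, 3)), "columns")
})

test_that("BMU assignment matches the brute-force oracle for all metrics", {
  set.seed(17)
  X <- matrix(rnorm(200 * 5), 200, 5)
  codes <- matrix(rnorm(100 * 5), 100, 5)
  for (metric in c("manhattan", "euclidean", "chebyshev", "cosine")) {
    cb <- structure(list(codes = codes,
                         params = som_params(10, 10, distance = metric)),
                    class = "codebook")
    got <- assign_bmu(cb, X)
    want <- brute_bmu(X, codes, metric)
    expect_identical(got$cluster_id, want$cluster_id)
    expect_equal(got$distance, want$distance, tolerance = 1e-12)
  }
})

test_that("quantization error has its closed forms and improves with training", {
  codes <- matrix(c(0, 0, 10, 10), 2, 2, byrow = TRUE)
  cb <- structure(list(codes = codes, params = som_params(2, 1)),
                  class = "codebook")
  expect_equal(quantization_error(cb, codes), 0)
  expect_equal(quantization_error(cb, matrix(c(0, 3), 1, 2)), 3)
  expect_error(quantization_error(cb, codes[0, , drop = FALSE]), "zero events")

  for (seed in 0:4) {
    sim <- make_mixture(k = 3, d = 4, n = 1500, seed = 70 + seed)
    p <- som_params(xdim = 3, ydim = 3, rlen = 5, seed = seed)
    init <- initialize_codes(sim$frame, p)
    trained <- train_som(sim$frame, p)
    expect_lte(quantization_error(trained, sim$frame$X),
               quantization_error(init, sim$frame$X))
  }
})

test_that("som parameter invariants are enforced", {
  expect_error(som_params(alpha_start = 0.01, alpha_end = 0.05), "alpha")
  expect_error(som_params(1, 1), "xdim")
  expect_error(som_params(radius_start = 1, radius_end = 2), "radius_end")
})
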