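tiny_setup <- function(n = 100, all_node1 = TRUE) {
  set.seed(1)
  cells <- cell_frame(matrix(rnorm(n * 2), n, 2))
  cb <- structure(list(codes = matrix(rnorm(8), 4, 2,
                                      dimnames = list(NULL, c("M1", "M2"))),
                       grid_xy = cbind(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1)),
                       params = som_params(2, 2, seed = 1), trained = TRUE),
                  class = "codebook")
  cells$cluster_id <- if (all_node1) rep(1L, n)
                      else assign_bmu(cb, cells$X)$cluster_id
  meta <- structure(list(labels = c(1L, 1L, 2L, 2L),
                         consensus = diag(4),
                         params = consensus_params(k = 2, seed = 1)),
                    class = "metacluster_result")
  list(cells = cells, cb = cb, meta = meta)
}

test_that("a degenerate all-in-one-node assignment yields percentage 100", {
  ts <- tiny_setup()
  res <- build_result(ts$cells, ts$cb, ts$meta)
  expect_equal(res$clusters$percentages, c(100, 0, 0, 0))
  expect_equal(sum(res$clusters$counts), 100)
})

test_that("label-length mismatch with the codebook is a dimension error", {
  ts <- tiny_setup()
  ts$meta$labels <- c(1L, 1L, 2L)
  expect_error(build_result(ts$cells, ts$cb, ts$meta), "3.*4 nodes")
})

test_that("node and event metacluster labels agree after a planted 2-blob run", {
  sim <- make_mixture(k = 2, d = 3, n = 2000, sep = 10, seed = 9)
  res <- flowsom(sim$frame, n_meta = 2, xdim = 2, ydim = 2, rlen = 5,
                 seed = 4)
  expect_identical(
    as.integer(res$clusters$metacluster[res$cells$cluster_id]),
    res$cells$metacluster_id)
  # relabeling by first appearance: node 1's metacluster is label 1
  expect_equal(res$clusters$metacluster[1], 1L)
  expect_equal(ari(res$cells$metacluster_id, sim$truth), 1)
})

test_that("save/load round-trips labels bit-exactly and floats to 1e-12", {
  sr <- small_result()
  path <- withr::local_tempfile(fileext = ".h5")
  save_result(sr$result, path)
  back <- load_result(path)
  expect_identical(back$cells$cluster_id, sr$result$cells$cluster_id)
  expect_identical(back$cells$metacluster_id, sr$result$cells$metacluster_id)
  expect_identical(back$clusters$metacluster, sr$result$clusters$metacluster)
  expect_lt(max(abs(back$cells$X - sr$result$cells$X)), 1e-12)
  expect_lt(max(abs(back$clusters$codes - sr$result$clusters$codes)), 1e-12)
  expect_equal(back$clusters$medians, sr$result$clusters$medians,
               tolerance = 1e-12)
  expect_equal(back$clusters$mst_edges, sr$result$clusters$mst_edges,
               tolerance = 1e-12)
  expect_equal(back$params$som$radius_start, sr$result$params$som$radius_start)
})

test_that("the container is a valid generic HDF5 file with cell and cluster groups", {
  sr <- small_result()
  path <- withr::local_tempfile(fileext = ".h5")
  save_result(sr$result, path)
  # independent generic reader: h5py through the system python
  script <- paste0(
    "import h5py,sys; f=h5py.File(sys.argv[1]);",
    "assert set(f.keys())=={'cell','cluster'};",
    "assert f['cell/X'].shape==(", nrow(sr$result$cells$X), ",",
    ncol(sr$result$cells$X), ");",
    "assert f['cluster/codes'].shape[0]==", nrow(sr$result$clusters$codes), ";",
    "print('H5OK')")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script),
                                              shQuote(path)),
                                  stdout = TRUE, stderr = TRUE))
  expect_true(any(grepl("H5OK", out)))
})

test_that("missing groups and corrupted arrays are rejected on load", {
  sr <- small_result()
  path <- withr::local_tempfile(fileext = ".h5")

  # a two-modality file missing the cluster group entirely
  cytosom:::.cpp_h5_write(path, list(cell = list(X = matrix(0, 2, 2))))
  expect_error(load_result(path), "cluster")

  # metacluster array of the wrong length
  save_result(sr$result, path)
  obj <- cytosom:::.cpp_h5_read(path)
  obj$cluster$metacluster <- obj$cluster$metacluster[-1]
  path2 <- withr::local_tempfile(fileext = ".h5")
  cytosom:::.cpp_h5_write(path2, obj)
  expect_error(load_result(path2), "metacluster")

  expect_error(load_result(withr::local_tempfile(fileext = ".h5")),
               "not found")
})

test_that("saving to an unwritable location is an I/O error", {
  sr <- small_result()
  expect_error(save_result(sr$result, "/nonexistent-dir-xyz/out.h5"),
               "cannot write")
})

test_that("cluster statistics export one CSV row per node", {
  sr <- small_result()
  path <- withr::local_tempfile(fileext = ".csv")
  export_cluster_stats(sr$result, path)
  df <- read.csv(path)
  expect_equal(nrow(df), nrow(sr$result$clusters$codes))
  expect_true(all(c("node", "x", "y", "count", "percentage", "metacluster",
                    "median_M1") %in% colnames(df)))
  expect_equal(sum(df$count), nrow(sr$result$cells$X))
})
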