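test_that("star values min-max scale per marker with documented degeneracies", {
  cl <- list(medians = cbind(A = c(1, 3, 5), B = c(7, 7, 7),
                             C = c(0, NA, 10)),
             channel_names = c("A", "B", "C"),
             marker_names = c("A", "B", "C"))
  v <- star_values(cl, c("A", "B", "C"))
  expect_equal(v[, "A"], c(0, 0.5, 1))
  expect_equal(v[, "B"], c(0.5, 0.5, 0.5))  # constant marker -> 0.5
  expect_equal(v[, "C"], c(0, 0, 1))        # empty node -> 0
  expect_error(star_values(cl, "CD19"), "unknown marker")
})

test_that("star values are monotone in the medians and stay in [0, 1]", {
  set.seed(41)
  for (i in 1:5) {
    med <- matrix(rnorm(30), 10, 3)
    cl <- list(medians = med, channel_names = paste0("M", 1:3),
               marker_names = paste0("M", 1:3))
    v <- star_values(cl, paste0("M", 1:3))
    expect_unit_interval(v)
    for (c in 1:3)
      expect_equal(order(v[, c]), order(med[, c]))
  }
})

test_that("node radii follow area scaling and track percentages", {
  cl <- list(percentages = c(40, 10, 0, 50))
  sp <- star_spec(markers_shown = "M1", node_scale = 2)
  r <- node_radii(cl, sp)
  expect_equal(r[4], 2)                   # largest node -> node_scale
  expect_equal(r[2], 2 * sqrt(10 / 50))
  # a node at 25% of the max percentage has half the max radius
  cl2 <- list(percentages = c(100, 25))
  expect_equal(node_radii(cl2, sp)[2], 1)
  expect_equal(r[3], 0.05 * 2)            # empty node gets the floor radius
  # ordering matches percentage ordering among non-empty nodes
  expect_equal(order(r[c(1, 2, 4)]), order(cl$percentages[c(1, 2, 4)]))
})

test_that("a 7-marker model draws 7 wedges per glyph", {
  path <- withr::local_tempfile(fileext = ".fcs")
  truth <- make_demo_fcs(path, seed = 3, n = 4000)
  res <- flowsom(read_fcs(path), n_meta = 5, xdim = 3, ydim = 3, rlen = 3,
                 seed = 6)
  gd <- star_glyph_data(res)
  expect_equal(length(unique(gd$wedges$id)), 9 * 7)
  expect_equal(length(gd$markers), 7)
  per_node <- table(gd$wedges$node[!duplicated(gd$wedges$id)])
  expect_true(all(per_node == 7))
  expect_unit_interval(gd$values)
})

test_that("pie fractions are per-node label tallies summing to 1", {
  sr <- small_result()
  p <- plot_pies(sr$result, sr$truth)
  frac <- attr(p, "fractions")
  rs <- rowSums(frac)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-9))
  # oracle recount on a few nodes
  for (j in c(1, 5, 9)) {
    idx <- which(sr$result$cells$cluster_id == j)
    if (length(idx)) {
      tal <- table(factor(sr$truth[idx], levels = colnames(frac)))
      expect_equal(as.numeric(frac[j, ]), as.numeric(tal / sum(tal)))
    }
  }
  expect_error(plot_pies(sr$result, sr$truth[-1]), "length")
})

test_that("figures render to parseable, seed-stable SVG", {
  sr <- small_result()
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  plot_stars(sr$result, file = f1)
  plot_stars(sr$result, file = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  doc <- xml2::read_xml(f1)
  expect_equal(xml2::xml_name(doc), "svg")
  # at least one drawn path per node glyph
  paths <- xml2::xml_find_all(doc, "//*[local-name() = 'path']")
  expect_gte(length(paths), nrow(sr$result$clusters$codes))

  fm <- withr::local_tempfile(fileext = ".svg")
  plot_marker(sr$result, "M1", file = fm)
  expect_equal(xml2::xml_name(xml2::read_xml(fm)), "svg")
  expect_error(plot_marker(sr$result, "nope", file = fm), "unknown marker")
})

test_that("marker view colors follow the median ordering", {
  sr <- small_result()
  p <- plot_marker(sr$result, "M2")
  df <- p$data
  vals <- tapply(df$value, df$node, unique)
  med <- sr$result$clusters$medians[, "M2"]
  expect_equal(as.numeric(vals), as.numeric(med))
})
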