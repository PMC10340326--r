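test_that("neighborhood sampling geometry is exact at integer offsets", {
  const <- matrix(7, 9, 9)
  expect_equal(sample_neighbors(const, 5, 5, lbp_config(p = 8L)), rep(7, 8))
  m <- matrix(seq_len(81), 9, 9)
  got <- sample_neighbors(m, 5, 5, lbp_config(r = 1, p = 4L))
  # counter-clockwise from the +column axis: right, up, left, down
  expect_equal(got, c(m[5, 6], m[4, 5], m[5, 4], m[6, 5]))
  expect_error(sample_neighbors(m, 1, 5, lbp_config()), "border")
})

test_that("bilinear interpolation is exact on a linear ramp", {
  ramp <- matrix(rep(1:9, each = 9), 9, 9)  # I(row, col) = col
  got <- sample_neighbors(ramp, 5, 5, lbp_config(r = 1, p = 8L))
  s2 <- sqrt(2) / 2
  expect_equal(got, c(6, 5 + s2, 5, 5 - s2, 4, 5 - s2, 5, 5 + s2),
               tolerance = 1e-12)
})

test_that("thresholding uses s(x) = 1 for x >= 0 (ties give 1)", {
  expect_identical(threshold_pattern(5, rep(5, 8)), rep(1L, 8))
  expect_identical(threshold_pattern(255, rep(0, 8)), rep(0L, 8))
  expect_identical(threshold_pattern(10, c(9, 10, 11, 9, 10, 11, 9, 10)),
                   c(0L, 1L, 1L, 0L, 1L, 1L, 0L, 1L))
})

test_that("uniformity counts circular transitions", {
  expect_identical(uniformity(rep(0L, 8)), 0L)
  expect_identical(uniformity(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)), 2L)
  expect_identical(uniformity(rep(c(0L, 1L), 4)), 8L)
})

test_that("riu2 coding follows the uniform/non-uniform rule", {
  expect_identical(riu2_code(rep(1L, 8)), 8L)
  expect_identical(riu2_code(rep(0L, 8)), 0L)
  expect_identical(riu2_code(rep(c(0L, 1L), 4)), 9L)
})

test_that("the riu2 table agrees with an independent oracle on all 256 patterns", {
  table8 <- riu2_mapping_table(8L)
  expect_identical(table8, vapply(0:255, oracle_riu2, integer(1)))
  expect_identical(length(unique(table8)), 10L)
  expect_identical(sum(table8 <= 8L), 58L)   # uniform patterns
  expect_identical(sum(table8 == 9L), 198L)  # all non-uniform collapse
})

test_that("every cyclic rotation of a pattern maps to the same riu2 code", {
  table8 <- riu2_mapping_table(8L)
  for (k in 0:255) {
    bits <- as.integer(intToBits(k))[1:8]
    for (rot in 1:7) {
      rotated <- bits[c((rot + 1):8, 1:rot)]
      k2 <- sum(rotated * 2^(0:7))
      expect_identical(table8[k2 + 1L], table8[k + 1L])
    }
  }
})

test_that("the riu2 codomain has p + 2 codes for several p", {
  for (p in c(4L, 6L, 8L, 12L)) {
    expect_identical(length(unique(riu2_mapping_table(p))), p + 2L)
  }
})

test_that("histograms conserve mass and map constant images to code p", {
  const <- matrix(42, 12, 15)
  h <- lbp_histogram(const, lbp_config(p = 8L))
  expect_equal(unname(h), c(rep(0, 8), 1, 0))  # all mass at code 8
  set.seed(1)
  noisy <- matrix(sample(0:255, 20 * 30, replace = TRUE), 20, 30)
  freq <- lbp_histogram(noisy, normalize = "frequency")
  cnts <- lbp_histogram(noisy, normalize = "counts")
  expect_equal(sum(freq), 1)
  expect_equal(sum(cnts), 18 * 28)  # interior pixels
  expect_error(lbp_histogram(matrix(1, 2, 2)), "degenerate")
})

test_that("riu2 histograms are invariant under 90-degree rotations", {
  set.seed(7)
  m <- matrix(runif(40 * 40), 40, 40)
  h0 <- lbp_histogram(m)
  m90 <- rot90cw(m)
  m180 <- rot90cw(m90)
  m270 <- rot90cw(m180)
  expect_identical(lbp_histogram(m90), h0)
  expect_identical(lbp_histogram(m180), h0)
  expect_identical(lbp_histogram(m270), h0)
})

test_that("riu2 histograms are exactly gray-shift invariant", {
  set.seed(8)
  m <- matrix(runif(30 * 30, 0, 200), 30, 30)
  expect_identical(lbp_histogram(m + 37.5), lbp_histogram(m))
})

test_that("feature matrices carry sample ids and round-trip through CSV", {
  d <- tiny_dataset(n_geo = 2L, n_non = 2L)
  imgs <- rasterize_dataset(preprocess_apply(default_preprocess_spec(2L), d),
                            tiny_render())
  f <- lbp_features(imgs)
  expect_identical(dim(f), c(4L, 10L))
  expect_identical(rownames(f), d$sample_ids)
  expect_equal(unname(rowSums(f)), rep(1, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(f, d$labels, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_identical(names(back)[1:2], c("sample_id", "label"))
  expect_equal(as.matrix(back[, -(1:2)]), f, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("single-pixel and image-level code paths agree", {
  set.seed(9)
  m <- matrix(runif(15 * 15, 0, 255), 15, 15)
  cfg <- lbp_config()
  codes <- nmrlbp:::lbp_code_matrix(m, cfg)
  for (rc in list(c(2, 2), c(8, 11), c(14, 14))) {
    nb <- sample_neighbors(m, rc[1], rc[2], cfg)
    expect_identical(codes[rc[1] - 1L, rc[2] - 1L],
                     riu2_code(threshold_pattern(m[rc[1], rc[2]], nb)))
  }
})
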