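# Huang thresholding, nucleus-seeded segmentation, ROI filtering and
# transfection gating.

test_that("Huang threshold separates bimodal intensities", {
  set.seed(1)
  img <- matrix(c(stats::rnorm(5000, 20, 3), stats::rnorm(5000, 200, 10)),
                100, 100)
  thr <- huang_threshold(img)
  expect_gt(thr, 20)
  expect_lt(thr, 200)
  two <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
  t2 <- huang_threshold(two)
  expect_gt(t2, 0)
  expect_lt(t2, 255)
  expect_error(huang_threshold(matrix(7, 5, 5)), "distinct")
})

test_that("Huang threshold is shift-equivariant at equal binning", {
  set.seed(2)
  img <- matrix(c(stats::rnorm(2000, 30, 5), stats::rnorm(2000, 150, 20)),
                40, 100)
  expect_equal(huang_threshold(img + 17.5), huang_threshold(img) + 17.5,
               tolerance = 1e-9)
})

test_that("non-touching cells segment one ROI per nucleus", {
  f <- gen_if_field(20, frac_transfected = 0.3, seed = 3)
  seg <- segment_cells(f$channels$dapi, f$channels$cellmask, f$pixel_size,
                       channels = f$channels[c("reporter", "stain")])
  expect_equal(nrow(seg$rois), 20)
  # every ground-truth nucleus centre falls in a distinct ROI
  px <- round(f$truth$x / f$pixel_size)
  py <- round(f$truth$y / f$pixel_size)
  labs <- seg$labels[cbind(py, px)]
  expect_true(all(labs > 0))
  expect_equal(length(unique(labs)), 20)
})

test_that("touching nuclei are split by the watershed", {
  disk <- function(img, cx, cy, r, val) {
    d2 <- outer(seq_len(nrow(img)) - cy, seq_len(ncol(img)) - cx,
                function(a, b) a^2 + b^2)
    img[d2 <= r^2] <- val
    img
  }
  dapi <- matrix(10, 120, 120)
  dapi <- disk(dapi, 50, 60, 8, 500)
  dapi <- disk(dapi, 62, 60, 8, 500)    # overlapping disks
  cm <- matrix(10, 120, 120)
  cm <- disk(cm, 56, 60, 25, 300)
  seg <- segment_cells(dapi, cm, pixel_size = 0.5)
  expect_equal(nrow(seg$rois), 2)
})

test_that("empty fields give zero ROIs with a warning", {
  f <- gen_if_field(0, seed = 4)
  expect_warning(
    seg <- segment_cells(f$channels$dapi, f$channels$cellmask,
                         f$pixel_size),
    "no nuclei")
  expect_equal(nrow(seg$rois), 0)
})

test_that("segmented cell counts track the true count within one", {
  for (i in 1:6) {
    n <- c(5, 14, 23, 32, 41, 50)[i]
    f <- gen_if_field(n, seed = 10 + i)
    seg <- segment_cells(f$channels$dapi, f$channels$cellmask,
                         f$pixel_size)
    expect_lte(abs(nrow(seg$rois) - n), 1)
  }
})

test_that("ROI filtering applies strict area and border rules", {
  rois <- data.frame(label = 1:4,
                     area_um2 = c(10, 10.5, 50, 200),
                     touches_border = c(FALSE, FALSE, TRUE, FALSE))
  kept <- filter_rois(rois, min_area = 10, exclude_border = TRUE)
  expect_equal(kept$label, c(2L, 4L))      # area exactly 10 is excluded
  all_pass <- data.frame(label = 1:2, area_um2 = c(20, 30),
                         touches_border = c(FALSE, FALSE))
  expect_equal(filter_rois(all_pass), all_pass)
})

test_that("the gating cutoff is control mean plus three SDs", {
  ctrl <- c(35, 50, 65, 50, 50, 50, 50, 50, 50, 50)
  g <- gate_positive(c(90, 100), ctrl)
  expect_equal(g$cutoff, mean(ctrl) + 3 * stats::sd(ctrl))
  expect_error(gate_positive(1, ctrl[1:5]), "at least 10")
  g2 <- gate_positive(c(90, 100), cutoff = 95)
  expect_equal(g2$positive, c(FALSE, TRUE))
})

test_that("gating of a pure Gaussian population has the z = 3 tail rate", {
  set.seed(6)
  ctrl <- stats::rnorm(10000, 50, 15)
  g <- gate_positive(ctrl, ctrl)
  expect_lt(abs(100 * g$fraction_positive - 0.135), 0.1)
})

test_that("well-separated transfected cells are gated perfectly", {
  set.seed(7)
  ctrl <- stats::rnorm(10000, 50, 15)
  transfected <- stats::rnorm(10000, 50 + 10 * 15, 15)
  g <- gate_positive(transfected, ctrl)
  expect_equal(g$fraction_positive, 1)
  # offset of 6 SDs: sensitivity at the z = 3 upper tail (99.87%),
  # false-positive rate below 0.5%
  g6 <- gate_positive(stats::rnorm(10000, 50 + 6 * 15, 15), ctrl)
  expect_gte(g6$fraction_positive, 0.995)
  expect_lte(gate_positive(ctrl, ctrl)$fraction_positive, 0.005)
})

test_that("staining background subtraction is exact and invertible", {
  expect_equal(subtract_staining_background(c(100, 200), 50), c(50, 150))
  expect_equal(subtract_staining_background(c(1, 2), 0), c(1, 2))
  v <- c(12.5, 80, 3)
  expect_equal(subtract_staining_background(v, 20) + 20, v)
})

test_that("segmentation is deterministic", {
  f <- gen_if_field(12, frac_transfected = 0.4, seed = 8)
  s1 <- segment_cells(f$channels$dapi, f$channels$cellmask, f$pixel_size,
                      channels = f$channels["reporter"])
  s2 <- segment_cells(f$channels$dapi, f$channels$cellmask, f$pixel_size,
                      channels = f$channels["reporter"])
  expect_identical(s1$rois, s2$rois)
})

test_that("the field-level wrapper gates transfected cells", {
  f <- gen_if_field(26, frac_transfected = 0.4, transfected_offset = 300,
                    seed = 9)
  res <- if_quantify(f)
  keep <- f$truth  # compare against truth by nearest ROI reporter mean
  expect_equal(res$gating$n_positive, sum(keep$transfected))
})
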