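test_that("skeletonization reduces bars to center-row paths and keeps loops", {
  empty <- skeletonize_mask(binary_mask(matrix(FALSE, 10, 10), 450))
  expect_equal(sum(empty$pixels), 0)

  sk <- skeletonize_mask(bar_mask(200, 9, pad = 10))
  idx <- which(sk$pixels, arr.ind = TRUE)
  expect_equal(max(rootmorph:::cpp_label(sk$pixels, 8L)), 1)
  expect_true(nrow(idx) >= 184 && nrow(idx) <= 200)
  expect_true(all(idx[, 1] == 15)) # center row of rows 11..19

  ann <- skeletonize_mask(annulus_mask(40, 30))
  lk <- rootmorph:::skeleton_links(ann$pixels)
  deg <- rootmorph:::accumulate_endpoints(lk, 1, 1, 1)
  expect_equal(sum(ann$pixels & deg == 1), 0) # no endpoints: closed loop
  expect_equal(max(rootmorph:::cpp_label(ann$pixels, 8L)), 1)

  # at most 1 px wide: no full 2x2 block
  for (m in list(sk, ann)) {
    S <- m$pixels; h <- nrow(S); w <- ncol(S)
    blocks <- S[-h, -w] & S[-1, -w] & S[-h, -1] & S[-1, -1]
    expect_equal(sum(blocks), 0)
  }
})

test_that("local diameters read 2x the distance transform", {
  bar <- bar_mask(200, 9)
  sk <- skeletonize_mask(bar)
  d <- local_diameters(bar, sk)
  expect_true(all(abs(d[10:180] - 9) <= 1)) # interior pixels

  single <- binary_mask(matrix(c(rep(FALSE, 12), TRUE, rep(FALSE, 12)), 5), 450)
  sks <- skeleton(single$pixels, 450)
  expect_equal(local_diameters(single, sks), 2)

  disc <- disc_mask(15)
  c0 <- 22 # center of the 43x43 canvas
  skd <- skeleton(matrix(FALSE, 43, 43), 450); skd$pixels[c0, c0] <- TRUE
  expect_lt(abs(local_diameters(disc, skd) - 30), 1 + 1e-9)

  bad <- skeleton(matrix(TRUE, 5, 5), 450)
  expect_error(local_diameters(single, bad), class = "rootmorph_validation_error")
})

test_that("chain and kimura link arithmetic matches hand counts", {
  two_orth <- skeleton(matrix(c(TRUE, TRUE, FALSE, FALSE), 2), 450)
  expect_equal(skeleton_length(two_orth, "chain", end_correction = FALSE)$length_px, 1)
  two_diag <- skeleton(diag(2) == 1, 450)
  expect_equal(skeleton_length(two_diag, "chain", end_correction = FALSE)$length_px,
               sqrt(2))
  path <- matrix(FALSE, 5, 220); path[3, 11:210] <- TRUE
  expect_equal(skeleton_length(skeleton(path, 450), "chain",
                               end_correction = FALSE)$length_px, 199)
  # kimura equals chain on pure-orthogonal and pure-diagonal paths
  dg <- skeleton(diag(50) == 1, 450)
  expect_equal(skeleton_length(dg, "kimura", end_correction = FALSE)$length_px,
               49 * sqrt(2), tolerance = 1e-12)
  # corrected width-9 bar recovers its full length within 3%
  bar <- bar_mask(200, 9)
  L <- skeleton_length(skeletonize_mask(bar), method = "kimura",
                       end_correction = TRUE, mask = bar)$length_px
  expect_lt(abs(L - 200) / 200, 0.03)
  expect_error(skeleton_length(two_orth, "nope"))
})

test_that("per-pixel shares conserve the total length exactly", {
  set.seed(21)
  tr <- generate_tray(small_scene(), seed = 31)
  mask <- binary_mask(tr$truth$root_mask, 450)
  sk <- skeletonize_mask(mask)
  for (meth in c("chain", "kimura")) {
    len <- skeleton_length(sk, meth, end_correction = TRUE, mask = mask)
    expect_equal(sum(len$shares_px), len$length_px, tolerance = 1e-12)
    d <- local_diameters(mask, sk)
    h <- build_histogram(sk, d, len$shares_px)
    expect_equal(sum(h$length_cm),
                 len$length_px / scale_calibration(450)$px_per_cm,
                 tolerance = 1e-9)
  }
})

test_that("histogram bins place a 9-px-wide path at 0.508 mm", {
  path <- matrix(FALSE, 5, 220); path[3, 11:210] <- TRUE
  sk <- skeleton(path, 450)
  len <- skeleton_length(sk, "chain", end_correction = FALSE)
  h <- build_histogram(sk, rep(9, 200), len$shares_px,
                       calib = scale_calibration(450))
  occ <- which(h$length_cm > 0)
  expect_equal(occ, 6L) # 9 px = 0.508 mm -> bin [0.5, 0.6)
  expect_equal(h$length_cm[6], 199 / (450 / 2.54), tolerance = 1e-12)
  e <- build_histogram(skeleton(matrix(FALSE, 4, 4), 450), numeric(0), numeric(0),
                       calib = scale_calibration(450))
  expect_true(all(e$length_cm == 0))
})

test_that("measured cm quantities are stable under a DPI change", {
  # one fixed serpentine rendered at 450 and 900 DPI
  measure_at <- function(dpi) {
    ppcm <- dpi / 2.54
    t_cm <- seq(0, 6, by = 0.3 / ppcm)
    pr <- (1 + 0.8 * sin(t_cm * 2)) * ppcm
    pc <- (0.5 + t_cm) * ppcm
    h <- as.integer(ceiling(max(pr)) + ppcm); w <- as.integer(ceiling(max(pc)) + ppcm)
    rs <- rootmorph:::render_stroke(pr, pc, 0.75 / 10 * ppcm, h, w)
    M <- matrix(FALSE, h, w)
    M[(rs$r0 + 1):(rs$r1 + 1), (rs$c0 + 1):(rs$c1 + 1)] <- rs$truth
    list(hist = measure_mask(binary_mask(M, dpi)),
         true_cm = sum(sqrt(diff(pr)^2 + diff(pc)^2)) / ppcm)
  }
  lo <- measure_at(450); hi <- measure_at(900)
  expect_lt(abs(sum(lo$hist$length_cm) - sum(hi$hist$length_cm)) /
              sum(hi$hist$length_cm), 0.03)
  expect_lt(abs(sum(lo$hist$length_cm) - lo$true_cm) / lo$true_cm, 0.03)
  # occupied diameter neighbourhood identical in mm
  expect_lt(abs(sum(bin_midpoints(lo$hist) * lo$hist$length_cm) / sum(lo$hist$length_cm) -
                sum(bin_midpoints(hi$hist) * hi$hist$length_cm) / sum(hi$hist$length_cm)),
            0.1)
})

test_that("straight-stroke length varies little with orientation", {
  lens <- vapply(c(0, 30, 45), function(a) {
    m <- stroke_mask(a, len_px = 800, w_px = 9)
    sum(measure_mask(m)$length_cm)
  }, 0)
  expect_lt((max(lens) - min(lens)) / min(lens), 0.03)
  true_cm <- 800 / (450 / 2.54)
  expect_true(all(abs(lens - true_cm) / true_cm < 0.05))
})
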