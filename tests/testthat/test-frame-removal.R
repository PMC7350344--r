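test_that("edge detection responds to steps and nothing else", {
  expect_equal(sum(detect_edges(const_image(0.7))$pixels), 0)
  # vertical step between 0-based columns 9 and 10
  S <- matrix(0, 20, 20); S[, 11:20] <- 1
  e <- detect_edges(raster_image(S, 450), 0.1, 0.3)
  cols <- unique(which(e$pixels, arr.ind = TRUE)[, 2]) - 1L
  expect_true(all(cols %in% c(9L, 10L)))
  expect_true(length(cols) > 0)
  expect_error(detect_edges(const_image(0.5), 0.5, 0.2),
               class = "rootmorph_validation_error")
})

test_that("hough_lines finds a collinear pixel row with exact votes", {
  M <- matrix(FALSE, 60, 250)
  M[21, 26:225] <- TRUE # 200 pixels on 0-based row 20
  lines <- hough_lines(binary_mask(M, 450), rho_res = 1, theta_res = pi / 360,
                       min_votes = 100)
  expect_gt(nrow(lines), 0)
  top <- lines[1, ]
  expect_equal(top$votes, 200)
  expect_lt(abs(top$theta - pi / 2), pi / 360 + 1e-12)
  expect_lt(abs(top$rho - 20), 1 + 1e-12)
  expect_equal(nrow(hough_lines(binary_mask(matrix(FALSE, 10, 10), 450))), 0)
})

test_that("hough accumulator matches a brute-force accumulator exactly", {
  for (seed in 1:3) {
    set.seed(seed)
    M <- matrix(FALSE, 48, 64)
    M[sample.int(48 * 64, 120)] <- TRUE
    rho_res <- 1; theta_res <- pi / 90
    pts <- which(M, arr.ind = TRUE)
    ntheta <- as.integer(round(pi / theta_res))
    nrho_half <- as.integer(ceiling(sqrt(48^2 + 64^2) / rho_res)) + 1L
    acc <- rootmorph:::cpp_hough_accumulate(as.integer(pts[, 1] - 1L),
                                            as.integer(pts[, 2] - 1L),
                                            nrho_half, rho_res, ntheta, theta_res)
    expect_identical(acc, brute_hough_acc(M, rho_res, theta_res))
  }
})

test_that("fit_frame reproduces the half-open interior arithmetic", {
  lines <- data.frame(
    rho = c(10, 990, 10, 690),
    theta = c(pi / 2, pi / 2, 0, 0),
    votes = c(900, 900, 900, 900))
  fr <- fit_frame(lines, c(1000, 700), safety_margin_px = 3)
  expect_identical(c(fr$row_min, fr$row_max, fr$col_min, fr$col_max),
                   c(14L, 987L, 14L, 687L))
  expect_error(fit_frame(lines[0, ], c(100, 100)), class = "rootmorph_frame_error")
  # nested rectangles: outermost pair wins
  nested <- data.frame(
    rho = c(10, 990, 100, 900, 200, 800, 10, 690, 100, 600),
    theta = c(pi / 2, pi / 2, pi / 2, pi / 2, pi / 2, pi / 2, 0, 0, 0, 0),
    votes = rep(500, 10))
  fr2 <- fit_frame(nested, c(1000, 700), safety_margin_px = 3)
  expect_identical(c(fr2$row_min, fr2$row_max), c(14L, 987L))
  expect_identical(c(fr2$col_min, fr2$col_max), c(14L, 687L))
})

test_that("cropping composes and never enlarges", {
  img <- raster_image(matrix(runif(1000 * 700), 1000), 450)
  lines <- data.frame(rho = c(10, 990, 10, 690),
                      theta = c(pi / 2, pi / 2, 0, 0), votes = rep(900, 4))
  fr <- fit_frame(lines, c(1000, 700))
  cr <- crop_interior(img, fr)
  expect_identical(dim(cr$pixels), c(973L, 673L))
  expect_identical(attr(cr, "offset"), c(14L, 14L))
  # crop of a crop: offsets add
  lines2 <- data.frame(rho = c(5, 900, 5, 600),
                       theta = c(pi / 2, pi / 2, 0, 0), votes = rep(800, 4))
  fr2 <- fit_frame(lines2, dim(cr$pixels))
  cr2 <- crop_interior(cr, fr2)
  expect_identical(attr(cr2, "offset"), c(14L + 9L, 14L + 9L))
  expect_true(all(dim(cr2$pixels) <= dim(cr$pixels)))
  # identity-like crop keeps content
  expect_identical(cr2$pixels[1, 1],
                   img$pixels[14 + 9 + 1, 14 + 9 + 1])
})

test_that("synthetic frames (straight and tilted) are cropped frame-free", {
  for (tilt in c(0, 2)) {
    p <- tray_params(scale = 0.15, n_fibrous = 0, n_storage = 0, n_dirt = 0,
                     tilt_deg = tilt)
    tr <- generate_tray(p, seed = 5 + tilt)
    img <- to_grayscale(median_project(tr$stack))
    edges <- detect_edges(img)
    lines <- hough_lines(edges, min_votes = 0.3 * min(image_shape(img)))
    fr <- fit_frame(lines, image_shape(img))
    cr <- crop_interior(img, fr)
    off <- attr(cr, "offset"); sh <- dim(cr$pixels)
    fm <- tr$truth$frame_mask[(off[1] + 1):(off[1] + sh[1]),
                              (off[2] + 1):(off[2] + sh[2])]
    expect_equal(sum(fm), 0, info = sprintf("tilt %d deg", tilt))
    if (tilt == 2) {
      hor <- lines[abs(lines$theta - pi / 2) < 5 * pi / 180, ]
      expect_true(any(abs(abs(hor$theta - pi / 2) - 2 * pi / 180) < pi / 360 + 1e-9))
    }
  }
})
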