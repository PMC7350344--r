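# Shared fixtures: small geometric masks, scaled-down scene parameters, and
# independent brute-force oracles used to cross-check the implementation.

# constant-intensity grayscale image
const_image <- function(value, h = 20, w = 20, dpi = 450) {
  raster_image(matrix(value, h, w), dpi)
}

# flat-ended horizontal bar mask (len x wid px) centred in a padded canvas
bar_mask <- function(len = 200, wid = 9, pad = 10, dpi = 450) {
  M <- matrix(FALSE, wid + 2 * pad, len + 2 * pad)
  M[(pad + 1):(pad + wid), (pad + 1):(pad + len)] <- TRUE
  binary_mask(M, dpi)
}

# disc mask: foreground where distance from center < r
disc_mask <- function(r = 15, pad = 6, dpi = 450) {
  n <- 2 * (r + pad) + 1
  ii <- matrix(rep(seq_len(n), n), n); jj <- t(ii)
  c0 <- r + pad + 1
  binary_mask(sqrt((ii - c0)^2 + (jj - c0)^2) < r, dpi)
}

# annulus mask (outer radius ro, inner ri)
annulus_mask <- function(ro = 40, ri = 30, pad = 6, dpi = 450) {
  n <- 2 * (ro + pad) + 1
  ii <- matrix(rep(seq_len(n), n), n); jj <- t(ii)
  c0 <- ro + pad + 1
  d <- sqrt((ii - c0)^2 + (jj - c0)^2)
  binary_mask(d < ro & d >= ri, dpi)
}

# flat-capped straight stroke mask at a given angle, via the same renderer
# the generator uses
stroke_mask <- function(angle_deg, len_px = 800, w_px = 9, pad = 40, dpi = 450) {
  a <- angle_deg * pi / 180
  t <- seq(0, len_px, by = 0.3)
  pr <- t * sin(a) + pad; pc <- t * cos(a) + pad
  h <- as.integer(ceiling(max(pr)) + pad); w <- as.integer(ceiling(max(pc)) + pad)
  rs <- rootmorph:::render_stroke(pr, pc, w_px, h, w)
  M <- matrix(FALSE, h, w)
  M[(rs$r0 + 1):(rs$r1 + 1), (rs$c0 + 1):(rs$c1 + 1)] <- rs$truth
  binary_mask(M, dpi)
}

# small, fast scene: a sub-A4 tray that still exercises every stage
small_scene <- function(...) {
  tray_params(scale = 0.25, n_fibrous = 6, n_storage = 2, length_cm = c(2, 5),
              n_dirt = 3, ...)
}

quiet_config <- function(...) {
  cfg <- utils::modifyList(default_config(), list(...))
  cfg$log_level <- "quiet"
  cfg
}

# precision/recall of the pipeline mask against the generator's truth raster,
# mapped through the crop offset
mask_pr <- function(tray, cfg = quiet_config()) {
  cfg$debug <- TRUE
  h <- run_tray(tray$stack, cfg)
  ints <- attr(h, "intermediates")
  mask <- ints$mask
  off <- attr(ints$cropped, "offset")
  sh <- dim(mask$pixels)
  tc <- tray$truth$root_mask[(off[1] + 1):(off[1] + sh[1]),
                             (off[2] + 1):(off[2] + sh[2])]
  tp <- sum(mask$pixels & tc)
  list(precision = tp / max(1, sum(mask$pixels)),
       recall = tp / max(1, sum(tc)),
       hist = h, intermediates = ints, truth_crop = tc, offset = off)
}

# ---- independent oracles ---------------------------------------------------

# brute-force Hough accumulator: explicit double loop over edge pixels and
# angle bins, same (rho, theta) grid definition as the implementation
brute_hough_acc <- function(mask, rho_res, theta_res) {
  pts <- which(mask, arr.ind = TRUE)
  h <- nrow(mask); w <- ncol(mask)
  ntheta <- max(1L, as.integer(round(pi / theta_res)))
  nrho_half <- as.integer(ceiling(sqrt(h^2 + w^2) / rho_res)) + 1L
  acc <- matrix(0L, 2L * nrho_half + 1L, ntheta)
  for (p in seq_len(nrow(pts))) {
    y <- pts[p, 1] - 1; x <- pts[p, 2] - 1
    for (t in seq_len(ntheta)) {
      th <- (t - 1) * theta_res
      idx <- as.integer(round((x * cos(th) + y * sin(th)) / rho_res)) + nrho_half + 1L
      acc[idx, t] <- acc[idx, t] + 1L
    }
  }
  acc
}

# exhaustive Otsu scan: per interior bin edge, class statistics recomputed
# from scratch
brute_otsu <- function(hist) {
  w <- hist$length_cm
  mids <- bin_midpoints(hist)
  p <- w / sum(w)
  nb <- length(w)
  best_t <- NA_real_; best_s <- -Inf
  for (i in seq_len(nb - 1)) {
    w0 <- sum(p[1:i]); w1 <- sum(p[(i + 1):nb])
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:i] * mids[1:i]) / w0
    mu1 <- sum(p[(i + 1):nb] * mids[(i + 1):nb]) / w1
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best_s + 1e-15) { best_s <- s; best_t <- hist$bin_edges[i + 1] }
  }
  list(diameter_mm = best_t, between_class_variance = best_s)
}

# random occupied histogram for Otsu stress tests
random_histogram <- function(seed, nb = 60) {
  set.seed(seed)
  edges <- seq(0, by = 0.1, length.out = nb + 1)
  lens <- numeric(nb)
  k <- sample(2:12, 1)
  lens[sample.int(nb, k)] <- runif(k, 0.5, 30)
  dl_histogram(edges, lens)
}
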