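test_that("pixel sampling is deterministic, complete on small images, unique", {
  img <- raster_image(matrix(runif(100), 10), 450)
  s <- sample_pixels(img, max_samples = 1000, seed = 3)
  expect_equal(nrow(s), 100)
  big <- raster_image(matrix(runif(500 * 500), 500), 450)
  a <- sample_pixels(big, max_samples = 10000, seed = 42)
  b <- sample_pixels(big, max_samples = 10000, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a), 10000)
  expect_error(sample_pixels(img, max_samples = 10), class = "rootmorph_validation_error")
})

test_that("EM recovers well-separated 1-D mixtures and is monotone", {
  set.seed(123)
  x <- c(rnorm(5000, 0.2, 0.05), rnorm(5000, 0.8, 0.05))
  fit <- fit_mixture(x, K = 2, seed = 9)
  mu <- sort(fit$means[, 1])
  expect_lt(abs(mu[1] - 0.2), 0.01)
  expect_lt(abs(mu[2] - 0.8), 0.01)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$vars >= 1e-6 - 1e-15))
  # independent likelihood evaluation agrees with the trace's final value
  ll <- sum(log(fit$weights[1] * dnorm(x, fit$means[1, 1], sqrt(fit$vars[1, 1])) +
                fit$weights[2] * dnorm(x, fit$means[2, 1], sqrt(fit$vars[2, 1]))))
  expect_equal(ll, fit$loglik_trace[length(fit$loglik_trace)], tolerance = 1e-6)
})

test_that("EM agrees with an independent mixture fitter on a 2-mode sample", {
  set.seed(5)
  x <- c(rnorm(3000, 0.25, 0.04), rnorm(3000, 0.75, 0.06))
  fit <- fit_mixture(x, K = 2, seed = 1)
  suppressMessages(library(mclust))
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means[, 1]), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.01)
})

test_that("degenerate samples yield a flagged, floored model instead of a crash", {
  expect_warning(fit <- fit_mixture(rep(0.37, 200), K = 3, seed = 1))
  expect_true(fit$degenerate)
  expect_equal(fit$means[1, 1], 0.37)
  expect_equal(fit$vars[1, 1], 1e-6)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  fit1 <- fit_mixture(rep(0.37, 50), K = 1, seed = 1)
  expect_equal(fit1$means[1, 1], 0.37)
  expect_equal(fit1$vars[1, 1], 1e-6)
})

test_that("posterior map matches direct density evaluation and sums to one", {
  set.seed(11)
  img <- raster_image(matrix(runif(30 * 20), 30), 450)
  fit <- fit_mixture(as.numeric(img$pixels), K = 3, seed = 2)
  post <- posterior_map(img, fit)
  expect_true(all(abs(rowSums(post) - 1) < 1e-9))
  x <- img$pixels[13, 7]
  dens <- fit$weights * dnorm(x, fit$means[, 1], sqrt(fit$vars[, 1]))
  expect_equal(post[13 + (7 - 1) * 30, ], dens / sum(dens), tolerance = 1e-9)
  # well-separated component center -> near-certain posterior
  m2 <- fit_mixture(c(rnorm(500, 0.1, 0.01), rnorm(500, 0.9, 0.01)), K = 2, seed = 3)
  k_dark <- darkest_components(m2, 1)
  p2 <- posterior_map(const_image(m2$means[k_dark, 1], 2, 2), m2)
  expect_gt(p2[1, k_dark], 0.999)
})

test_that("root classification honours the tie rule at min_posterior", {
  post <- cbind(c(0.5, 0.49, 1, 0), c(0.5, 0.51, 0, 1))
  attr(post, "shape") <- c(2L, 2L); attr(post, "dpi") <- 450
  mask <- classify_root_pixels(post, 1L, 0.5)
  expect_identical(as.vector(mask$pixels), c(TRUE, FALSE, TRUE, FALSE))
  expect_error(classify_root_pixels(post, 5L), class = "rootmorph_validation_error")
  expect_error(classify_root_pixels(post, integer(0)), class = "rootmorph_validation_error")
})

test_that("clean_mask removes specks and fills only small enclosed holes", {
  empty <- binary_mask(matrix(FALSE, 30, 30), 450)
  expect_equal(sum(clean_mask(empty)$pixels), 0)

  M <- matrix(FALSE, 40, 40)
  M[5:6, 5] <- TRUE; M[5, 6] <- TRUE            # 3-px speck
  M[20:30, 20:30] <- TRUE; M[24:25, 24:26] <- TRUE # block ...
  M[24, 24] <- FALSE; M[24, 25] <- FALSE        # ... with a 2-px hole
  cl <- clean_mask(binary_mask(M, 450), min_speck_px = 10, fill_hole_px = 10)
  expect_equal(sum(cl$pixels[5:6, 5:6]), 0)
  expect_true(all(cl$pixels[20:30, 20:30]))
  # hole at/above the limit stays
  cl2 <- clean_mask(binary_mask(M, 450), min_speck_px = 10, fill_hole_px = 2)
  expect_false(cl2$pixels[24, 24])

  ann <- annulus_mask(ro = 10, ri = 2)
  filled <- clean_mask(ann, min_speck_px = 0, fill_hole_px = 20)
  expect_true(all(filled$pixels[disc_mask(10, pad = 6)$pixels]))
})

test_that("dirt removal keeps elongated or very large components only", {
  bar <- bar_mask(200, 9)
  res <- remove_dirt(bar, min_elongation = 3, max_area_px = 50000)
  expect_equal(sum(res$mask$pixels), sum(bar$pixels))
  expect_equal(nrow(res$removed), 0)
  expect_gt(res$kept$elongation, 20)

  disc <- disc_mask(15)
  res2 <- remove_dirt(disc, min_elongation = 3, max_area_px = 50000)
  expect_equal(sum(res2$mask$pixels), 0)
  expect_equal(nrow(res2$removed), 1)
  expect_lt(res2$removed$elongation, 1.1)

  # big compact mats survive via the area escape hatch
  res3 <- remove_dirt(disc, min_elongation = 3, max_area_px = 100)
  expect_equal(sum(res3$mask$pixels), sum(disc$pixels))

  e <- remove_dirt(binary_mask(matrix(FALSE, 5, 5), 450))
  expect_equal(sum(e$mask$pixels), 0)
  expect_equal(nrow(e$removed), 0)
  # never adds pixels
  expect_true(all(res2$mask$pixels <= disc$pixels))
})
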