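# Pixel classification into root vs non-root via a Gaussian mixture model
# fitted by EM, followed by connected-component cleanup and shape-based dirt
# removal.
#
# Default feature space is grayscale intensity (1-D mixture, K = 3: bright
# background, dark root, intermediate dirt/shadow); the root component is the
# darkest mean unless overridden.

#' Binary mask container
#'
#' @param pixels Logical matrix.
#' @param dpi Dots per inch carried from the source image.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, dpi) {
  if (!is.matrix(pixels)) abort_validation("`pixels` must be a matrix")
  storage.mode(pixels) <- "logical"
  calib <- scale_calibration(dpi)
  structure(list(pixels = pixels, dpi = calib$dpi), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d px, %d foreground px, %.0f dpi\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels), x$dpi))
  invisible(x)
}

# pixel feature matrix (n x d): d = 1 for gray, 3 for rgb
pixel_features <- function(image) {
  if (n_channels(image) == 1L) matrix(as.numeric(image$pixels), ncol = 1)
  else matrix(image$pixels, ncol = 3)
}

#' Subsample pixel features for mixture fitting
#'
#' Uniform random subsample of pixel feature vectors, without replacement,
#' deterministic given `seed`. If the image has no more than `max_samples`
#' pixels, all pixels are returned.
#'
#' @param image A [raster_image()].
#' @param max_samples Maximum number of pixels to return (>= 100).
#' @param seed Integer seed.
#' @return A numeric matrix (n x channels) of features in \[0, 1\].
#' @export
sample_pixels <- function(image, max_samples = 50000, seed = 1) {
  if (max_samples < 100) abort_validation("`max_samples` must be >= 100")
  feats <- pixel_features(image)
  n <- nrow(feats)
  if (n <= max_samples) return(feats)
  idx <- with_local_seed(seed, sample.int(n, max_samples, replace = FALSE))
  feats[idx, , drop = FALSE]
}

# mixture log-likelihood and log-responsibilities via log-sum-exp;
# x: n x d, means/vars: K x d
mixture_logdens <- function(x, weights, means, vars) {
  n <- nrow(x); K <- nrow(means)
  ll <- matrix(0, n, K)
  for (k in seq_len(K)) {
    lk <- log(weights[k])
    for (d in seq_len(ncol(x)))
      lk <- lk + dnorm(x[, d], means[k, d], sqrt(vars[k, d]), log = TRUE)
    ll[, k] <- lk
  }
  ll
}

logsumexp_rows <- function(m) {
  mx <- m[, 1]
  if (ncol(m) > 1) for (k in 2:ncol(m)) mx <- pmax(mx, m[, k])
  s <- exp(m[, 1] - mx)
  if (ncol(m) > 1) for (k in 2:ncol(m)) s <- s + exp(m[, k] - mx)
  mx + log(s)
}

# k-means++-style seeding: first center uniform, later centers with
# probability proportional to squared distance to the nearest chosen center
kmeanspp_centers <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(0, K, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (K > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (k in 2:K) {
      if (sum(d2) <= 0) idx <- sample.int(n, 1)
      else idx <- sample.int(n, 1, prob = d2 / sum(d2))
      centers[k, ] <- x[idx, ]
      dk <- rowSums((x - matrix(centers[k, ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, dk)
    }
  }
  centers
}

#' Fit a Gaussian mixture model by EM
#'
#' Diagonal-covariance Gaussian mixture fitted with expectation-maximisation,
#' seeded by k-means++-style center selection. Iteration stops when the
#' absolute log-likelihood gain falls below `tol` or `max_iter` is reached. A
#' variance floor is applied at every M-step. The fit is deterministic given
#' `seed`, and the per-iteration log-likelihood trace is retained.
#'
#' Degenerate input (all samples identical with K > 1) yields a model with one
#' dominant component, floored variances and `degenerate = TRUE` instead of an
#' error.
#'
#' @param samples Numeric matrix (n x channels) from [sample_pixels()], or a
#'   numeric vector for 1-D features.
#' @param K Number of components (>= 1).
#' @param seed Integer seed.
#' @param max_iter Maximum EM iterations.
#' @param tol Absolute log-likelihood gain below which EM stops.
#' @param var_floor Lower bound on every component variance.
#' @return An object of class `mixture_model` with fields `K`, `weights`,
#'   `means`, `vars` (K x d), `loglik_trace`, `iterations`, `feature_space`,
#'   `seed`, `degenerate`.
#' @export
fit_mixture <- function(samples, K = 3, seed = 1, max_iter = 300, tol = 1e-6,
                        var_floor = 1e-6) {
  if (is.vector(samples)) samples <- matrix(as.numeric(samples), ncol = 1)
  n <- nrow(samples); d <- ncol(samples)
  if (K < 1) abort_validation("`K` must be >= 1")
  if (n < 10 * K) abort_validation("need at least 10 * K samples")
  feature_space <- if (d == 1) "gray" else "rgb"

  degenerate <- all(apply(samples, 2, var) < .Machine$double.eps)
  if (degenerate && K > 1) {
    means <- matrix(rep(samples[1, ], each = K), K, d)
    model <- structure(list(K = K, weights = c(1 - (K - 1) * 1e-12, rep(1e-12, K - 1)),
                            means = means, vars = matrix(var_floor, K, d),
                            loglik_trace = numeric(0), iterations = 0L,
                            feature_space = feature_space, seed = seed,
                            degenerate = TRUE),
                      class = "mixture_model")
    warning("degenerate sample set: all feature vectors identical")
    return(model)
  }

  with_local_seed(seed, {
    means <- kmeanspp_centers(samples, K)
    # initial hard assignment to seeds -> weights and variances
    d2 <- sapply(seq_len(K), function(k)
      rowSums((samples - matrix(means[k, ], n, d, byrow = TRUE))^2))
    if (K == 1) d2 <- matrix(d2, ncol = 1)
    assign <- max.col(-d2, ties.method = "first")
    weights <- pmax(tabulate(assign, K), 1) / n
    weights <- weights / sum(weights)
    vars <- matrix(var_floor, K, d)
    for (k in seq_len(K)) {
      xk <- samples[assign == k, , drop = FALSE]
      if (nrow(xk) > 1)
        vars[k, ] <- pmax(apply(xk, 2, function(v) mean((v - mean(v))^2)), var_floor)
      else vars[k, ] <- pmax(apply(samples, 2, var) / K^2, var_floor)
    }

    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      lj <- mixture_logdens(samples, weights, means, vars)
      lse <- logsumexp_rows(lj)
      ll <- sum(lse)
      resp <- exp(lj - lse)
      trace <- c(trace, ll)
      if (it > 1 && (ll - trace[it - 1]) < tol) break
      nk <- colSums(resp)
      for (k in seq_len(K)) {
        if (nk[k] < .Machine$double.eps * n) { # vanished component: keep mean, floor
          vars[k, ] <- var_floor
          next
        }
        means[k, ] <- colSums(resp[, k] * samples) / nk[k]
        dev <- sweep(samples, 2, means[k, ], "-")^2
        vars[k, ] <- pmax(colSums(resp[, k] * dev) / nk[k], var_floor)
      }
      weights <- pmax(nk, .Machine$double.xmin) / sum(pmax(nk, .Machine$double.xmin))
    }
    structure(list(K = K, weights = weights, means = means, vars = vars,
                   loglik_trace = trace, iterations = length(trace),
                   feature_space = feature_space, seed = seed, degenerate = FALSE),
              class = "mixture_model")
  })
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("mixture_model: K = %d (%s), %d EM iteration(s)%s\n",
              x$K, x$feature_space, x$iterations,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  ord <- order(x$means[, 1])
  for (k in ord)
    cat(sprintf("  w = %.3f, mean = %s, var = %s\n", x$weights[k],
                paste(sprintf("%.4f", x$means[k, ]), collapse = ", "),
                paste(sprintf("%.2e", x$vars[k, ]), collapse = ", ")))
  invisible(x)
}

#' Per-pixel posterior probabilities under a mixture model
#'
#' Evaluates `p(k | x) = w_k N(x; mu_k, sigma2_k) / sum_j w_j N(x; mu_j,
#' sigma2_j)` for every pixel. Rows sum to 1 (within 1e-9).
#'
#' @param image A [raster_image()] whose channel count matches the model's
#'   feature space.
#' @param model A `mixture_model`.
#' @return An n_pixels x K matrix of posteriors with attributes `shape`
#'   (image height/width) and `dpi`.
#' @export
posterior_map <- function(image, model) {
  d_img <- n_channels(image)
  d_mod <- ncol(model$means)
  if (d_img != d_mod)
    abort_validation(sprintf("model feature space (%d-D) does not match image channels (%d)",
                             d_mod, d_img))
  x <- pixel_features(image)
  lj <- mixture_logdens(x, model$weights, model$means, model$vars)
  post <- exp(lj - logsumexp_rows(lj))
  attr(post, "shape") <- image_shape(image)
  attr(post, "dpi") <- image$dpi
  post
}

#' Indices of the darkest mixture components
#'
#' Ranks components by (luminance-weighted) mean intensity and returns the `n`
#' darkest, the default choice for roots on a bright tray.
#'
#' @param model A `mixture_model`.
#' @param n How many components to return.
#' @return Integer vector of component indices.
#' @export
darkest_components <- function(model, n = 1) {
  lum <- if (ncol(model$means) == 3)
    as.numeric(model$means %*% c(0.299, 0.587, 0.114)) else model$means[, 1]
  order(lum)[seq_len(n)]
}

#' Classify root pixels from posterior probabilities
#'
#' A pixel is root iff the summed posterior over `root_components` is at least
#' `min_posterior`; ties at exactly `min_posterior` are included.
#'
#' @param posteriors Matrix from [posterior_map()].
#' @param root_components Integer vector of component indices treated as root.
#' @param min_posterior Threshold in \[0, 1) (0.5 = maximum a posteriori).
#' @return A [binary_mask()].
#' @export
classify_root_pixels <- function(posteriors, root_components, min_posterior = 0.5) {
  K <- ncol(posteriors)
  if (length(root_components) == 0) abort_validation("`root_components` must be nonempty")
  if (any(root_components < 1 | root_components > K))
    abort_validation(sprintf("unknown component index (K = %d)", K))
  sh <- attr(posteriors, "shape")
  p_root <- rowSums(posteriors[, root_components, drop = FALSE])
  binary_mask(matrix(p_root >= min_posterior, sh[1], sh[2]), attr(posteriors, "dpi"))
}

#' Remove specks and fill small holes
#'
#' Deletes 8-connected foreground components smaller than `min_speck_px` and
#' fills enclosed background holes (4-connected, not touching the image
#' border) smaller than `fill_hole_px`. Rot-degraded root interiors appear as
#' holes in otherwise sound root outlines, hence the filling step.
#'
#' @param mask A [binary_mask()].
#' @param min_speck_px Minimum component area kept, px.
#' @param fill_hole_px Holes strictly smaller than this are filled, px.
#' @return A cleaned [binary_mask()].
#' @export
clean_mask <- function(mask, min_speck_px = 25, fill_hole_px = 100) {
  if (min_speck_px < 0 || fill_hole_px < 0) abort_validation("parameters must be >= 0")
  px <- mask$pixels
  if (any(px) && min_speck_px > 0) {
    lab <- cpp_label(px, 8L)
    areas <- tabulate(lab[lab > 0])
    px[lab > 0 & areas[pmax(lab, 1)] < min_speck_px] <- FALSE
  }
  if (fill_hole_px > 0 && any(px) && any(!px)) {
    bg <- cpp_label(!px, 4L)
    border_labs <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    areas <- tabulate(bg[bg > 0])
    fill <- bg > 0 & !(bg %in% border_labs) & areas[pmax(bg, 1)] < fill_hole_px
    px[fill] <- TRUE
  }
  binary_mask(px, mask$dpi)
}

# second-moment-ellipse elongation and convex-hull solidity per labelled
# component; coordinates in px
component_stats_table <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0)
    return(data.frame(label = integer(0), area_px = integer(0),
                      elongation = numeric(0), solidity = numeric(0)))
  labs <- lab[idx]
  h <- nrow(lab)
  rows <- (idx - 1L) %% h
  cols <- (idx - 1L) %/% h
  split_idx <- split(seq_along(labs), labs)
  out <- lapply(names(split_idx), function(lb) {
    ii <- split_idx[[lb]]
    r <- rows[ii]; c <- cols[ii]
    n <- length(ii)
    # pixel-extent correction 1/12 keeps single-pixel rows/columns finite
    vrr <- mean((r - mean(r))^2) + 1 / 12
    vcc <- mean((c - mean(c))^2) + 1 / 12
    vrc <- mean((r - mean(r)) * (c - mean(c)))
    tr <- vrr + vcc
    det_ <- vrr * vcc - vrc^2
    disc <- sqrt(max(0, (tr / 2)^2 - det_))
    l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-12)
    elong <- sqrt(l1 / l2)
    sol <- 1
    if (n >= 3) {
      pts <- cbind(c, r)
      hull <- chull(pts)
      hp <- pts[hull, , drop = FALSE]
      m <- nrow(hp)
      if (m >= 3) {
        x <- hp[, 1]; y <- hp[, 2]
        area_hull <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
        per_hull <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
        # pixel-area hull estimate (Pick-style boundary correction)
        area_hull <- area_hull + per_hull / 2 + 1
        sol <- min(1, n / max(n, area_hull))
      }
    }
    data.frame(label = as.integer(lb), area_px = n, elongation = elong, solidity = sol)
  })
  do.call(rbind, out)
}

#' Remove compact dirt components by shape
#'
#' A component is kept iff its second-moment elongation (major/minor axis
#' ratio) is at least `min_elongation` OR its area exceeds `max_area_px`
#' (large root mats are kept regardless of shape). Removed components are
#' returned with their stats for audit. The output mask is a subset of the
#' input.
#'
#' @param mask A [binary_mask()].
#' @param min_elongation Minimum elongation for a component to count as root
#'   (>= 1).
#' @param max_area_px Components larger than this are always kept, px.
#' @return A list with `mask` (cleaned [binary_mask()]), `removed`
#'   (data.frame of removed-component stats) and `kept` (stats of retained
#'   components).
#' @export
remove_dirt <- function(mask, min_elongation = 3, max_area_px = 50000) {
  if (min_elongation < 1) abort_validation("`min_elongation` must be >= 1")
  px <- mask$pixels
  empty <- data.frame(label = integer(0), area_px = integer(0),
                      elongation = numeric(0), solidity = numeric(0))
  if (!any(px))
    return(list(mask = mask, removed = empty, kept = empty))
  lab <- cpp_label(px, 8L)
  stats <- component_stats_table(lab)
  keep <- stats$elongation >= min_elongation | stats$area_px > max_area_px
  drop_labels <- stats$label[!keep]
  if (length(drop_labels)) px[lab %in% drop_labels] <- FALSE
  list(mask = binary_mask(px, mask$dpi),
       removed = stats[!keep, , drop = FALSE],
       kept = stats[keep, , drop = FALSE])
}
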