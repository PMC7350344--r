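# Synthetic root-tray generator with exact ground truth.
#
# Emulated scene: a bright DIN-A4-proportioned sheet (the "frame") on a darker
# stage, dark constant-width root strokes separated on the sheet (fibrous and
# storage width classes), compact dirt blobs of intermediate intensity, and
# ~5 exposures with independent Gaussian sensor noise plus impulse specks.
# Every stroke's centerline arc length and width are recorded before noise,
# so each pipeline stage and the end-to-end traits can be validated exactly.

#' Scene parameters for the synthetic tray generator
#'
#' Defaults emulate the imaging protocol: a DIN A4 sheet at 450 DPI with
#' fibrous widths uniform in 0.3-0.8 mm, storage widths uniform in 1.5-4 mm,
#' stroke lengths 2-20 cm, and 5 exposures. `scale` shrinks the sheet
#' linearly (0.5 = A6, i.e. a quarter of an A4 sheet) for faster runs.
#' Stroke widths are snapped to the diameter-histogram bin-midpoint grid so
#' that closed-form truth traits and histogram-based traits coincide exactly.
#'
#' @param scale Linear tray scale (1 = A4, 21.0 x 29.7 cm).
#' @param dpi Rendering resolution, dots per inch.
#' @param n_fibrous,n_storage Stroke counts per class.
#' @param fibrous_width_mm,storage_width_mm Width ranges (truncation limits),
#'   mm.
#' @param fibrous_width_mode,fibrous_width_sd,storage_width_mode,storage_width_sd
#'   Widths are drawn from normals centred on the class mode and truncated to
#'   the class range, giving the bimodal width distribution (modes ~0.45 and
#'   2.5 mm) that the fibrous/storage dichotomy implies.
#' @param length_cm Stroke length range (uniform), cm; lengths a stroke of a
#'   given width cannot physically reach inside the tray (bend radius below
#'   half its width) are capped at the feasible maximum.
#' @param n_dirt Number of dirt blobs.
#' @param dirt_radius_mm Dirt radius range (uniform), mm.
#' @param n_exposures Number of exposures in the stack.
#' @param noise_sd Per-exposure Gaussian noise standard deviation.
#' @param speck_frac Per-exposure impulse-speck fraction of pixels.
#' @param stage_intensity,sheet_intensity,root_intensity,dirt_intensity Scene
#'   intensities in \[0, 1\].
#' @param margin_frac Width of the dark stage margin around the sheet as a
#'   fraction of the smaller image dimension.
#' @param tilt_deg Sheet rotation in degrees (for frame-detection tests).
#' @param bin_width_mm,max_diameter_mm Diameter-class grid used for the truth
#'   histogram (match the measurement defaults).
#' @param max_tries Rejection limit for non-overlapping placement.
#' @return A named list of parameters.
#' @export
tray_params <- function(scale = 1, dpi = 450,
                        n_fibrous = 10, n_storage = 3,
                        fibrous_width_mm = c(0.3, 0.8),
                        storage_width_mm = c(1.5, 4),
                        fibrous_width_mode = 0.45, fibrous_width_sd = 0.10,
                        storage_width_mode = 2.5, storage_width_sd = 0.45,
                        length_cm = c(2, 20),
                        n_dirt = 6, dirt_radius_mm = c(0.5, 2),
                        n_exposures = 5, noise_sd = 0.02, speck_frac = 2e-5,
                        stage_intensity = 0.35, sheet_intensity = 0.9,
                        root_intensity = 0.15, dirt_intensity = 0.55,
                        margin_frac = 0.05, tilt_deg = 0,
                        bin_width_mm = 0.1, max_diameter_mm = 10,
                        max_tries = 400) {
  list(scale = scale, dpi = dpi, n_fibrous = n_fibrous, n_storage = n_storage,
       fibrous_width_mm = fibrous_width_mm, storage_width_mm = storage_width_mm,
       fibrous_width_mode = fibrous_width_mode, fibrous_width_sd = fibrous_width_sd,
       storage_width_mode = storage_width_mode, storage_width_sd = storage_width_sd,
       length_cm = length_cm, n_dirt = n_dirt, dirt_radius_mm = dirt_radius_mm,
       n_exposures = n_exposures, noise_sd = noise_sd, speck_frac = speck_frac,
       stage_intensity = stage_intensity, sheet_intensity = sheet_intensity,
       root_intensity = root_intensity, dirt_intensity = dirt_intensity,
       margin_frac = margin_frac, tilt_deg = tilt_deg,
       bin_width_mm = bin_width_mm, max_diameter_mm = max_diameter_mm,
       max_tries = max_tries)
}

# arc-length ratio of y = A sin(k x) with slope amplitude m = A k, relative
# to the chord: mean over a period of sqrt(1 + m^2 cos^2 u)
serpentine_ratio <- function(m) {
  u <- seq(0, pi / 2, length.out = 201)
  mean(sqrt(1 + m^2 * cos(u)^2))
}

# solve serpentine_ratio(m) = r; small-ratio expansion ratio ~ 1 + m^2/4
serpentine_slope <- function(r) {
  if (r <= 1 + 1e-9) return(0)
  if (r < 1.0005) return(2 * sqrt(r - 1))
  if (r >= serpentine_ratio(60)) return(60)
  uniroot(function(m) serpentine_ratio(m) - r, c(1e-3, 60))$root
}

# snap a width to the diameter-class midpoint grid
snap_width <- function(width_mm, bin_width_mm) {
  (floor(width_mm / bin_width_mm) + 0.5) * bin_width_mm
}

# build one serpentine centerline polyline (px coordinates, 0-based), given
# the usable rectangle [r0,r1] x [c0,c1]; returns NULL if it cannot be placed
make_stroke_path <- function(L_cm, w_px, px_per_cm, usable, max_tries) {
  w_cm <- w_px / px_per_cm
  R0_cm <- w_cm / 2 + 0.1 # minimum bend radius: half width + 1 mm clearance
  for (try in seq_len(max_tries)) {
    phi <- runif(1, 0, pi)
    span_r <- usable[2] - usable[1]
    span_c <- usable[4] - usable[3]
    # available extent along the baseline and perpendicular to it
    avail_par <- abs(cos(phi)) * span_c + abs(sin(phi)) * span_r
    chord_px <- min(L_cm * px_per_cm, 0.85 * avail_par)
    chord_cm <- chord_px / px_per_cm
    r_need <- L_cm / chord_cm
    # perpendicular room: conservative bound from the smaller span
    H_avail_cm <- 0.8 * min(span_r, span_c) / px_per_cm
    A_max_cm <- max((H_avail_cm - w_cm) / 2, 0.01)
    m_max <- sqrt(A_max_cm / R0_cm)
    r_max <- serpentine_ratio(m_max)
    L_use <- if (r_need > r_max) 0.98 * r_max * chord_cm else L_cm
    r_use <- L_use / chord_cm
    m <- serpentine_slope(r_use)
    if (m > 0) {
      lam_min_cm <- 2 * pi * m * R0_cm
      lam_max_cm <- 2 * pi * A_max_cm / m
      if (lam_min_cm > lam_max_cm) next
      lam_cm <- sqrt(lam_min_cm * lam_max_cm)
      A_px <- m * lam_cm / (2 * pi) * px_per_cm
      k <- 2 * pi / (lam_cm * px_per_cm)
    } else {
      A_px <- 0; k <- 1
    }
    phase <- runif(1, 0, 2 * pi)
    dx <- 0.35 / sqrt(1 + m^2)
    t <- seq(0, chord_px, by = dx)
    y <- A_px * sin(k * t + phase)
    # rotate baseline by phi
    pr <- t * sin(phi) + y * cos(phi)
    pc <- t * cos(phi) - y * sin(phi)
    half <- w_px / 2
    rmin <- min(pr) - half; rmax <- max(pr) + half
    cmin <- min(pc) - half; cmax <- max(pc) + half
    lo_r <- usable[1] - rmin; hi_r <- usable[2] - rmax
    lo_c <- usable[3] - cmin; hi_c <- usable[4] - cmax
    if (lo_r > hi_r || lo_c > hi_c) next
    off_r <- runif(1, lo_r, hi_r)
    off_c <- runif(1, lo_c, hi_c)
    return(list(pr = pr + off_r, pc = pc + off_c))
  }
  NULL
}

polyline_length_px <- function(pr, pc) {
  sum(sqrt(diff(pr)^2 + diff(pc)^2))
}

# render one flat-capped constant-width stroke over its bounding box.
# Flat caps (clipping by the end-tangent planes) make the rendered shape a
# true "cylinder": volume pi r^2 L holds exactly and the medial axis retracts
# ~w/2 at each end, which the measurement end correction compensates.
# Returns the bbox (0-based, inclusive) with alpha / truth / clearance masks.
render_stroke <- function(pr, pc, w_px, h, w, clearance_px = 3) {
  half <- w_px / 2
  rmax <- half + clearance_px + 1.5
  r0 <- max(0L, as.integer(floor(min(pr) - rmax)))
  r1 <- min(h - 1L, as.integer(ceiling(max(pr) + rmax)))
  c0 <- max(0L, as.integer(floor(min(pc) - rmax)))
  c1 <- min(w - 1L, as.integer(ceiling(max(pc) + rmax)))
  nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
  dist <- cpp_dist_to_points(nr, nc, pr - r0, pc - c0, rmax)
  n <- length(pr)
  k <- min(n, max(2L, as.integer(ceiling(2 / max(1e-9, polyline_length_px(pr, pc) / (n - 1))))))
  u0 <- c(pr[k] - pr[1], pc[k] - pc[1]); u0 <- u0 / sqrt(sum(u0^2))
  u1 <- c(pr[n - k + 1] - pr[n], pc[n - k + 1] - pc[n]); u1 <- u1 / sqrt(sum(u1^2))
  ii <- matrix(rep(r0:r1, times = nc), nr) ; jj <- matrix(rep(c0:c1, each = nr), nr)
  s0 <- (ii - pr[1]) * u0[1] + (jj - pc[1]) * u0[2]
  s1 <- (ii - pr[n]) * u1[1] + (jj - pc[n]) * u1[2]
  alpha <- pmin(1, pmax(0, (half + 0.5) - dist)) *
    pmin(1, pmax(0, s0 + 0.5)) * pmin(1, pmax(0, s1 + 0.5))
  list(r0 = r0, r1 = r1, c0 = c0, c1 = c1,
       alpha = alpha,
       truth = dist <= half & s0 >= 0 & s1 >= 0,
       core = dist <= half + clearance_px & s0 >= -clearance_px & s1 >= -clearance_px)
}

#' Generate one synthetic root tray with ground truth
#'
#' Renders, per exposure, the bright sheet on its darker stage margin, dark
#' anti-aliased constant-width root strokes (pairwise non-overlapping),
#' compact dirt blobs with mildly irregular boundaries, independent Gaussian
#' pixel noise, and a small number of per-exposure impulse specks (so the
#' median projection has work to do). Deterministic given `seed`; ground
#' truth is recorded before noise.
#'
#' @param params Scene parameters from [tray_params()].
#' @param seed Integer seed.
#' @param tray_id,plant_id Identifiers.
#' @return A list with `stack` (a [tray_stack()]) and `truth`, an object of
#'   class `tray_truth` holding: `strokes` (data.frame of class, width_mm,
#'   length_cm), `histogram` (truth [dl_histogram()]), `root_mask` (exact
#'   truth raster: pixel centers within width/2 of a centerline),
#'   `clean_image` (the noise-free rendered scene),
#'   `sheet_interior` (0-based half-open rows/cols of the sheet), `frame_mask`
#'   (pixels belonging to the stage margin / sheet border), `dirt` (centers
#'   and radii), `specks` (per-exposure impulse coordinates), `seed`, `dpi`,
#'   `params`.
#' @export
generate_tray <- function(params = tray_params(), seed = 1,
                          tray_id = "tray1", plant_id = "plant1") {
  p <- params
  ppcm <- p$dpi / 2.54
  h <- as.integer(round(29.7 * p$scale * ppcm))
  w <- as.integer(round(21.0 * p$scale * ppcm))
  margin <- as.integer(round(p$margin_frac * min(h, w)))
  tilt <- p$tilt_deg * pi / 180

  with_local_seed(seed, {
    # sheet mask (bright frame); everything outside it is "frame"/margin
    if (abs(tilt) < 1e-12) {
      sheet <- matrix(FALSE, h, w)
      sheet[(margin + 1):(h - margin), (margin + 1):(w - margin)] <- TRUE
    } else {
      cy <- (h - 1) / 2; cx <- (w - 1) / 2
      jj <- matrix(rep(0:(w - 1), each = h), h, w) - cx
      ii <- matrix(rep(0:(h - 1), times = w), h, w) - cy
      u <- jj * cos(tilt) + ii * sin(tilt)
      v <- -jj * sin(tilt) + ii * cos(tilt)
      sheet <- abs(u) <= (w / 2 - margin) & abs(v) <= (h / 2 - margin)
    }
    base <- matrix(p$stage_intensity, h, w)
    base[sheet] <- p$sheet_intensity

    # usable stroke region: inside the sheet with clearance for tilt + widths
    tilt_inset <- ceiling(abs(tan(tilt)) * max(h, w) / 2)
    inset <- margin + tilt_inset + 6L
    usable <- c(inset, h - 1 - inset, inset, w - 1 - inset) # r0 r1 c0 c1
    if (usable[2] - usable[1] < 20 || usable[4] - usable[3] < 20)
      abort_validation("tray too small for the requested margin/tilt")

    truth_mask <- matrix(FALSE, h, w)
    occupancy <- matrix(FALSE, h, w)
    strokes <- list()
    classes <- c(rep("fibrous", p$n_fibrous), rep("storage", p$n_storage))
    for (s in seq_along(classes)) {
      cls <- classes[s]
      if (cls == "fibrous") {
        rng <- p$fibrous_width_mm
        wmu <- p$fibrous_width_mode; wsd <- p$fibrous_width_sd
      } else {
        rng <- p$storage_width_mm
        wmu <- p$storage_width_mode; wsd <- p$storage_width_sd
      }
      width_mm <- snap_width(min(rng[2], max(rng[1], rnorm(1, wmu, wsd))),
                             p$bin_width_mm)
      w_px <- width_mm / 10 * ppcm
      L_cm <- runif(1, p$length_cm[1], p$length_cm[2])
      placed <- FALSE
      for (try in seq_len(p$max_tries)) {
        # crowded trays: progressively shorten the stroke toward what fits
        if (try %% 20 == 0) L_cm <- max(p$length_cm[1], 0.85 * L_cm)
        path <- make_stroke_path(L_cm, w_px, ppcm, usable, max_tries = 20)
        if (is.null(path)) next
        # cheap overlap pre-check on the centerline before the full render
        sub <- seq(1, length(path$pr), by = 4)
        if (any(occupancy[cbind(round(path$pr[sub]) + 1, round(path$pc[sub]) + 1)]))
          next
        rs <- render_stroke(path$pr, path$pc, w_px, h, w)
        rows <- (rs$r0 + 1):(rs$r1 + 1); cols <- (rs$c0 + 1):(rs$c1 + 1)
        if (any(rs$core & occupancy[rows, cols])) next
        base[rows, cols] <- rs$alpha * p$root_intensity + (1 - rs$alpha) * base[rows, cols]
        truth_mask[rows, cols] <- truth_mask[rows, cols] | rs$truth
        occupancy[rows, cols] <- occupancy[rows, cols] | rs$core
        strokes[[length(strokes) + 1]] <- data.frame(
          class = cls, width_mm = width_mm,
          length_cm = polyline_length_px(path$pr, path$pc) / ppcm)
        placed <- TRUE
        break
      }
      if (!placed)
        abort_rm(sprintf(
          "could not place stroke %d after %d tries; use fewer or shorter strokes",
          s, p$max_tries), "rootmorph_placement_error")
    }
    strokes <- if (length(strokes)) do.call(rbind, strokes)
               else data.frame(class = character(0), width_mm = numeric(0),
                               length_cm = numeric(0))

    # dirt blobs: discs with mild radial boundary modulation, intensity
    # between root and sheet, placed clear of the strokes
    dirt <- data.frame(row = numeric(0), col = numeric(0), radius_px = numeric(0))
    if (p$n_dirt > 0) {
      for (b in seq_len(p$n_dirt)) {
        for (try in seq_len(p$max_tries)) {
          r_px <- runif(1, p$dirt_radius_mm[1], p$dirt_radius_mm[2]) / 10 * ppcm
          cr <- runif(1, usable[1] + r_px, usable[2] - r_px)
          cc <- runif(1, usable[3] + r_px, usable[4] - r_px)
          ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
          rmax <- 1.25 * r_px + 4
          r0 <- max(0L, as.integer(floor(cr - rmax)))
          r1 <- min(h - 1L, as.integer(ceiling(cr + rmax)))
          c0 <- max(0L, as.integer(floor(cc - rmax)))
          c1 <- min(w - 1L, as.integer(ceiling(cc + rmax)))
          ii <- matrix(rep(r0:r1, times = c1 - c0 + 1), r1 - r0 + 1) - cr
          jj <- matrix(rep(c0:c1, each = r1 - r0 + 1), r1 - r0 + 1) - cc
          dd <- sqrt(ii^2 + jj^2)
          ang <- atan2(ii, jj)
          r_eff <- r_px * (1 + 0.12 * sin(3 * ang + ph1) + 0.06 * sin(5 * ang + ph2))
          rows <- (r0 + 1):(r1 + 1); cols <- (c0 + 1):(c1 + 1)
          near <- dd <= r_eff + 3
          if (any(near & occupancy[rows, cols])) next
          alpha <- pmin(1, pmax(0, r_eff + 0.5 - dd))
          base[rows, cols] <- alpha * p$dirt_intensity + (1 - alpha) * base[rows, cols]
          occupancy[rows, cols] <- occupancy[rows, cols] | near
          dirt <- rbind(dirt, data.frame(row = cr, col = cc, radius_px = r_px))
          break
        }
      }
    }

    # exposures: base + independent Gaussian noise + impulse specks
    n_speck <- as.integer(round(p$speck_frac * h * w))
    images <- vector("list", p$n_exposures)
    specks <- vector("list", p$n_exposures)
    for (e in seq_len(p$n_exposures)) {
      img <- base + matrix(rnorm(h * w, 0, p$noise_sd), h, w)
      if (n_speck > 0) {
        idx <- sample.int(h * w, n_speck)
        img[idx] <- ifelse(runif(n_speck) < 0.5, 0.02, 0.98)
        specks[[e]] <- idx
      } else specks[[e]] <- integer(0)
      img[img < 0] <- 0; img[img > 1] <- 1
      images[[e]] <- raster_image(img, dpi = p$dpi)
    }

    # truth histogram on the measurement grid (widths sit on bin midpoints)
    nb <- as.integer(ceiling(p$max_diameter_mm / p$bin_width_mm))
    edges <- seq(0, by = p$bin_width_mm, length.out = nb + 1)
    lens <- numeric(nb)
    if (nrow(strokes)) {
      bin <- pmin(pmax(floor(strokes$width_mm / p$bin_width_mm) + 1, 1), nb)
      acc <- rowsum(strokes$length_cm, bin)
      lens[as.integer(rownames(acc))] <- acc[, 1]
    }
    hist <- dl_histogram(edges, lens, plant_id = plant_id)

    truth <- structure(list(
      strokes = strokes, histogram = hist, root_mask = truth_mask,
      clean_image = base,
      sheet_interior = c(row_min = margin, row_max = h - margin,
                         col_min = margin, col_max = w - margin),
      frame_mask = !sheet, dirt = dirt, specks = specks,
      seed = seed, dpi = p$dpi, params = p), class = "tray_truth")
    list(stack = tray_stack(images, tray_id = tray_id, plant_id = plant_id),
         truth = truth)
  })
}

#' @export
print.tray_truth <- function(x, ...) {
  cat(sprintf("tray_truth: %d stroke(s) (%.1f cm total), %d dirt blob(s), seed %d\n",
              nrow(x$strokes), sum(x$strokes$length_cm), nrow(x$dirt), x$seed))
  invisible(x)
}

#' Exact traits from stroke ground truth
#'
#' Closed-form cylinder traits from the stroke list: per class,
#' `L = sum length_cm`, `V = sum pi (width/20)^2 length`, `A = sum pi
#' (width/10) length`. Classes are assigned by width against `threshold_mm`
#' with the same tie rule as [cylinder_traits()] (fibrous strictly below).
#'
#' @param truth A `tray_truth` (or a list of them, cumulated).
#' @param threshold_mm Diameter threshold, mm.
#' @param plant_id Identifier for the output.
#' @return A `root_traits` object.
#' @export
truth_traits <- function(truth, threshold_mm, plant_id = "plant") {
  strokes <- if (inherits(truth, "tray_truth")) truth$strokes
             else do.call(rbind, lapply(truth, `[[`, "strokes"))
  fib <- strokes$width_mm < threshold_mm
  sums <- function(sel) {
    ww <- strokes$width_mm[sel]; ll <- strokes$length_cm[sel]
    list(length_cm = sum(ll),
         volume_cm3 = sum(pi * (ww / 20)^2 * ll),
         area_cm2 = sum(pi * (ww / 10) * ll),
         mean_radius_mm = if (sum(ll) > 0) sum((ww / 2) * ll) / sum(ll) else 0)
  }
  f <- sums(fib); s <- sums(!fib)
  flags <- character(0)
  if (f$length_cm == 0) flags <- c(flags, "empty fibrous class")
  if (s$length_cm == 0) flags <- c(flags, "empty storage class")
  structure(list(plant_id = plant_id, fibrous = f, storage = s,
                 combined = list(length_cm = f$length_cm + s$length_cm,
                                 volume_cm3 = f$volume_cm3 + s$volume_cm3,
                                 area_cm2 = f$area_cm2 + s$area_cm2),
                 otsu_threshold_mm = threshold_mm, flags = flags),
            class = "root_traits")
}

#' Cumulate truth histograms over trays
#'
#' @param truths List of `tray_truth` objects of one plant.
#' @param plant_id Identifier.
#' @return A [dl_histogram()].
#' @export
truth_histogram <- function(truths, plant_id = "plant") {
  cumulate(lapply(truths, `[[`, "histogram"), plant_id = plant_id)
}

#' Write a generated tray to disk
#'
#' The stack goes to one multi-page TIFF, the ground truth to JSON (strokes,
#' dirt, sheet geometry, seed, dpi; the full truth raster is not serialised).
#'
#' @param tray A list from [generate_tray()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_tray <- function(tray, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(tray$stack$tray_id, ".tif"))
  tiff::writeTIFF(lapply(tray$stack$images, `[[`, "pixels"), tif,
                  bits.per.sample = 16L)
  js <- file.path(dir, paste0(tray$stack$tray_id, "_truth.json"))
  tr <- tray$truth
  jsonlite::write_json(list(
    tray_id = tray$stack$tray_id, plant_id = tray$stack$plant_id,
    seed = tr$seed, dpi = tr$dpi, strokes = tr$strokes, dirt = tr$dirt,
    sheet_interior = as.list(tr$sheet_interior)), js,
    auto_unbox = TRUE, digits = NA)
  invisible(c(tif, js))
}
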