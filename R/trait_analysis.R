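# Per-plant trait extraction: cumulate diameter-length histograms over trays,
# split fibrous vs storage roots with Otsu's method on the length-weighted
# diameter distribution, and compute length, volume, surface area and mean
# radius under a cylinder geometry.

#' Cumulate diameter-length histograms
#'
#' Bin-wise sum over trays of one plant. Inputs must share bin edges exactly
#' (no silent rebinning). Total mass is the exact sum of input masses.
#'
#' @param histograms List of [dl_histogram()] with identical bin edges.
#' @param plant_id Identifier of the cumulated histogram (default: first
#'   input's).
#' @return A [dl_histogram()].
#' @export
cumulate <- function(histograms, plant_id = NULL) {
  if (!is.list(histograms) || length(histograms) < 1)
    abort_validation("`histograms` must be a nonempty list")
  ref <- histograms[[1]]
  for (i in seq_along(histograms)) {
    hi <- histograms[[i]]
    if (!inherits(hi, "dl_histogram"))
      abort_validation(sprintf("histograms[[%d]] is not a dl_histogram", i))
    if (!identical(hi$bin_edges, ref$bin_edges))
      abort_validation(sprintf("histograms[[%d]] has mismatched bin edges", i))
  }
  total <- Reduce(`+`, lapply(histograms, `[[`, "length_cm"))
  dl_histogram(ref$bin_edges, total,
               plant_id = if (is.null(plant_id)) ref$plant_id else plant_id,
               tray_count = sum(vapply(histograms, `[[`, 1L, "tray_count")))
}

#' Otsu split of a diameter-length histogram
#'
#' Treats the per-bin root length as the weight distribution over bin-midpoint
#' diameters and returns the bin edge `t` maximising the between-class
#' variance `sigma_B^2(t) = w0 w1 (mu0 - mu1)^2`, where `w0, w1` are the two
#' classes' length fractions and `mu0, mu1` their length-weighted mean
#' diameters. All interior bin edges are scanned; ties break toward the
#' smallest threshold.
#'
#' @param hist A [dl_histogram()] with at least two occupied bins.
#' @return An object of class `class_threshold` with fields `diameter_mm`,
#'   `between_class_variance`, `method = "otsu"`.
#' @export
otsu_split <- function(hist) {
  w <- hist$length_cm
  mids <- bin_midpoints(hist)
  if (sum(w > 0) < 2)
    abort_rm(paste("degenerate histogram: fewer than two occupied diameter",
                   "classes; classify all mass as fibrous"),
             "rootmorph_degenerate_error")
  tot <- sum(w)
  p <- w / tot
  nb <- length(w)
  # cut after bin i: class 0 = bins 1..i, class 1 = bins (i+1)..nb
  cw0 <- cumsum(p)[-nb]
  cm0 <- cumsum(p * mids)[-nb]
  mu_all <- sum(p * mids)
  w0 <- cw0; w1 <- 1 - cw0
  valid <- w0 > 0 & w1 > 0
  mu0 <- ifelse(valid, cm0 / w0, 0)
  mu1 <- ifelse(valid, (mu_all - cm0) / w1, 0)
  sigma_b2 <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  best <- which.max(sigma_b2) # which.max takes the first (smallest t) on ties
  structure(list(diameter_mm = hist$bin_edges[best + 1],
                 between_class_variance = sigma_b2[best],
                 method = "otsu"),
            class = "class_threshold")
}

#' @export
print.class_threshold <- function(x, ...) {
  cat(sprintf("class_threshold (otsu): %.2f mm (sigma_B^2 = %.4g)\n",
              x$diameter_mm, x$between_class_variance))
  invisible(x)
}

cylinder_sums <- function(mids_mm, len_cm) {
  list(length_cm = sum(len_cm),
       volume_cm3 = sum(pi * (mids_mm / 20)^2 * len_cm),
       area_cm2 = sum(pi * (mids_mm / 10) * len_cm),
       mean_radius_mm = if (sum(len_cm) > 0) sum((mids_mm / 2) * len_cm) / sum(len_cm) else 0)
}

#' Cylinder-geometry root traits
#'
#' Treats each diameter class as a cylinder of diameter `d_i` (bin midpoint,
#' mm) and length `l_i` (cm): per class, `L = sum l_i`,
#' `V = sum pi (d_i/20)^2 l_i` (cm^3), `A = sum pi (d_i/10) l_i` (cm^2), and
#' the length-weighted `mean_radius = sum (d_i/2) l_i / sum l_i` (mm).
#' Fibrous = strictly below the threshold; storage = at or above. An empty
#' class yields zeros and an `"empty class"` flag.
#'
#' @param hist A [dl_histogram()].
#' @param threshold A `class_threshold` from [otsu_split()], or a diameter in
#'   mm; `NULL` (with `flags = "degenerate"`) classifies all mass as fibrous.
#' @param flags Character vector of upstream flags to carry along.
#' @return An object of class `root_traits`: per-class and combined length,
#'   volume, surface area and mean radius, plus `otsu_threshold_mm` and
#'   `flags`.
#' @export
cylinder_traits <- function(hist, threshold, flags = character(0)) {
  thr <- if (inherits(threshold, "class_threshold")) threshold$diameter_mm
         else if (is.null(threshold)) Inf else as.numeric(threshold)
  mids <- bin_midpoints(hist)
  len <- hist$length_cm
  fib <- mids < thr
  f <- cylinder_sums(mids[fib], len[fib])
  s <- cylinder_sums(mids[!fib], len[!fib])
  if (f$length_cm == 0) flags <- c(flags, "empty fibrous class")
  if (s$length_cm == 0) flags <- c(flags, "empty storage class")
  structure(list(
    plant_id = hist$plant_id,
    fibrous = f, storage = s,
    combined = list(length_cm = f$length_cm + s$length_cm,
                    volume_cm3 = f$volume_cm3 + s$volume_cm3,
                    area_cm2 = f$area_cm2 + s$area_cm2),
    otsu_threshold_mm = if (is.finite(thr)) thr else NA_real_,
    flags = flags), class = "root_traits")
}

#' @export
print.root_traits <- function(x, ...) {
  cat(sprintf("root_traits '%s' (threshold %.2f mm)\n", x$plant_id,
              if (is.na(x$otsu_threshold_mm)) NA else x$otsu_threshold_mm))
  for (cl in c("fibrous", "storage")) {
    v <- x[[cl]]
    cat(sprintf("  %-7s L = %8.2f cm  V = %7.4f cm^3  A = %8.3f cm^2  r = %.3f mm\n",
                cl, v$length_cm, v$volume_cm3, v$area_cm2, v$mean_radius_mm))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' One-row data.frame view of root traits
#'
#' @param x A `root_traits` object.
#' @param ... Unused.
#' @return A one-row data.frame with the trait-table columns.
#' @export
as.data.frame.root_traits <- function(x, ...) {
  data.frame(plant_id = x$plant_id,
             fibrous_length_cm = x$fibrous$length_cm,
             storage_length_cm = x$storage$length_cm,
             fibrous_volume_cm3 = x$fibrous$volume_cm3,
             storage_volume_cm3 = x$storage$volume_cm3,
             fibrous_area_cm2 = x$fibrous$area_cm2,
             storage_area_cm2 = x$storage$area_cm2,
             fibrous_mean_radius_mm = x$fibrous$mean_radius_mm,
             storage_mean_radius_mm = x$storage$mean_radius_mm,
             total_length_cm = x$combined$length_cm,
             total_volume_cm3 = x$combined$volume_cm3,
             total_area_cm2 = x$combined$area_cm2,
             otsu_threshold_mm = x$otsu_threshold_mm,
             flags = paste(x$flags, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Pool trait tables across experiments
#'
#' Row concatenation with experiment identifiers retained; columns must match
#' exactly.
#'
#' @param tables List of data.frames with identical columns.
#' @return A single data.frame.
#' @export
pool_experiments <- function(tables) {
  if (!is.list(tables) || length(tables) < 1)
    abort_validation("`tables` must be a nonempty list of data.frames")
  ref <- names(tables[[1]])
  for (i in seq_along(tables))
    if (!identical(names(tables[[i]]), ref))
      abort_validation(sprintf("tables[[%d]] has mismatched columns", i))
  do.call(rbind, c(tables, list(make.row.names = FALSE)))
}

#' Coefficient of determination
#'
#' `r^2` of the least-squares line of `y` on `x`, with intercept.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; `x` must vary.
#' @return A list with `r_squared` and `n`.
#' @export
coefficient_of_determination <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3) abort_validation("need equal lengths n >= 3")
  if (var(x) <= 0) abort_validation("degenerate predictor: `x` is constant")
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1, n = n)
}

#' Validate estimated traits against ground truth
#'
#' Computes the coefficient of determination between estimated and true total
#' root volume across plants, plus per-plant relative errors for length and
#' volume.
#'
#' @param estimated,truth data.frames with columns `plant_id`,
#'   `total_length_cm`, `total_volume_cm3`; matched by `plant_id`.
#' @return A list (class `validation_report`) with `r_squared`, `n`, and a
#'   data.frame `per_plant` of relative errors.
#' @export
validate_traits <- function(estimated, truth) {
  m <- merge(estimated, truth, by = "plant_id", suffixes = c("_est", "_true"))
  if (nrow(m) < 3) abort_validation("need at least 3 matched plants")
  r2 <- coefficient_of_determination(m$total_volume_cm3_true, m$total_volume_cm3_est)
  per_plant <- data.frame(
    plant_id = m$plant_id,
    length_rel_error = (m$total_length_cm_est - m$total_length_cm_true) /
      ifelse(m$total_length_cm_true > 0, m$total_length_cm_true, NA_real_),
    volume_rel_error = (m$total_volume_cm3_est - m$total_volume_cm3_true) /
      ifelse(m$total_volume_cm3_true > 0, m$total_volume_cm3_true, NA_real_))
  structure(list(r_squared = r2$r_squared, n = r2$n, per_plant = per_plant),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: r^2 = %.3f (n = %d), mean |length error| = %.1f%%, mean |volume error| = %.1f%%\n",
              x$r_squared, x$n,
              100 * mean(abs(x$per_plant$length_rel_error), na.rm = TRUE),
              100 * mean(abs(x$per_plant$volume_rel_error), na.rm = TRUE)))
  invisible(x)
}
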