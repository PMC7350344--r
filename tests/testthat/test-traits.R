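test_that("cumulation is exactly additive and guards bin edges", {
  h1 <- random_histogram(1)
  expect_identical(cumulate(list(h1))$length_cm, h1$length_cm)
  zero <- dl_histogram(h1$bin_edges, numeric(length(h1$length_cm)))
  expect_identical(cumulate(list(h1, zero))$length_cm, h1$length_cm)

  edges <- seq(0, 6, by = 0.1)
  a <- dl_histogram(edges, replace(numeric(60), 7, 3.0))
  b <- dl_histogram(edges, replace(numeric(60), 7, 4.5))
  expect_equal(cumulate(list(a, b))$length_cm[7], 7.5)
  expect_equal(cumulate(list(a, b))$tray_count, 2L)

  other <- dl_histogram(seq(0, 6, by = 0.2), numeric(30))
  expect_error(cumulate(list(a, other)), class = "rootmorph_validation_error")
})

test_that("otsu_split equals the exhaustive scan on 100 random histograms", {
  for (seed in 1:100) {
    h <- random_histogram(seed)
    got <- otsu_split(h)
    want <- brute_otsu(h)
    expect_equal(got$diameter_mm, want$diameter_mm,
                 info = sprintf("seed %d", seed))
    expect_equal(got$between_class_variance, want$between_class_variance,
                 tolerance = 1e-12)
  }
})

test_that("otsu_split lands between well-separated modes and flags degenerates", {
  edges <- seq(0, 10, by = 0.1)
  lens <- numeric(100); lens[4] <- 30; lens[25] <- 10 # 0.35 and 2.45 mm
  t <- otsu_split(dl_histogram(edges, lens))
  expect_gt(t$diameter_mm, 0.35)
  expect_lt(t$diameter_mm, 2.45)
  expect_gt(t$between_class_variance, 0)

  lens1 <- numeric(100); lens1[4] <- 30
  expect_error(otsu_split(dl_histogram(edges, lens1)),
               class = "rootmorph_degenerate_error")
})

test_that("cylinder traits match closed forms and conserve totals", {
  edges <- seq(0, 2.4, by = 0.8) # midpoints 0.4, 1.2, 2.0
  one <- dl_histogram(edges, c(0, 0, 10))
  tr <- cylinder_traits(one, 1.0)
  expect_equal(tr$storage$volume_cm3, pi * 0.1^2 * 10, tolerance = 1e-12)
  expect_equal(tr$storage$area_cm2, pi * 0.2 * 10, tolerance = 1e-12)
  expect_equal(tr$storage$mean_radius_mm, 1.0, tolerance = 1e-12)
  expect_equal(tr$fibrous$length_cm, 0)
  expect_true("empty fibrous class" %in% tr$flags)

  two <- dl_histogram(edges, c(30, 0, 10))
  tr2 <- cylinder_traits(two, 1.0)
  expect_equal(tr2$fibrous$length_cm, 30)
  expect_equal(tr2$storage$length_cm, 10)
  expect_equal(tr2$fibrous$volume_cm3, pi * 0.02^2 * 30, tolerance = 1e-12)

  # conservation + ordering invariants on random inputs
  for (seed in 1:20) {
    h <- random_histogram(seed + 300)
    thr <- otsu_split(h)
    t3 <- cylinder_traits(h, thr)
    whole <- rootmorph:::cylinder_sums(bin_midpoints(h), h$length_cm)
    expect_equal(t3$combined$length_cm, whole$length_cm, tolerance = 1e-12)
    expect_equal(t3$combined$volume_cm3, whole$volume_cm3, tolerance = 1e-12)
    expect_equal(t3$combined$area_cm2, whole$area_cm2, tolerance = 1e-12)
    if (t3$fibrous$length_cm > 0 && t3$storage$length_cm > 0) {
      expect_lte(t3$fibrous$mean_radius_mm, thr$diameter_mm / 2)
      expect_gte(t3$storage$mean_radius_mm, thr$diameter_mm / 2)
    }
  }
})

test_that("adding mass never decreases combined traits", {
  h <- random_histogram(77)
  base <- cylinder_traits(h, 1.0)
  for (b in c(3, 30, 55)) {
    lens <- h$length_cm; lens[b] <- lens[b] + 5
    more <- cylinder_traits(dl_histogram(h$bin_edges, lens), 1.0)
    expect_gte(more$combined$length_cm, base$combined$length_cm)
    expect_gte(more$combined$volume_cm3, base$combined$volume_cm3)
    expect_gte(more$combined$area_cm2, base$combined$area_cm2)
  }
})

test_that("experiment pooling concatenates with identifiers intact", {
  t1 <- data.frame(plant_id = paste0("a", 1:6), total_volume_cm3 = runif(6),
                   experiment = "E1")
  t2 <- data.frame(plant_id = paste0("b", 1:6), total_volume_cm3 = runif(6),
                   experiment = "E2")
  expect_identical(pool_experiments(list(t1)), t1)
  pooled <- pool_experiments(list(t1, t2))
  expect_equal(nrow(pooled), 12)
  expect_equal(table(pooled$experiment)[["E2"]], 6L)
  bad <- t2; names(bad)[2] <- "volume"
  expect_error(pool_experiments(list(t1, bad)), class = "rootmorph_validation_error")
})

test_that("coefficient of determination matches its textbook definition", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(coefficient_of_determination(x, 2 * x + 1)$r_squared, 1)
  y <- c(2.1, 3.9, 6.2, 8.1, 9.8)
  fitted <- coefficient_of_determination(x, y)
  res <- y - (lm(y ~ x)$fitted.values)
  byhand <- 1 - sum(res^2) / sum((y - mean(y))^2)
  expect_equal(fitted$r_squared, byhand, tolerance = 1e-12)
  expect_equal(fitted$n, 5)

  set.seed(99)
  xi <- rnorm(1000); yi <- rnorm(1000)
  expect_lt(coefficient_of_determination(xi, yi)$r_squared, 0.01)
  expect_error(coefficient_of_determination(rep(1, 5), x),
               class = "rootmorph_validation_error")
  expect_error(coefficient_of_determination(1:2, 1:2),
               class = "rootmorph_validation_error")
})

test_that("trait validation reports r^2 and per-plant errors", {
  set.seed(4)
  truth <- data.frame(plant_id = sprintf("p%02d", 1:10),
                      total_length_cm = runif(10, 50, 150),
                      total_volume_cm3 = runif(10, 0.5, 3))
  est <- truth
  est$total_length_cm <- truth$total_length_cm * 1.02
  est$total_volume_cm3 <- truth$total_volume_cm3 * 0.95
  rep <- validate_traits(est, truth)
  expect_equal(rep$r_squared, 1, tolerance = 1e-9)
  expect_equal(rep$n, 10)
  expect_equal(rep$per_plant$length_rel_error, rep(0.02, 10), tolerance = 1e-9)
})
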