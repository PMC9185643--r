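test_that("the registry exposes the 18 canonical indices", {
  reg <- index_registry()
  expect_length(reg, 18)
  expect_setequal(names(reg),
                  c("NDVI", "RVI", "EVI", "SSC", "SAVI", "CCI", "ARVI", "GCI",
                    "MCARI", "DCNI", "SIPI", "NBR", "DNBR", "NDWI", "PLS",
                    "PRI", "PSRI", "TA"))
  ndvi <- index_lookup("NDVI")
  expect_equal(sort(vapply(ndvi$bands, `[[`, 0, "target_nm")), c(640, 860))
  expect_error(index_lookup("XYZ"), class = "agrisurvey_unknown_index")

  # every closed-form index resolves against the standard band set
  wl <- c(450, 531, 560, 570, 640, 680, 705, 750, 800, 860, 1240, 2200)
  cube <- hyper_cube(array(0.3, c(2, 2, length(wl))), wl,
                     units = "reflectance")
  for (def in reg) {
    if (def$coefficients_required) next
    for (req in def$bands)
      expect_silent(band_at(cube, req$target_nm, req$tolerance_nm))
    # chemometric indices are declared parameterized, not band-bound
  }
  expect_true(all(vapply(reg[c("SSC", "PLS", "TA")], `[[`, TRUE,
                         "coefficients_required")))
  expect_true(reg$DNBR$two_epoch)
})

test_that("NDVI evaluates the normalized difference with nodata safety", {
  wl <- c(640, 860)
  arr <- array(0, c(3, 4, 2))
  arr[, , 1] <- 0.1; arr[, , 2] <- 0.5
  cube <- hyper_cube(arr, wl, units = "reflectance")
  map <- compute_index(cube, "NDVI")
  expect_equal(unique(round(as.vector(map$values), 4)), 0.6667)

  # IR = RED gives exactly zero
  arr[, , 2] <- 0.1
  expect_true(all(compute_index(hyper_cube(arr, wl, units = "reflectance"),
                                "NDVI")$values == 0))

  # zero denominator and nodata inputs become nodata
  arr[1, 1, ] <- 0
  arr[2, 2, 1] <- NA
  map2 <- compute_index(hyper_cube(arr, wl, units = "reflectance"), "NDVI")
  expect_true(is.na(map2$values[1, 1]))
  expect_true(is.na(map2$values[2, 2]))

  dn <- hyper_cube(arr, wl, units = "DN")
  expect_error(compute_index(dn, "NDVI"), "calibration")
  one_band <- hyper_cube(array(0.5, c(2, 2, 1)), 550, units = "reflectance")
  expect_error(compute_index(one_band, "NDVI"),
               class = "agrisurvey_missing_band")
})

test_that("every closed-form formula matches independent scalar evaluation", {
  set.seed(13)
  closed <- c("NDVI", "RVI", "EVI", "SAVI", "CCI", "ARVI", "GCI", "MCARI",
              "DCNI", "SIPI", "NBR", "NDWI", "PRI", "PSRI")
  for (rep in 1:100) {
    s <- standard_spectrum()
    cube <- constant_cube(vapply(s, identity, 0), rows = 1, cols = 1)
    for (nm in closed) {
      got <- compute_index(cube, nm)$values[1, 1]
      want <- scalar_index_oracle(nm, s)
      expect_equal(got, want, tolerance = 1e-12,
                   label = sprintf("%s (rep %d)", nm, rep))
    }
  }
})

test_that("normalized-difference indices are antisymmetric under band swap", {
  set.seed(19)
  reg <- index_registry()
  nd <- Filter(function(d) d$normalized_difference, reg)
  expect_gte(length(nd), 4)
  for (def in nd) {
    wls <- vapply(def$bands, `[[`, 0, "target_nm")
    for (k in 1:20) {
      a <- runif(1, 0.05, 0.9); b <- runif(1, 0.05, 0.9)
      mk <- function(v1, v2) {
        arr <- array(c(v1, v2), c(1, 1, 2))
        # attach values to this definition's two wavelengths
        hyper_cube(arr, sort(wls), units = "reflectance")
      }
      lo <- sort(wls)
      # map role order: fun uses roles, resolved by wavelength targets
      c1 <- mk(a, b); c2 <- mk(b, a)
      v1 <- compute_index(c1, def$name)$values[1, 1]
      v2 <- compute_index(c2, def$name)$values[1, 1]
      expect_equal(v1, -v2, tolerance = 1e-12, label = def$name)
    }
  }
})

test_that("NDVI stays in [-1, 1] and is scale-invariant", {
  set.seed(29)
  for (k in 1:50) {
    ir <- runif(1, 0, 1); red <- runif(1, 0, 1)
    if (ir + red == 0) next
    arr <- array(c(red, ir), c(1, 1, 2))
    cube <- hyper_cube(arr, c(640, 860), units = "reflectance")
    v <- compute_index(cube, "NDVI")$values[1, 1]
    expect_gte(v, -1); expect_lte(v, 1)
    s <- runif(1, 0.1, 5)
    cube2 <- hyper_cube(arr * s, c(640, 860), units = "reflectance")
    expect_equal(compute_index(cube2, "NDVI")$values[1, 1], v,
                 tolerance = 1e-12)
  }
})

test_that("chemometric indices demand coefficients and evaluate linearly", {
  wl <- c(450, 531, 560, 570, 640, 680, 705, 750, 800, 860, 1240, 2200)
  cube <- hyper_cube(array(0.2, c(2, 2, length(wl))), wl,
                     units = "reflectance")
  expect_error(compute_index(cube, "SSC"), "coefficients")
  map <- compute_index(cube, "SSC",
                       coefficients = list(intercept = 1, w860 = 10,
                                           w640 = -5))
  expect_equal(unique(as.vector(map$values)), 1 + 10 * 0.2 - 5 * 0.2)
})

test_that("DNBR subtracts post-epoch from pre-epoch NBR", {
  wl <- c(860, 2200)
  pre <- hyper_cube(array(c(0.6, 0.2), c(1, 1, 2)), wl, units = "reflectance")
  post <- hyper_cube(array(c(0.3, 0.4), c(1, 1, 2)), wl, units = "reflectance")
  expect_error(compute_index(pre, "DNBR"), "two-epoch")
  got <- compute_index(pre, "DNBR", cube_post = post)$values[1, 1]
  nbr <- function(n, s) (n - s) / (n + s)
  expect_equal(got, nbr(0.6, 0.2) - nbr(0.3, 0.4), tolerance = 1e-12)
})

test_that("classification covers half-open intervals with exact counts", {
  vals <- matrix(c(0.5, 0.2, 0.3, NA, 0.31, -0.1), 2, 3)
  map <- structure(list(values = vals, index_name = "NDVI",
                        range_hint = c(-1, 1), provenance = list()),
                   class = "index_map")
  cls <- classify(map)
  expect_equal(sum(cls$counts), 5)             # NA pixel unlabeled
  expect_equal(cls$counts[["healthy"]], 2)     # 0.5 and 0.31
  expect_equal(cls$counts[["not_healthy"]], 3) # 0.2, 0.3 (boundary), -0.1
  expect_identical(cls$labels[1, 2], "not_healthy")  # exactly 0.3

  # constructed 40% healthy fraction
  v40 <- matrix(c(rep(0.8, 40), rep(0.1, 60)), 10, 10)
  m40 <- structure(list(values = v40, index_name = "NDVI",
                        range_hint = c(-1, 1), provenance = list()),
                   class = "index_map")
  c40 <- classify(m40)
  expect_equal(c40$counts[["healthy"]] / sum(c40$counts), 0.40)

  # permutation invariance of counts
  vperm <- matrix(sample(as.vector(v40)), 10, 10)
  mperm <- m40; mperm$values <- vperm
  expect_equal(classify(mperm)$counts, c40$counts)

  bad <- data.frame(label = c("a", "b"), lower = c(0, 0.2), upper = c(0.5, 1))
  expect_error(classify(map, bad), class = "agrisurvey_invalid_rules")
})

test_that("histograms conserve pixel counts and spread uniform data evenly", {
  vals <- matrix(0.25, 8, 8)
  map <- structure(list(values = vals, index_name = "NDVI",
                        range_hint = c(-1, 1), provenance = list()),
                   class = "index_map")
  h <- index_histogram(map, n_bins = 10)
  expect_equal(sum(h$counts), 64)
  expect_equal(sum(h$counts > 0), 1)           # single nonzero bin
  expect_equal(range(h$edges), c(-1, 1))       # fixed edges for ND indices

  set.seed(37)
  n <- 1e5
  u <- matrix(runif(n, -1, 1), 250, 400)
  mu <- structure(list(values = u, index_name = "NDVI",
                       range_hint = c(-1, 1), provenance = list()),
                  class = "index_map")
  hu <- index_histogram(mu, n_bins = 10)
  expect_equal(sum(hu$counts), n)
  p <- 1 / 10
  sigma <- sqrt(n * p * (1 - p))
  expect_true(all(abs(hu$counts - n * p) < 4 * sigma))

  mna <- mu; mna$values[] <- NA
  expect_error(index_histogram(mna), "nodata")
})
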