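test_that("extractHU pulls exactly the masked voxel values", {
  vol <- imageVolume(array(40, dim = c(6, 6, 6)))
  m <- array(FALSE, c(6, 6, 6))
  m[2, 2, 2:4] <- TRUE; m[5, 5, 1:5] <- TRUE; m[1, 1, 1:2] <- TRUE
  mask <- suppressWarnings(binaryMask(m, geometry = vol, organ = "kidney_L"))
  s <- extractHU(vol, mask)
  expect_length(huValues(s), sum(m))
  expect_true(all(huValues(s) == 40))

  v2 <- array(0, dim = c(6, 6, 6))
  v2[2, 2, 2] <- -700; v2[2, 2, 3] <- -650; v2[2, 2, 4] <- -720
  m2 <- array(FALSE, c(6, 6, 6)); m2[2, 2, 2:4] <- TRUE
  s2 <- extractHU(imageVolume(v2),
                  suppressWarnings(binaryMask(m2, organ = "lung_L")))
  expect_setequal(huValues(s2), c(-700, -650, -720))

  empty <- suppressWarnings(binaryMask(array(FALSE, c(6, 6, 6)),
                                       organ = "brain"))
  expect_error(extractHU(vol, empty), "degenerate")
  other <- imageVolume(array(0, dim = c(6, 6, 6)), spacing = c(2, 2, 2))
  expect_error(extractHU(other, mask), "geometry error")
})

test_that("a Gaussian-sample KDE matches the variance-inflated normal density", {
  set.seed(7)
  x <- rnorm(10000, 40, 10)
  grid <- kdeGrid(-20, 100, 0.5)
  k <- fitKDE(huSample(x), grid)
  h <- bandwidth(k)
  expect_equal(h, sd(x) * 10000^(-1 / 5))  # Scott's rule
  oracle <- dnorm(gridPoints(grid), 40, sqrt(10^2 + h^2))
  expect_lt(max(abs(densityValues(k) - oracle)), 0.004)
  expect_equal(kdeIntegral(k), 1, tolerance = 0.02)
})

test_that("KDE handles degenerate samples and stays normalized", {
  grid <- kdeGrid(-20, 100, 0.5)
  expect_warning(k <- fitKDE(huSample(rep(40, 50)), grid), "zero sample")
  expect_equal(gridPoints(grid)[which.max(densityValues(k))], 40)
  expect_equal(kdeIntegral(k), 1, tolerance = 0.02)
  expect_true(all(densityValues(k) >= 0))

  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(500, runif(1, 0, 60), runif(1, 5, 15))
    k <- suppressWarnings(fitKDE(huSample(x), grid))
    expect_true(all(densityValues(k) >= 0))
    expect_gte(kdeIntegral(k), 0.98)
    expect_lte(kdeIntegral(k), 1.02)
  }
  expect_warning(fitKDE(huSample(rnorm(100, 200, 10)), grid), "grid does not cover")
})

test_that("baselines average pointwise with sample-SD two-sigma bounds", {
  grid <- kdeGrid(0, 80, 1)
  set.seed(21)
  k1 <- suppressWarnings(fitKDE(huSample(rnorm(2000, 40, 8)), grid))
  k2 <- suppressWarnings(fitKDE(huSample(rnorm(2000, 42, 8)), grid))

  same <- buildBaseline(list(k1, k1, k1), organ = "brain")
  expect_equal(sdDensity(same), rep(0, length(gridPoints(grid))))
  expect_equal(lowerBound(same), meanDensity(same))
  expect_equal(upperBound(same), meanDensity(same))

  two <- buildBaseline(list(k1, k2), organ = "brain")
  expect_equal(sdDensity(two),
               abs(densityValues(k1) - densityValues(k2)) / sqrt(2))
  mu <- meanDensity(two)
  step <- 1
  expect_equal(sum((mu[-1] + mu[-length(mu)]) / 2) * step, 1,
               tolerance = 0.02)
  expect_equal(lowerBound(two), pmax(mu - 2 * sdDensity(two), 0))

  expect_error(buildBaseline(list(k1), organ = "brain"), "degenerate")
  other <- suppressWarnings(fitKDE(huSample(rnorm(100, 40, 8)),
                                   kdeGrid(0, 80, 2)))
  expect_error(buildBaseline(list(k1, other), organ = "brain"),
               "geometry error")
})

test_that("agreement value counts grid points inside the inclusive envelope", {
  # 5-point grid with hand-set bounds: mean = (lower+upper)/2, sd = (u-l)/4
  pts <- 0:4
  grid <- new("KDEGrid", points = as.numeric(pts), step = 1)
  lower <- c(0.08, 0.18, 0.38, 0.18, 0.08)
  upper <- c(0.12, 0.22, 0.42, 0.22, 0.12)
  mu <- (lower + upper) / 2
  sdv <- (upper - lower) / 4
  bl <- new("BaselineKDE", organ = "brain", grid = grid, meanDensity = mu,
            sdDensity = sdv, lower = lower, upper = upper,
            nReference = 2L, bandwidthRule = "fixed")
  mkCurve <- function(d) new("KDECurve", grid = grid, density = d,
                             bandwidth = 1, nSamples = 10L)
  expect_equal(agreementValue(mkCurve(c(0.10, 0.25, 0.40, 0.20, 0.10)), bl),
               4 / 5)
  expect_equal(agreementValue(mkCurve(mu), bl), 1.0)
  offGrid <- new("KDECurve", grid = new("KDEGrid", points = as.numeric(1:5),
                                        step = 1),
                 density = mu, bandwidth = 1, nSamples = 10L)
  expect_error(agreementValue(offGrid, bl), "geometry error")
})

test_that("agreement is organ-size invariant on matched populations", {
  grid <- kdeGrid(0, 80, 1)
  set.seed(13)
  curves <- lapply(1:30, function(i)
    suppressWarnings(fitKDE(huSample(rnorm(2000, 40, 10)), grid)))
  bl <- buildBaseline(curves, organ = "kidney_L")
  x <- rnorm(2000, 40, 10)
  a1 <- agreementValue(suppressWarnings(fitKDE(huSample(x), grid)), bl)
  a2 <- agreementValue(suppressWarnings(fitKDE(huSample(c(x, x)), grid)), bl)
  expect_lt(abs(a1 - a2), 0.05)
})

test_that("contamination degrades agreement monotonically", {
  grid <- kdeGrid(-160, 120, 1)
  set.seed(29)
  curves <- lapply(1:40, function(i)
    suppressWarnings(fitKDE(huSample(rnorm(3000, 40, 10)), grid)))
  bl <- buildBaseline(curves, organ = "kidney_L")
  agr <- vapply(c(0, 0.2, 0.5, 0.8), function(phi) {
    vals <- replicate(5, {
      n <- 3000
      nc <- round(phi * n)
      # contaminant mode shifted by 5 baseline SDs (50 HU below the mean)
      x <- c(rnorm(n - nc, 40, 10), rnorm(nc, -10, 10))
      agreementValue(suppressWarnings(fitKDE(huSample(x), grid)), bl)
    })
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(agr) <= 1e-9))
  expect_lt(agr[4], agr[1])
})

test_that("qaContourSet flags contaminated organs and missing baselines", {
  spec <- defaultPhantomSpec()
  ph <- generatePhantom(spec, seed = 101)
  grid <- kdeGrid(-1024, 400, 2)
  curves <- lapply(1:25, function(i) {
    phi <- generatePhantom(spec, seed = 1000 + i)
    fitKDE(extractHU(phi$image, phi$masks$kidney_L), grid)
  })
  bl <- list(kidney_L = buildBaseline(curves, organ = "kidney_L"))

  matched <- qaContourSet(ph$image, list(ph$masks$kidney_L), bl,
                          threshold = 0.75, patientId = "p1",
                          method = "nn")
  expect_equal(matched$verdict, "pass")

  dilated <- perturbMask(ph$masks$kidney_L, "dilate", 3)
  bad <- qaContourSet(ph$image, list(dilated), bl, threshold = 1.0,
                      patientId = "p1", method = "atlas")
  expect_lt(bad$agreement, matched$agreement)
  expect_equal(bad$verdict, "review")

  rows <- qaContourSet(ph$image, list(ph$masks$brain), bl, threshold = 1.0)
  expect_equal(rows$verdict, "no_baseline")
  expect_true(is.nan(rows$agreement))
})

test_that("baseline JSON serialization round-trips bit-identically", {
  grid <- kdeGrid(-100, 100, 2)
  set.seed(41)
  curves <- lapply(1:5, function(i)
    suppressWarnings(fitKDE(huSample(rnorm(800, 30, 12)), grid)))
  bl <- list(kidney_L = buildBaseline(curves, organ = "kidney_L"),
             brain = buildBaseline(curves[1:3], organ = "brain"))
  f <- withr::local_tempfile(fileext = ".json")
  writeBaselines(bl, f)
  back <- readBaselines(f)
  expect_identical(names(back), names(bl))
  for (org in names(bl)) {
    expect_identical(meanDensity(back[[org]]), meanDensity(bl[[org]]))
    expect_identical(sdDensity(back[[org]]), sdDensity(bl[[org]]))
    expect_identical(gridPoints(back[[org]]), gridPoints(bl[[org]]))
    expect_identical(nReference(back[[org]]), nReference(bl[[org]]))
  }
})

test_that("support-restricted agreement strips trivially agreeing tails", {
  grid <- kdeGrid(-1024, 1600, 2)   # mostly zero-density tails
  set.seed(55)
  curves <- lapply(1:20, function(i)
    suppressWarnings(fitKDE(huSample(rnorm(2000, 40, 10)), grid)))
  bl <- buildBaseline(curves, organ = "brain")
  test <- suppressWarnings(fitKDE(huSample(rnorm(2000, 40, 18)), grid))
  full <- agreementValue(test, bl, support = "full")
  restr <- agreementValue(test, bl, support = "restricted")
  expect_lt(restr, full)   # the full-grid denominator inflates agreement
})
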