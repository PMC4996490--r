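unit_over <- function(x0, x1, y) data.frame(x0 = x0, x1 = x1, y = y)

test_that("median summaries: constant field and sorting oracle", {
  ls <- toy_landscape(matrix(1500, 3, 5))
  cv <- extract_covariates(unit_over(0, 10, 3), ls, geometry = FALSE)
  expect_equal(cv$field, 1500)
  # 3x3 grid holding 1..9: median must equal the brute-force sort midpoint
  vals <- matrix(c(7, 3, 9, 1, 5, 8, 2, 6, 4), 3, 3)
  ls2 <- toy_landscape(vals)
  cv2 <- extract_covariates(unit_over(0, 6, 3), ls2, geometry = FALSE)
  expect_equal(cv2$field, sort(as.vector(vals))[5])
})

test_that("land-cover share: 6 of 16 class cells gives 0.375", {
  cls <- matrix(0, 4, 4)
  cls[c(1, 2, 5, 9, 10, 16)] <- 1
  ls <- toy_landscape(cls, type = "proportion")
  cv <- extract_covariates(unit_over(0, 8, 4), ls, width_km = 8,
                           geometry = FALSE)
  expect_equal(cv$field, 6 / 16)
})

test_that("units without intersecting cells error", {
  ls <- toy_landscape(matrix(1, 3, 3))
  expect_error(extract_covariates(unit_over(50, 60, 3), ls), "no grid cells")
})

test_that("correlation screening flags |r| > 0.6 and is order-invariant", {
  set.seed(61)
  d <- data.frame(x = rnorm(100))
  d$double_x <- 2 * d$x
  d$z <- rnorm(100)
  sc <- screen_correlation(d)
  expect_true(sc$flagged[sc$var1 %in% c("x", "double_x") &
                         sc$var2 %in% c("x", "double_x")])
  expect_equal(sc$r[1], 1)
  sc2 <- screen_correlation(d[, c("z", "double_x", "x")])
  key <- function(s) sort(paste(pmin(s$var1, s$var2), pmax(s$var1, s$var2),
                                round(s$r, 12)))
  expect_identical(key(sc[sc$flagged, ]), key(sc2[sc2$flagged, ]))
})

test_that("screening r matches the covariance formula on a 5-point table", {
  d <- data.frame(a = c(1, 4, 2, 8, 5), b = c(2, 3, 1, 9, 4))
  sc <- screen_correlation(d)
  za <- d$a - mean(d$a); zb <- d$b - mean(d$b)
  r_brute <- sum(za * zb) / sqrt(sum(za^2) * sum(zb^2))
  expect_equal(sc$r, r_brute, tolerance = 1e-12)
})

test_that("zero-variance covariates are dropped from screening with warning", {
  d <- data.frame(a = rnorm(10), b = rnorm(10), c = 1)
  expect_warning(sc <- screen_correlation(d), "zero-variance")
  expect_false("c" %in% c(sc$var1, sc$var2))
})

test_that("design building enforces the quadratic hierarchy", {
  expect_error(rsf_spec(linear = "forest", quadratic = "elevation"),
               "linear parent")
  sp <- rsf_spec(linear = "elevation", quadratic = "elevation")
  d <- data.frame(elevation = 1:5)
  X <- build_design(d, sp)
  expect_identical(colnames(X), c("(Intercept)", "elevation",
                                  "I(elevation^2)"))
  expect_equal(X[, 3], d$elevation^2, ignore_attr = TRUE)
})

test_that("full- and final-model designs have the hand-counted widths", {
  set.seed(62)
  n <- 20
  nms <- c("elevation", "solar", "popdens", "ruggedness", "road1", "road2",
           "wind_class", "shrub", "grassland", "crop", "developed",
           "forest", "barren", "wetland")
  d <- as.data.frame(setNames(lapply(nms, function(x) rnorm(n)), nms))
  d$aspect <- factor(sample(c("N", "S", "E", "W"), n, TRUE),
                     levels = c("N", "S", "E", "W"))
  # full model: 14 continuous + 2 quadratics + 3 aspect indicators + intercept
  full <- rsf_spec(linear = nms, quadratic = c("elevation", "solar"),
                   categorical = "aspect")
  expect_identical(ncol(build_design(d, full)), 20L)
  expect_identical(colnames(build_design(d, full))[1], "(Intercept)")
  # final model: elevation, solar (+ quadratics), forest, developed, wind
  fin <- rsf_spec(linear = c("elevation", "solar", "forest", "developed",
                             "wind_class"),
                  quadratic = c("elevation", "solar"))
  expect_identical(ncol(build_design(d, fin)), 8L)
})

test_that("univariate AIC comparison prefers the covariate driving counts", {
  set.seed(63)
  wins <- 0
  for (r in 1:20) {
    n <- 800
    forest <- runif(n)
    ndvi <- 0.25 + 0.5 * forest + rnorm(n, 0, 0.12)  # correlated proxy
    mu <- exp(0.3 - 2.2 * forest)
    d <- data.frame(forest = forest, ndvi = ndvi,
                    pseudocount = rnbinom(n, mu = mu, size = 1.5),
                    n_years = 1)
    cmp <- suppressWarnings(compare_univariate(d, "forest", "ndvi"))
    wins <- wins + (identical(cmp$preferred, "forest"))
  }
  expect_gte(wins, 18)
})

test_that("identical candidates tie within numerical tolerance", {
  set.seed(64)
  d <- data.frame(a = rnorm(200), n_years = 1)
  d$b <- d$a
  d$pseudocount <- rnbinom(200, mu = exp(0.5 + 0.3 * d$a), size = 2)
  cmp <- suppressWarnings(compare_univariate(d, "a", "b"))
  expect_true(cmp$tie)
  expect_equal(unname(diff(cmp$aic)), 0, tolerance = 1e-6)
})

test_that("aspect summaries fall back to N only when a unit is wholly flat", {
  ls <- toy_landscape(matrix(1, 4, 5))
  ls$fields$aspect <- matrix(NA_character_, 4, 5)  # flat terrain everywhere
  cv <- extract_covariates(unit_over(0, 10, 4), ls, width_km = 8,
                           geometry = FALSE)
  expect_identical(as.character(cv$aspect), "N")
})
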