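test_that("intercept-only fit recovers the closed-form log mean", {
  d <- data.frame(pseudocount = rep(4L, 60), n_years = 1)
  f <- suppressWarnings(rsf_nb(pseudocount ~ 1, d))
  expect_equal(unname(coef(f)), log(4), tolerance = 1e-6)
})

test_that("offsets rescale the intercept and leave slopes untouched", {
  set.seed(71)
  n <- 600
  d <- data.frame(x = rnorm(n), n_years = 1)
  d$pseudocount <- rnbinom(n, mu = 5 * exp(0.2 + 0.5 * d$x), size = 2)
  f1 <- rsf_nb(pseudocount ~ x, d)
  d5 <- d; d5$n_years <- 5
  f5 <- rsf_nb(pseudocount ~ x, d5)
  expect_equal(coef(f1)[["x"]], coef(f5)[["x"]], tolerance = 1e-8)
  expect_equal(coef(f1)[["(Intercept)"]] - coef(f5)[["(Intercept)"]],
               log(5), tolerance = 1e-8)
  # doubling every effort shifts the intercept by -log 2
  d10 <- d; d10$n_years <- 10
  f10 <- rsf_nb(pseudocount ~ x, d10)
  expect_equal(coef(f10)[["(Intercept)"]] - coef(f5)[["(Intercept)"]],
               -log(2), tolerance = 1e-8)
})

test_that("degenerate inputs are rejected with clear messages", {
  d <- data.frame(pseudocount = c(0L, 0L, 0L, 0L), n_years = 1, x = 1:4)
  expect_error(rsf_nb(pseudocount ~ x, d), "all-zero")
  d2 <- data.frame(pseudocount = c(1.5, 2, 1), n_years = 1, x = 1:3)
  expect_error(rsf_nb(pseudocount ~ x, d2), "non-negative integers")
  d3 <- data.frame(pseudocount = 1:3, n_years = c(0, 1, 1), x = 1:3)
  expect_error(rsf_nb(pseudocount ~ x, d3), "effort")
})

test_that("BIC follows the fixed convention: dispersion counts, n = units", {
  set.seed(72)
  n <- 300
  d <- data.frame(x = rnorm(n), n_years = 1)
  d$pseudocount <- rnbinom(n, mu = exp(0.6 + 0.4 * d$x), size = 2)
  f <- rsf_nb(pseudocount ~ x, d)
  expect_equal(f$bic,
               bic_value(as.numeric(logLik(f)), length(coef(f)) + 1, n),
               tolerance = 1e-10)
  expect_equal(f$bic, BIC(f), tolerance = 1e-10)
  # a deletion that leaves the log-likelihood unchanged changes BIC by ln(n)
  ll <- as.numeric(logLik(f))
  expect_equal(bic_value(ll, 4, 1845) - bic_value(ll, 3, 1845), log(1845),
               tolerance = 1e-12)
})

test_that("backwards selection respects the hierarchy and lowers BIC", {
  set.seed(73)
  n <- 800
  d <- data.frame(x = rnorm(n), z = rnorm(n), n_years = 1)
  d$pseudocount <- rnbinom(n, mu = exp(0.3 + 0.6 * d$x - 0.3 * d$x^2),
                           size = 2)
  full <- suppressWarnings(rsf_nb(pseudocount ~ x + I(x^2) + z, d))
  sel <- suppressWarnings(backwards_bic(full))
  kept <- attr(terms(sel$fit$rsf$formula), "term.labels")
  if ("I(x^2)" %in% kept) expect_true("x" %in% kept)
  # replay the trace: the linear parent is never removed before its square
  labs <- c("x", "I(x^2)", "z")
  for (rm in sel$removed) {
    expect_false(rm == "x" && "I(x^2)" %in% labs)
    labs <- setdiff(labs, rm)
  }
  if (nrow(sel$trace)) {
    expect_true(all(diff(c(full$bic, sel$trace$bic_after)) < 0))
    expect_true(all(is.finite(sel$trace$max_rel_coef_change)))
  }
  expect_lte(sel$fit$bic, full$bic)
})

test_that("deviance GOF statistic equals the hand-computed NB2 deviance", {
  set.seed(74)
  n <- 200
  d <- data.frame(x = rnorm(n), n_years = sample(2:5, n, TRUE))
  d$pseudocount <- rnbinom(n, mu = d$n_years * exp(0.3 + 0.4 * d$x),
                           size = 2)
  f <- rsf_nb(pseudocount ~ x, d)
  g <- gof_deviance(f)
  mu <- fitted(f); y <- d$pseudocount; th <- f$theta
  dev_i <- 2 * (ifelse(y > 0, y * log(y / mu), 0) -
                (y + th) * log((y + th) / (mu + th)))
  expect_equal(unname(g$statistic), sum(dev_i), tolerance = 1e-8)
  expect_equal(unname(g$parameter), n - 2, ignore_attr = TRUE)
  expect_equal(g$p.value,
               pchisq(sum(dev_i), n - 2, lower.tail = FALSE),
               tolerance = 1e-7)
})

test_that("Moran's I: antisymmetric pair gives -1, matches the double sum", {
  expect_equal(morans_i(c(3, -3), c(0, 0), c(0, 10))$I, -1)
  set.seed(75)
  x <- runif(5, 0, 300); y <- runif(5, 0, 300); v <- rnorm(5)
  mi <- morans_i(v, x, y, radius_km = 200)
  d <- as.matrix(dist(cbind(x, y)))
  w <- (d > 0 & d <= 200) * 1
  z <- v - mean(v)
  s <- 0
  for (i in 1:5) for (j in 1:5) s <- s + w[i, j] * z[i] * z[j]
  expect_equal(mi$I, (5 / sum(w)) * s / sum(z^2), tolerance = 1e-12)
  expect_identical(mi$flagged, mi$I > 0.2)
  expect_error(morans_i(v, x, y, radius_km = 0.001), "no neighbour")
})

test_that("row-standardized Moran's I agrees with ape and stays in [-1, 1]", {
  skip_if_not_installed("ape")
  set.seed(76)
  for (r in 1:5) {
    n <- 25
    x <- runif(n, 0, 500); y <- runif(n, 0, 500); v <- rnorm(n)
    mi <- morans_i(v, x, y, 200, row_standardize = TRUE)
    d <- as.matrix(dist(cbind(x, y)))
    w <- (d > 0 & d <= 200) * 1
    expect_equal(mi$I, ape::Moran.I(v, w)$observed, tolerance = 1e-10)
    expect_true(mi$I >= -1 - 1e-9 && mi$I <= 1 + 1e-9)
  }
})

test_that("intensity predictions drop the effort offset", {
  sv <- small_survey()$survey
  f <- suppressWarnings(rsf_nb(pseudocount ~ elevation_s + forest, sv$units))
  lam <- predict(f, sv$units, type = "intensity")
  expect_equal(lam * sv$units$n_years, unname(fitted(f)), tolerance = 1e-10)
  nd <- sv$units[1:3, c("elevation_s", "forest")]  # no effort column needed
  expect_equal(predict(f, nd, type = "intensity"), lam[1:3],
               tolerance = 1e-10)
  cf <- coef(f)
  brute <- exp(cf[1] + cf[2] * nd$elevation_s + cf[3] * nd$forest)
  expect_equal(predict(f, nd, type = "intensity"), unname(brute),
               tolerance = 1e-10)
})
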