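test_that("worked example: three inflated groups sum to 7.734 and round to 8", {
  det <- default_detection()
  recs <- data.frame(group_size = c(1, 2, 1),
                     obs_type = c("flying", "perched107", "perched107"),
                     position = c("back-left", "right", "right"))
  infl <- inflate_observation(recs, det)
  expect_equal(infl[1], 1 / 0.380, tolerance = 1e-10)
  expect_equal(infl[2], 2 / 0.588, tolerance = 1e-10)
  expect_equal(sum(infl), 7.734, tolerance = 5e-4)
  units <- data.frame(unit_id = 1, n_years = 5)
  recs$unit_id <- 1
  pc <- accumulate_units(recs, det, units)
  expect_equal(pc$raw_sum, 7.734, tolerance = 5e-4)
  expect_identical(pc$pseudocount, 8L)
})

test_that("certain detection leaves group sizes unchanged", {
  det <- flat_detection(1)
  recs <- data.frame(group_size = c(3, 1, 7),
                     obs_type = c("flying", "perched150", "perched107"),
                     position = c("right", "back-left", "front-right"))
  expect_equal(inflate_observation(recs, det), c(3, 1, 7))
})

test_that("inflation matches brute-force group_size / p_bar summation", {
  set.seed(101)
  det <- default_detection()
  recs <- data.frame(
    group_size = sample(1:4, 50, replace = TRUE),
    obs_type = sample(c("perched107", "perched150", "flying"), 50, TRUE),
    position = sample(c("back-left", "right", "front-right"), 50, TRUE),
    unit_id = 1)
  brute <- 0
  for (i in 1:50) {
    p <- det$p_bar[det$obs_type == recs$obs_type[i] &
                   det$position == recs$position[i]]
    brute <- brute + recs$group_size[i] / p
  }
  units <- data.frame(unit_id = 1, n_years = 5)
  pc <- accumulate_units(recs, det, units)
  expect_equal(pc$raw_sum, brute, tolerance = 1e-12)
  # monotone: adding a record never decreases the sum; lower bound: at least
  # the detected individuals
  pc2 <- accumulate_units(rbind(recs, recs[1, ]), det, units)
  expect_gt(pc2$raw_sum, pc$raw_sum)
  expect_gte(pc$raw_sum, sum(recs$group_size))
})

test_that("rounding rule is half away from zero, half-even selectable", {
  det <- flat_detection(0.5)
  units <- data.frame(unit_id = 1, n_years = 1)
  recs <- data.frame(unit_id = 1, group_size = c(1, 1, 1, 2),
                     obs_type = "flying", position = "right")
  # raw_sum = 2 + 2 + 2 + 4 = 10; engineered halves below
  d <- detection_table(data.frame(
    obs_type = rep(c("perched107", "perched150", "flying"), each = 3),
    position = rep(c("back-left", "right", "front-right"), 3),
    p_bar = 0.8, se = 0))
  r1 <- data.frame(unit_id = 1, group_size = 2, obs_type = "flying",
                   position = "right")  # 2 / 0.8 = 2.5
  expect_identical(accumulate_units(r1, d, units)$pseudocount, 3L)
  expect_identical(accumulate_units(r1, d, units,
                                    round_rule = "half-even")$pseudocount, 2L)
  expect_equal(accumulate_units(recs, det, units)$raw_sum, 10)
})

test_that("unknown strata and malformed tables error informatively", {
  det <- default_detection()
  bad <- data.frame(group_size = 1, obs_type = "soaring",
                    position = "right")
  expect_error(inflate_observation(bad, det), "soaring")
  expect_error(detection_table(data.frame(obs_type = "flying",
                                          position = "right",
                                          p_bar = 0.5, se = 0)),
               "missing strata")
  d2 <- default_detection()
  d2$p_bar[1] <- 0
  expect_error(detection_table(d2), "p_bar")
  units <- data.frame(unit_id = 1, n_years = 5)
  orphan <- data.frame(unit_id = 99, group_size = 1, obs_type = "flying",
                       position = "right")
  expect_error(accumulate_units(orphan, det, units), "unknown unit")
})

test_that("empty units get pseudocount zero and zero iff raw_sum < 0.5", {
  det <- default_detection()
  units <- data.frame(unit_id = 1:3, n_years = 5)
  recs <- data.frame(unit_id = 2, group_size = 1, obs_type = "perched107",
                     position = "right")  # 1/0.588 = 1.70
  pc <- accumulate_units(recs, det, units)
  expect_equal(pc$raw_sum, c(0, 1 / 0.588, 0))
  expect_identical(pc$pseudocount, c(0L, 2L, 0L))
  expect_true(all(abs(pc$pseudocount - pc$raw_sum) <= 0.5))
  expect_identical(pc$pseudocount == 0L, pc$raw_sum < 0.5)
})

test_that("detection tables round-trip through CSV", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write.csv(as.data.frame(default_detection()), tmp, row.names = FALSE)
  d <- read_detection(tmp)
  expect_s3_class(d, "detection_table")
  expect_equal(d$p_bar, default_detection()$p_bar)
})

test_that("side-to-position mapping follows the crew configuration", {
  expect_identical(obs_position(c("left", "right")), c("back-left", "right"))
  expect_identical(obs_position("right", two_observer = TRUE), "front-right")
  expect_error(obs_position("top"), "side")
})
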