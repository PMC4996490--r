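# shared small synthetic survey, generated once per test run
small_survey <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(4001)
      land <- landscape(c(500, 360))
      cache <<- list(land = land,
                     survey = simulate_survey(land, n_points = 500))
    }
    cache
  }
})

# landscape whose single covariate field is set verbatim (for oracle tests);
# values: ny x nx matrix
toy_landscape <- function(values, cell_km = 2,
                          type = c("continuous", "proportion")) {
  type <- match.arg(type)
  ny <- nrow(values); nx <- ncol(values)
  ls <- landscape(c(nx * cell_km, ny * cell_km), cell_km = cell_km,
                  covariates = list(field = covariate_spec(type, mean = 0,
                                                           sd = 0)),
                  seed = 1)
  ls$fields$field <- values
  ls$fields$aspect <- NULL
  ls
}

# detection table with one probability (and se) for every stratum
flat_detection <- function(p = 1, se = 0) {
  d <- default_detection()
  d$p_bar <- p
  d$se <- se
  d
}
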