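test_that("moving average: identity, constancy, linear interior, affine equivariance", {
  x <- c(5, 5, 5, 5, 5)
  expect_equal(moving_average(x, 3), x)
  expect_equal(moving_average(1:10, 1), 1:10)
  expect_error(moving_average(numeric(0), 3), "empty")

  # centered mean of a ramp is exact away from the edges
  ramp <- 0:10
  sm <- moving_average(ramp, 2)
  expect_equal(sm[2:10], ramp[2:10])
  expect_equal(sm[1], 0.5)  # truncated edge window {0,1}
  expect_equal(sm[11], 9.5)

  # commutes with affine maps of the series
  set.seed(11)
  y <- cumsum(rnorm(200))
  expect_equal(moving_average(3 * y + 2, 20), 3 * moving_average(y, 20) + 2,
               tolerance = 1e-12)
})

test_that("paired t test agrees with the explicit formula on random samples", {
  set.seed(99)
  for (k in 1:1000) {
    n <- sample(3:12, 1)
    before <- rnorm(n, 37, 1)
    after <- before - rnorm(n, 0.5, 0.3)
    got <- paired_t(before, after)
    d <- before - after
    t_ref <- mean(d) / (sd(d) / sqrt(n))
    p_ref <- 2 * stats::pt(-abs(t_ref), n - 1)
    expect_equal(got$t, t_ref, tolerance = 1e-10)
    expect_equal(got$p, p_ref, tolerance = 1e-10)
    expect_identical(got$df, n - 1)
  }
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "degenerate")
})

test_that("Shapiro-Wilk wrapper matches reference values and is affine invariant", {
  # reference W/p computed with an independent implementation of the
  # standard approximation on frozen fixtures
  x1 <- c(-1.5466352714, -1.0004905456, -0.6554235052, -0.3754617702,
          -0.1225808439, 0.1225808439, 0.3754617702, 0.6554235052,
          1.0004905456, 1.5466352714)
  r1 <- shapiro_wilk(x1)
  expect_equal(r1$W, 0.9965048684, tolerance = 1e-6)
  expect_gt(r1$W, 0.98)
  expect_gt(r1$p, 0.99)

  r2 <- shapiro_wilk(c(rep(1, 9), 100))
  expect_equal(r2$W, 0.3657206277, tolerance = 1e-6)
  expect_lt(r2$p, 0.01)

  r3 <- shapiro_wilk(c(2.1, 3.4, 1.9, 5.6, 4.4, 2.7, 3.1))
  expect_equal(r3$W, 0.9329744712, tolerance = 1e-6)
  expect_equal(r3$p, 0.5764717682, tolerance = 1e-4)

  set.seed(5)
  y <- rnorm(25)
  expect_equal(shapiro_wilk(2.5 * y + 7)$W, shapiro_wilk(y)$W,
               tolerance = 1e-10)
  expect_error(shapiro_wilk(c(1, 2)), "at least 3")
})

test_that("cohort summary reproduces the published per-animal table cell for cell", {
  rep <- summarize_cohort(table1_records(), window_s = 60)
  pa <- rep$per_animal
  expect_equal(round(pa$brain_baseline, 1), c(36.0, 36.5, 36.8, 36.8))
  expect_equal(round(pa$brain_final, 1), c(35.6, 35.9, 36.1, 36.4))
  expect_equal(round(pa$body_baseline, 1), c(36.9, 37.1, 37.6, 37.5))
  expect_equal(round(pa$body_final, 1), c(36.3, 36.6, 36.8, 37.1))

  g <- rep$group
  gv <- function(v, f) g[[f]][g$variable == v]
  expect_equal(round(gv("brain_baseline", "mean"), 1), 36.5)
  expect_equal(round(gv("brain_baseline", "sd"), 1), 0.4)
  expect_equal(round(gv("body_baseline", "mean"), 1), 37.3)
  expect_equal(round(gv("body_baseline", "sd"), 1), 0.3)
  expect_equal(round(gv("body_rate", "mean"), 1), 0.6)
  expect_equal(round(gv("body_rate", "sd"), 1), 0.2)
  # the brain endpoint differences average 0.525 C/h at full precision
  expect_equal(gv("brain_rate", "mean"), 0.525, tolerance = 0.01)

  expect_equal(round(rep$paired$brain$p, 4), 0.0060)
  expect_equal(round(rep$paired$body$p, 4), 0.0067)
  expect_equal(rep$paired$brain$t, 7.00, tolerance = 0.01)
  expect_identical(rep$paired$brain$df, 3)
  expect_true(rep$normality_flag)
})

test_that("cohort summary basic contracts", {
  recs <- table1_records()
  expect_error(summarize_cohort(recs[1]), "length")
  short <- recs
  short[[2]]$brain_C <- short[[2]]$brain_C[-1]
  expect_error(summarize_cohort(short), "unequal")
  # two identical records give zero SDs
  twin <- list(recs[[1]], recs[[1]])
  twin[[2]]$animal_id <- "copy"
  g <- summarize_cohort(twin)$group
  expect_true(all(g$sd == 0))
})

test_that("simulation/experiment CI comparison flags containment correctly", {
  recs <- table1_records()
  tt <- seq(0, 3600)
  mean_brain <- rowMeans(vapply(recs, function(r) r$brain_C, numeric(3601)))
  mean_body <- rowMeans(vapply(recs, function(r) r$body_C, numeric(3601)))
  tr <- fake_trace(tt, body = mean_body, head = mean_brain)
  cmp <- compare_sim_to_experiment(tr, recs)
  expect_equal(unname(cmp$fraction_inside["overall"]), 1.0)

  tr_off <- fake_trace(tt, body = mean_body + 10, head = mean_brain + 10)
  cmp_off <- compare_sim_to_experiment(tr_off, recs)
  expect_equal(unname(cmp_off$fraction_inside["overall"]), 0.0)

  expect_error(compare_sim_to_experiment(fake_trace(seq(0, 100),
                                                    body = 0:100, head = 0:100),
                                         recs), "cooling hour")
})
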