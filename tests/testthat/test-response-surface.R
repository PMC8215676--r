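test_that("region classification realises the half-open saturated corner", {
  expect_equal(classify_region(16, 400), 1L)    # I = 400 edge stays Region 1
  expect_equal(classify_region(13.9, 500), 1L)  # before day 14
  expect_equal(classify_region(15, 450), 2L)
  expect_equal(classify_region(14, 401), 2L)
  expect_error(classify_region(17, 300), "t outside")
  expect_error(classify_region(10, 20), "I outside")
})

test_that("every in-domain point maps to exactly one region", {
  set.seed(13)
  t <- runif(1e4, 0, 16); I <- runif(1e4, 50, 500)
  r <- classify_region(t, I)
  expect_true(all(r %in% c(1L, 2L)))
  expect_identical(r, ifelse(t >= 14 & I > 400, 2L, 1L))
})

test_that("surface prediction dispatches by region", {
  s <- ref_surface
  expect_equal(predict(s, 13.02, 259.5), 111.225, tolerance = 1e-9)
  expect_equal(predict(s, 14, 400), 230.7177, tolerance = 1e-6)
  expect_equal(predict(s, 16, 500), 268.12, tolerance = 1e-6)
  expect_equal(predict(s, 15, 450), 10.6 + 30.47 * 15 - 0.46 * 450)
  # vectorised mixed-region call agrees with scalar calls
  expect_equal(predict(s, c(13.02, 15), c(259.5, 450)),
               c(predict(s, 13.02, 259.5), predict(s, 15, 450)))
  expect_error(predict(s, 17, 300), "outside")
})

test_that("reference-surface predictions are monotone and bounded", {
  s <- ref_surface
  t <- seq(0, 16, by = 0.25)
  for (I in c(50, 200, 400)) expect_true(all(diff(predict(s, t, I)) >= 0))
  I1 <- seq(50, 400, by = 5)
  for (tt in c(4, 10, 13.9)) expect_true(all(diff(predict(s, tt, I1)) >= 0))
  # Region 2 strictly decreasing in I at fixed t (negative light slope)
  I2 <- seq(405, 500, by = 5)
  for (tt in c(14, 15, 16)) expect_true(all(diff(predict(s, tt, I2)) < 0))
  grid <- expand.grid(t = seq(0, 16, by = 0.5), I = seq(50, 400, by = 10))
  v <- predict(s, grid$t, grid$I)
  expect_true(all(v >= 0.8 & v <= 442.5))
})

test_that("the boundary discontinuity is reported as a diagnostic", {
  gap <- boundary_gap(ref_surface)
  expect_equal(gap$t, c(14, 15, 16))
  # jump of ~22 mg at (14, 400): Region 2 plane sits above Region 1 there
  expect_gt(gap$gap[1], 20); expect_lt(gap$gap[1], 25)
})

test_that("build_surface recovers the generating surface without noise", {
  dat <- generate_growth(noise = noise_model(0, 0), seed = 1)
  built <- build_surface(dat)
  expect_equal(built$chosen_r1, "logistic_cum")
  expect_equal(built$chosen_r2, "plane")
  expect_equal(built$surface$region1$coef, ref_surface$region1$coef,
               tolerance = 1e-3)
  # Region-2 plane respects the sign constraints
  cf2 <- built$surface$region2$coef
  expect_gt(cf2[["kt"]], 0); expect_lt(cf2[["kI"]], 0)
})

test_that("a region without data raises an insufficient-data error", {
  dat <- generate_growth(grid_design(intensities = seq(50, 400, by = 50)),
                         noise = noise_model(0, 0), seed = 1)
  expect_error(build_surface(dat), "insufficient data for Region 2")
})

test_that("a positive Region-2 light slope triggers failover or failure", {
  # truth increasing in I everywhere: the plane candidate violates the
  # saturated-region sign constraint and cannot be selected
  grid <- expand.grid(t = c(0, 5, 8, 10, 14, 16),
                      I = seq(50, 500, by = 50))
  dat <- data.frame(t = grid$t, I = grid$I,
                    dw = 1 + 2 * grid$t + 0.3 * grid$I)
  set.seed(3); dat$dw <- dat$dw * (1 + rnorm(nrow(dat), 0, 0.01))
  expect_error(build_surface(dat, candidates_r1 = c("plane", "logistic_cum"),
                             candidates_r2 = "plane"),
               "sign")
  # with a non-plane fallback candidate the selection fails over
  built <- build_surface(dat, candidates_r1 = c("plane", "logistic_cum"),
                         candidates_r2 = c("plane", "exponential2d"))
  expect_equal(built$chosen_r2, "exponential2d")
})

test_that("validation protocol passes on-truth data and rejects offsets", {
  s <- ref_surface
  conds <- validation_conditions()
  exact <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i)
    data.frame(t = conds$t[i], I = conds$I[i],
               dw = predict(s, conds$t[i], conds$I[i]) * c(1, 1, 1.0001,
                                                           0.9999, 1, 1))))
  v <- validate_surface(s, exact)
  expect_true(all(v$pass)); expect_true(attr(v, "verdict"))
  # identical replicates equal to the prediction: degenerate but passing
  same <- data.frame(t = 10, I = 300, dw = rep(predict(s, 10, 300), 6))
  vs <- validate_surface(s, same)
  expect_true(vs$degenerate); expect_true(vs$pass)
  # +50% systematic offset at 5% noise is detected
  off <- generate_validation_set(s, rel_sd = 0.05, seed = 4)
  off$dw <- off$dw * 1.5
  vo <- validate_surface(s, off)
  expect_false(any(vo$pass))
  expect_false(attr(vo, "verdict"))
})

test_that("an exactly linear energy map leaves the fit invariant", {
  dat <- generate_growth(noise = noise_model(0, 0), seed = 1)
  rb <- robustness_substitution(dat, function(I) I / 4.44)
  expect_equal(rb$energy$region1$gof$rss, rb$intensity$region1$gof$rss,
               tolerance = 1e-6)
  ci <- rb$intensity$region1$params$coef
  ce <- rb$energy$region1$params$coef
  expect_equal(ce[["I_m4"]] * 4.44, ci[["I_m4"]], tolerance = 1e-6)
  expect_equal(ce[["k4"]] * 4.44, ci[["k4"]], tolerance = 1e-6)
  # time-axis parameters untouched by the regressor substitution
  expect_equal(ce[c("DW0", "DWmax", "t_m4", "k3")],
               ci[c("DW0", "DWmax", "t_m4", "k3")], tolerance = 1e-6)
})

test_that("per-level energy map keeps Region-1 inference significant", {
  emap <- data.frame(intensity = led_conditions()$intensity,
                     energy = led_conditions()$E_I)
  for (s in 1:5) {
    dat <- generate_growth(noise = noise_model(0.02, 0), seed = s)
    rb <- robustness_substitution(dat, emap)
    pe <- rb$parameter_table[rb$parameter_table$variant == "energy", ]
    expect_true(all(pe$p_value[pe$region == 1] < 0.05))
    # E_m4 lands near I_m4 / (I/E ratio ~ 4.4)
    e_m4 <- pe$estimate[pe$region == 1 & pe$coefficient == "I_m4"]
    expect_gt(259.5 / e_m4, 4.2); expect_lt(259.5 / e_m4, 4.7)
  }
  # the Region-2 intercept is weakly identified in the synthetic world
  # (boundary discontinuity of the truth surface); the verdict reports it
  dat <- generate_growth(noise = noise_model(0.02, 0), seed = 1)
  rb <- robustness_substitution(dat, emap)
  p2 <- rb$parameter_table[rb$parameter_table$variant == "energy" &
                           rb$parameter_table$region == 2, ]
  expect_true(all(p2$p_value[p2$coefficient != "DW0"] < 0.05))
  expect_false(rb$robust)
})

test_that("an unmapped intensity level raises a mapping error", {
  dat <- generate_growth(noise = noise_model(0, 0), seed = 1)
  emap <- data.frame(intensity = seq(50, 450, by = 50),
                     energy = seq(50, 450, by = 50) / 4.44)
  expect_error(robustness_substitution(dat, emap),
               "energy map missing intensity level")
})

test_that("surface config serialisation round-trips exactly", {
  path <- withr::local_tempfile(fileext = ".cfg")
  write_surface_config(ref_surface, path)
  back <- read_surface_config(path)
  expect_equal(back$region1$coef, ref_surface$region1$coef)
  expect_equal(back$region2$coef, ref_surface$region2$coef)
  expect_equal(back$t_range, ref_surface$t_range)
  expect_equal(back$I_range, ref_surface$I_range)
})
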