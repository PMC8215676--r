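test_that("goodness-of-fit identities and AIC arithmetic hold", {
  obs <- c(2, 4, 7, 11); fit <- c(1, 5, 6, 12)   # residuals 1,-1,1,-1
  g <- goodness_of_fit(obs, fit, p = 2)
  expect_equal(g$rss, 4); expect_equal(g$mae, 1)
  expect_equal(g$mse, 1); expect_equal(g$rmse, 1)
  expect_equal(g$r2, 1 - g$rss / g$tss)
  expect_equal(g$adj_r2, 1 - (1 - g$r2) * (g$n - 1) / (g$n - g$p))
  expect_equal(g$aic, g$n * log(g$rss / g$n) + 2 * g$p)
  # zero residuals: perfect fit, AIC diverges and is flagged
  gz <- goodness_of_fit(obs, obs, p = 2)
  expect_true(gz$perfect_fit); expect_true(is.nan(gz$aic))
  expect_equal(gz$r2, 1); expect_equal(gz$mae, 0)
  expect_error(goodness_of_fit(rep(5, 4), rep(4, 4), p = 2),
               "zero total sum of squares")
  expect_error(goodness_of_fit(obs, fit, p = 4), "n > p")
  # AIC monotone in RSS; one extra parameter costs exactly +2
  expect_true(aic_rss(2, 6, 3) > aic_rss(1, 6, 3))
  expect_equal(aic_rss(1.5, 6, 4) - aic_rss(1.5, 6, 3), 2)
})

test_that("one-sample t-test matches the closed form", {
  expect_equal(one_sample_ttest(c(3, 3, 3), 3)[c("t", "p")],
               list(t = 0, p = 1))
  r <- one_sample_ttest(1:5, 3)
  expect_equal(r$t, 0); expect_equal(r$p, 1); expect_equal(r$df, 4)
  r0 <- one_sample_ttest(1:5, 0)
  expect_equal(r0$t, 3 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r0$p, 0.0132, tolerance = 1e-2)  # printed to 3 significant figures
  dg <- one_sample_ttest(c(2, 2), 1)
  expect_true(dg$degenerate); expect_equal(dg$p, 0)
  expect_error(one_sample_ttest(1, 1), "at least 2")
})

test_that("default_init is deterministic and sane on noise-free logistic", {
  truth <- params_2d("logistic", A = 400, k2 = 0.5, tc = 13)
  t <- c(0, 5, 8, 10, 14, 16)
  d <- data.frame(t = t, dw = eval_2d(truth, t))
  init <- default_init("logistic", d)
  expect_true(init[["A"]] >= 350 && init[["A"]] <= 500)
  expect_identical(init, default_init("logistic", d))
  expect_error(default_init("logistic", d[1, , drop = FALSE]),
               "at least p \\+ 1")
  expect_error(default_init("logistic", data.frame(t = t, dw = rep(5, 6))),
               "flat data")
})

test_that("noise-free generator/fitter round trips recover the truth", {
  truth <- params_2d("logistic", A = 419.5, k2 = 0.49, tc = 13.5)
  t <- c(0, 2, 5, 8, 10, 12, 14, 16)
  d <- data.frame(t = t, dw = eval_2d(truth, t))
  f <- fit_growth("logistic", d)
  expect_true(f$converged)
  expect_lt(f$gof$rss, 1e-10)
  expect_equal(f$params$coef, truth$coef, tolerance = 1e-4)
  # every family round-trips on data it generated
  fams <- list(
    gompertz = params_2d("gompertz", A = 300, k = 0.4, tc = 12),
    exponential = params_2d("exponential", DW0 = -1.3, A = 1.81, R0 = 0.33),
    linear = params_2d("linear", DW0 = 0.5, A = 2.33))
  for (fam in names(fams)) {
    d <- data.frame(t = t, dw = eval_2d(fams[[fam]], t))
    f <- fit_growth(fam, d)
    expect_lt(f$gof$rss, 1e-8)
  }
})

test_that("fit statistics follow the regression ANOVA contract", {
  d <- logistic2d_data(3)
  f <- fit_growth("logistic", d)
  g <- f$gof
  expect_equal(f$f_value,
               ((g$tss - g$rss) / (f$p - 1)) / (g$rss / (f$n - f$p)))
  expect_equal(f$p_f, pf(f$f_value, f$p - 1, f$n - f$p, lower.tail = FALSE))
  ct <- f$coef_table
  expect_equal(ct$t_value, ct$estimate / ct$sd)
  expect_equal(ct$p_value, 2 * pt(-abs(ct$t_value), f$n - f$p))
  # estimates and SDs agree with the nls() reference on a noisy problem
  fn <- nls(dw ~ A / (1 + exp(-k2 * (t - tc))), d,
            start = list(A = 400, k2 = 0.5, tc = 13))
  expect_equal(f$coef_table$estimate,
               unname(coef(summary(fn))[, "Estimate"]), tolerance = 1e-6)
  expect_equal(f$coef_table$sd,
               unname(coef(summary(fn))[, "Std. Error"]), tolerance = 1e-6)
  # linear fit agrees with lm() exactly (shared closed-form optimum)
  fl <- fit_growth("linear", d)
  expect_equal(unname(fl$params$coef), unname(coef(lm(dw ~ t, d))),
               tolerance = 1e-8)
  expect_equal(fl$coef_table$sd,
               unname(sqrt(diag(vcov(lm(dw ~ t, d))))), tolerance = 1e-6)
})

test_that("optimizer never loses to a brute-force grid (oracle check)", {
  for (s in 1:5) {
    d <- logistic2d_data(s, rel_sd = 0.05)
    init <- default_init("logistic", d)
    f <- fit_growth("logistic", d)
    grid <- expand.grid(
      A = seq(0.5, 1.5, length.out = 20) * init[["A"]],
      k2 = seq(0.5, 1.5, length.out = 20) * init[["k2"]],
      tc = seq(0.5, 1.5, length.out = 20) * init[["tc"]])
    rss_grid <- vapply(seq_len(nrow(grid)), function(i) {
      p <- params_2d("logistic", A = grid$A[i], k2 = grid$k2[i],
                     tc = grid$tc[i])
      sum((eval_2d(p, d$t) - d$dw)^2)
    }, numeric(1))
    expect_lte(f$gof$rss, min(rss_grid))
  }
})

test_that("reported SDs shrink like 1 / sqrt(replication)", {
  # doubling the replicate count means measuring three more seedlings per
  # cell on top of the same first three, so the comparison is paired
  truth <- params_2d("logistic", A = 400, k2 = 0.5, tc = 13)
  days <- c(0, 5, 8, 10, 14, 16)
  r <- vapply(1:40, function(s) {
    set.seed(s)
    d6 <- data.frame(t = rep(days, each = 6))
    mu <- eval_2d(truth, d6$t)
    d6$dw <- mu * (1 + rnorm(nrow(d6), 0, 0.05))
    d3 <- do.call(rbind, lapply(split(d6, d6$t), utils::head, 3))
    fit_growth("logistic", d3)$coef_table$sd[1] /
      fit_growth("logistic", d6)$coef_table$sd[1]
  }, numeric(1))
  expect_gt(median(r), sqrt(2) * 0.8)
  expect_lt(median(r), sqrt(2) * 1.2)
})

test_that("cell-mean aggregation collapses replicates", {
  dat <- generate_growth(noise = noise_model(0, 0), seed = 1)
  cells <- aggregate_cells(dat)
  expect_equal(nrow(cells), 60)   # 10 levels x 6 sampling days
  expect_equal(anyDuplicated(cells[c("t", "I")]), 0)
  one <- dat[dat$I == 200 & dat$t == 16, "dw"]
  expect_equal(cells$dw[cells$I == 200 & cells$t == 16], mean(one))
})
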