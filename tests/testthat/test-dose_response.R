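test_that("predict_sigmoid has the logistic midpoint, asymptotes and values", {
  expect_equal(predict_sigmoid(-6, bottom = 0.2, top = 1.4, log_ec50 = -6),
               (0.2 + 1.4) / 2)
  expect_equal(predict_sigmoid(-300, 0.1, 2, -6), 0.1, tolerance = 1e-12)
  expect_equal(predict_sigmoid(300, 0.1, 2, -6), 2, tolerance = 1e-12)
  # plug-in arithmetic: bottom 0, top 2, logEC50 -6, x = -5 -> 2 * 10/11
  expect_equal(predict_sigmoid(-5, 0, 2, -6), 20 / 11, tolerance = 1e-15)
})

test_that("fit_sigmoid recovers noiseless parameters", {
  pts <- sigmoid_points(bottom = 0.15, top = 1.2, log_ec50 = -5.3)
  fit <- fit_sigmoid(pts)
  expect_true(fit$converged)
  expect_equal(unname(fit$params["bottom"]), 0.15, tolerance = 1e-6)
  expect_equal(unname(fit$params["top"]), 1.2, tolerance = 1e-6)
  expect_equal(unname(fit$params["log_ec50"]), -5.3, tolerance = 1e-6)
  expect_equal(fit$df, fit$n_points - 3L)
  # CIs bracket the point estimates
  free <- c("bottom", "top", "log_ec50")
  expect_true(all(fit$ci95[free, "lower"] <= fit$params[free] + 1e-9))
  expect_true(all(fit$ci95[free, "upper"] >= fit$params[free] - 1e-9))
})

test_that("fit_sigmoid recovers a noisy logEC50 within tolerance", {
  pts <- sigmoid_points(0, 1, -5, sigma = 0.02, seed = 77)
  fit <- fit_sigmoid(pts)
  expect_true(fit$converged)
  expect_lt(abs(fit$params["log_ec50"] + 5), 0.1)
})

test_that("variable-slope mode recovers a non-unit Hill coefficient", {
  pts <- sigmoid_points(0.1, 1.1, -5, hill = 1.8)
  fit <- fit_sigmoid(pts, fix_hill = NULL)
  expect_equal(unname(fit$params["hill"]), 1.8, tolerance = 1e-4)
  expect_equal(fit$df, fit$n_points - 4L)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_sigmoid(data.frame(x = c(-6, -5, -4), y = c(0, 0.5, 1))),
               "at least 4")
  expect_error(fit_sigmoid(data.frame(x = rep(-5, 6), y = rnorm(6))),
               "distinct")
})

test_that("flat data converge with overlapping CIs, never an agonist", {
  set.seed(3)
  pts <- data.frame(x = rep(dose_ladder(), each = 3),
                    y = rnorm(42, 0.3, 0.05))
  fit <- fit_sigmoid(pts)
  expect_true(fit$converged)
  call <- call_agonist(fit, list(reject = TRUE), receptor_id = "r",
                       odor_id = "o")
  expect_false(call$crit_ci_separation)
  expect_false(call$is_agonist)
})

test_that("fit objective beats a brute-force parameter grid", {
  pts <- sigmoid_points(0.2, 1.0, -5, sigma = 0.05, seed = 11,
                        x = c(-12, seq(-8, -2, 1)), reps = 2)
  fit <- fit_sigmoid(pts)
  grid <- expand.grid(bottom = seq(-0.5, 1, length.out = 50),
                      top = seq(0, 2, length.out = 50),
                      le = seq(-9, -2, length.out = 50))
  rss_grid <- vapply(seq_len(nrow(grid)), function(i) {
    sum((pts$y - predict_sigmoid(pts$x, grid$bottom[i], grid$top[i],
                                 grid$le[i]))^2)
  }, numeric(1))
  expect_lte(fit$rss, min(rss_grid) + 1e-9)
})

test_that("affine response transforms map the fit equivariantly", {
  pts <- sigmoid_points(0.1, 0.9, -5.5, sigma = 0.03, seed = 23)
  vec <- sigmoid_points(0.05, 0.05, -5.5, sigma = 0.03, seed = 24)
  fit1 <- fit_sigmoid(pts)
  t1 <- extra_ss_test(pts, vec)
  a <- 3.7; b <- -1.2
  pts2 <- transform(pts, y = a * y + b)
  vec2 <- transform(vec, y = a * y + b)
  fit2 <- fit_sigmoid(pts2)
  t2 <- extra_ss_test(pts2, vec2)
  expect_equal(unname(fit2$params["bottom"]),
               a * unname(fit1$params["bottom"]) + b, tolerance = 1e-5)
  expect_equal(unname(fit2$params["top"]),
               a * unname(fit1$params["top"]) + b, tolerance = 1e-5)
  expect_equal(unname(fit2$params["log_ec50"]),
               unname(fit1$params["log_ec50"]), tolerance = 1e-5)
  expect_equal(t2$f_stat, t1$f_stat, tolerance = 1e-5)
  c1 <- call_agonist(fit1, t1)
  c2 <- call_agonist(fit2, t2)
  expect_equal(c2[c("crit_ci_separation", "crit_ec50_sd", "crit_extra_ss",
                    "is_agonist")],
               c1[c("crit_ci_separation", "crit_ec50_sd", "crit_extra_ss",
                    "is_agonist")])
})

test_that("extra_ss_test separates receptor activation from a flat vector", {
  pts <- sigmoid_points(0, 1, -5, sigma = 0.01, seed = 31)
  vec <- sigmoid_points(0, 0, -5, sigma = 0.01, seed = 32)
  t <- extra_ss_test(pts, vec)
  expect_lt(t$p_value, 1e-10)
  expect_true(t$reject)
  expect_gt(t$span_receptor, t$span_vector)
  expect_equal(t$df_num, 3L)

  # identical duplicated data: the pooled fit nests exactly, F = 0
  t0 <- extra_ss_test(pts, pts)
  expect_lt(t0$f_stat, 1e-6)
  expect_false(t0$reject)
})

test_that("extra-SS F test is calibrated under the null", {
  set.seed(88)
  R <- 60
  ps <- vapply(seq_len(R), function(i) {
    base <- sigmoid_points(0.2, 0.2, -5, x = c(-12, seq(-8, -2, 1)), reps = 2)
    r <- transform(base, y = y + rnorm(nrow(base), 0, 0.05))
    v <- transform(base, y = y + rnorm(nrow(base), 0, 0.05))
    extra_ss_test(r, v)$p_value
  }, numeric(1))
  rate <- mean(ps < 0.05)
  # binomial band around alpha for R draws
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / R))
})

test_that("the three agonist criteria behave per their definitions", {
  pts <- sigmoid_points(0, 1, -5, sigma = 0.01, seed = 51)
  vec <- sigmoid_points(0.05, 0.05, -5, sigma = 0.01, seed = 52)
  t <- extra_ss_test(pts, vec)
  call <- call_agonist(t$fit_receptor, t, receptor_id = "1001",
                       odor_id = "3001")
  expect_true(call$crit_ci_separation)
  expect_true(call$crit_ec50_sd)
  expect_true(call$crit_extra_ss)
  expect_true(call$is_agonist)
  expect_equal(call$reported_log_ec50, -5L)

  # the logEC50 precision criterion is a strict inequality
  fit <- t$fit_receptor
  fit$se["log_ec50"] <- 1.0
  expect_false(call_agonist(fit, t)$crit_ec50_sd)
  fit$se["log_ec50"] <- 0.999
  expect_true(call_agonist(fit, t)$crit_ec50_sd)

  # unconverged fits yield a reasoned negative call
  bad <- fit
  bad$converged <- FALSE
  nocall <- call_agonist(bad, t)
  expect_false(nocall$is_agonist)
  expect_equal(nocall$reason, "fit_not_converged")
})

test_that("EC50 reporting rounds to integers, ties toward more potent", {
  expect_equal(orscreen:::.round_log_ec50(-4.9), -5L)
  expect_equal(orscreen:::.round_log_ec50(-4.2), -4L)
  expect_equal(orscreen:::.round_log_ec50(-4.5), -5L)
  expect_equal(orscreen:::.round_log_ec50(-8.5), -9L)
})

test_that("ec50_table keeps passing pairs, repeats, and joined labels", {
  calls <- tibble::tibble(
    receptor_id = c("1037", "1037", "1044"),
    odor_id = c("3001", "3001", "3002"),
    is_agonist = c(TRUE, TRUE, FALSE),
    reported_log_ec50 = c(-3L, -5L, -6L)
  )
  odors <- tibble::tibble(odor_id = c("3001", "3002"),
                          odor_name = c("lyral", "coumarin"))
  receptors <- tibble::tibble(receptor_id = c("1037", "1044"),
                              gene_label = c("OR10J5", "OR1C1"))
  tab <- ec50_table(calls, receptors, odors)
  # repeated experiments stay as separate rows; failures are dropped
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$reported_log_ec50, c(-3L, -5L))
  expect_equal(unique(tab$odor_name), "lyral")
  expect_equal(unique(tab$gene_label), "OR10J5")
  expect_equal(nrow(ec50_table(calls[calls$is_agonist == FALSE, ])), 0L)
})
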