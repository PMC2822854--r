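test_that("K = 1 fit reduces to the closed-form Gaussian MLE on log speeds", {
  set.seed(11)
  sp <- rlnorm(400, meanlog = 1.2, sdlog = 0.4)
  fit <- fit_mixture_em(sp, K = 1)
  x <- log(sp)
  expect_equal(fit$mu, mean(x), tolerance = 1e-8)
  expect_equal(fit$sigma2, var(x) * (length(x) - 1) / length(x),
               tolerance = 1e-6)
  expect_equal(fit$weights, 1)
})

test_that("EM log-likelihood is non-decreasing and zero speeds are dropped", {
  set.seed(12)
  sim <- simulate_speed_mixture(800, seed = 12)
  sp <- c(sim$speed, rep(0, 25))   # receiver null-velocity artefacts
  fit <- fit_mixture_em(sp, K = 2)
  expect_equal(fit$n_zero_dropped, 25L)
  expect_equal(fit$n_obs, 800L)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_true(all(fit$sigma2 > 0))

  expect_error(fit_mixture_em(rep(2.5, 50), K = 2), "degenerate")
  expect_error(fit_mixture_em(sim$speed, K = 0), "K")
  expect_error(fit_mixture_em(c(-1, 2, 3, 4), K = 1), "negative")
  expect_error(fit_mixture_em(c(1, 2, 3), K = 2), "at least 4")
})

test_that("EM recovers the two movement modes from synthetic speeds", {
  sim <- simulate_speed_mixture(5000, seed = 21)
  fit <- fit_mixture_em(sim$speed, K = 2)
  nat <- natural_scale_summary(fit)
  expect_equal(nat$mean[1], 0.83, tolerance = 0.05)
  expect_equal(nat$mean[2], 10.20, tolerance = 0.05)
  expect_lt(nat$mean[1], nat$mean[2])

  # independent cross-check: mclust's EM on the same log speeds
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  mc <- Mclust(log(sim$speed), G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$mu), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("classification assigns each speed to its most likely mode", {
  m <- paper_model()
  cl <- classify(m, c(0.83, 10.20, 0.9))
  expect_equal(cl$label, c("SLOW", "FAST", "SLOW"))
  expect_equal(rowSums(cl[, c("p_slow", "p_fast")]), rep(1, 3))
  expect_true(all(cl$p_slow[c(1, 3)] > 0.5))

  expect_error(classify(m, 0), "positive")
  expect_error(classify(m, -2), "positive")
})

test_that("an exact posterior tie resolves to the slow mode", {
  # symmetric construction: equal weights and variances, means 0 and 2,
  # so the posterior-equality boundary is exactly log-speed 1
  m <- speed_mixture(c(0.5, 0.5), c(0, 2), c(0.3, 0.3))
  cl <- classify(m, exp(1))
  expect_equal(cl$p_slow, 0.5)
  expect_equal(cl$label, "SLOW")
})

test_that("relabelling components leaves speed classifications unchanged", {
  p <- lognormal_params(c(0.83, 10.20), c(0.13, 27.0))
  m1 <- speed_mixture(c(0.4, 0.6), p$mu, p$sigma2)
  m2 <- speed_mixture(c(0.4, 0.6)[2:1], p$mu[2:1], p$sigma2[2:1])
  sp <- exp(seq(log(0.1), log(30), length.out = 60))
  expect_identical(classify(m1, sp)$label, classify(m2, sp)$label)
})

test_that("cluster classification skips flagged clusters and yields
          per-track mode proportions", {
  m <- paper_model()
  clusters <- data.frame(
    cluster = 1:5,
    speed = c(0.9, 11.2, NA, 0.6, 9.0),
    flagged = c(FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  out <- classify_cluster(m, clusters)
  expect_equal(out$label, c("SLOW", "FAST", NA, "SLOW", "FAST"))
  prop <- classification_proportions(out$label, m)
  expect_equal(unname(prop), c(0.5, 0.5))
  expect_equal(names(prop), c("SLOW", "FAST"))
})

test_that("natural-scale moment map matches the log-normal identities and
          inverts exactly", {
  m0 <- speed_mixture(1, 0, 1e-12)
  s0 <- natural_scale_summary(m0)
  expect_equal(s0$mean, 1, tolerance = 1e-10)
  expect_equal(s0$variance, 0, tolerance = 1e-10)

  # round trip: natural moments -> (mu, sigma2) -> natural moments
  means <- c(0.83, 10.20); vars <- c(0.13, 27.0)
  p <- lognormal_params(means, vars)
  m <- speed_mixture(c(0.5, 0.5), p$mu, p$sigma2)
  nat <- natural_scale_summary(m)
  expect_equal(nat$mean, means, tolerance = 1e-10)
  expect_equal(nat$variance, vars, tolerance = 1e-10)
})

test_that("the fitted mixture density integrates to one on both scales", {
  sim <- simulate_speed_mixture(2000, seed = 33)
  fit <- fit_mixture_em(sim$speed, K = 2)
  nat <- integrate(function(x) mixture_density(fit, x), 0, Inf,
                   rel.tol = 1e-10)
  expect_equal(nat$value, 1, tolerance = 1e-6)
  lg <- integrate(function(x) mixture_density(fit, x, scale = "log"),
                  -Inf, Inf, rel.tol = 1e-10)
  expect_equal(lg$value, 1, tolerance = 1e-6)
})

test_that("a model carried over from high-resolution data beats refitting
          on an acquisition-biased sparse sample", {
  # When fix success is behaviour-dependent, refitting the mixture on the
  # sparse biased speeds inherits both the bias and a small sample; the
  # model transferred from the near-complete high-resolution track does
  # not. Compare mode-mean errors over replicates.
  n_rep <- 100
  err_transfer <- matrix(NA_real_, n_rep, 2)
  err_refit <- matrix(NA_real_, n_rep, 2)
  truth <- c(0.83, 10.20)
  cfg <- sim_config(duration_s = 12 * 3600)
  for (r in seq_len(n_rep)) {
    hi <- simulate_two_state_track(cfg, seed = 4000 + r)
    sp_hi <- compute_speeds(hi, max_dt = 30)
    fit_hi <- fit_mixture_em(sp_hi$speed, K = 2)

    sparse <- apply_duty_cycle(hi, "BURST_2H")
    sparse <- apply_acquisition_bias(sparse, c(SLOW = 0.9, FAST = 0.5),
                                     seed = 8000 + r)
    sp_lo <- compute_speeds(sparse, max_dt = 30)
    fit_lo <- try(fit_mixture_em(sp_lo$speed, K = 2), silent = TRUE)
    if (inherits(fit_lo, "try-error")) next
    err_transfer[r, ] <- abs(natural_scale_summary(fit_hi)$mean - truth)
    err_refit[r, ] <- abs(natural_scale_summary(fit_lo)$mean - truth)
  }
  ok <- stats::complete.cases(err_transfer) & stats::complete.cases(err_refit)
  expect_gte(sum(ok), 90)
  expect_lt(mean(err_transfer[ok, 1]), mean(err_refit[ok, 1]))
  expect_lt(mean(err_transfer[ok, 2]), mean(err_refit[ok, 2]))
})
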