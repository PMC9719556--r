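test_that("a single Gaussian population is recovered", {
  x <- rmix_events(5000, 1000, 30, 1, seed = 1)
  fit <- fit_finite_mixture(x, g_min = 1, g_max = 1, seed = 1)
  expect_equal(fit$g, 1)
  expect_lt(abs(fit$components$mean - 1000) / 1000, 0.01)
  expect_true(fit$converged)
})

test_that("two well-separated populations are located within 2%", {
  x <- rmix_events(10000, c(800, 1200), c(30, 30), c(0.5, 0.5), seed = 2)
  fit <- fit_finite_mixture(x, g_min = 1, g_max = 3, seed = 1)
  comp <- fit$components
  near <- function(target) which.min(abs(comp$mean - target))
  expect_lt(abs(comp$mean[near(800)] - 800) / 800, 0.02)
  expect_lt(abs(comp$mean[near(1200)] - 1200) / 1200, 0.02)
  # summed weight on each side of the valley is close to 1/2
  left <- sum(comp$weight[comp$mean < 1000])
  expect_lt(abs(left - 0.5), 0.05)
})

test_that("fits are deterministic for identical input and seed", {
  x <- rmix_events(3000, c(900, 1100), c(35, 35), c(0.4, 0.6), seed = 3)
  f1 <- fit_finite_mixture(x, g_min = 2, g_max = 3, seed = 5)
  f2 <- fit_finite_mixture(x, g_min = 2, g_max = 3, seed = 5)
  expect_identical(f1$bic, f2$bic)
  expect_identical(f1$components, f2$components)
})

test_that("extra components never lose log-likelihood on bimodal data", {
  x <- rmix_events(4000, c(900, 1100), c(30, 30), c(0.5, 0.5), seed = 4)
  ll <- vapply(1:3, function(g) {
    fit_finite_mixture(x, g_min = g, g_max = g, seed = 1)$loglik
  }, numeric(1))
  expect_true(all(diff(ll) > -1e-6))
})

test_that("skewed populations fit better with the skew-normal family", {
  # build right-skewed events from the skew-normal stochastic representation
  set.seed(9)
  n <- 4000; delta <- 5 / sqrt(26)
  x <- 1000 + 40 * (delta * abs(rnorm(n)) + sqrt(1 - delta^2) * rnorm(n))
  fsn <- fit_finite_mixture(x, g_min = 1, g_max = 1, seed = 1)
  fn <- fit_finite_mixture(x, g_min = 1, g_max = 1, family = "normal", seed = 1)
  expect_lt(fsn$bic, fn$bic)
  expect_gt(fsn$components$alpha, 1)
})

test_that("normal-family EM agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  x <- rmix_events(4000, c(850, 1150), c(40, 50), c(0.35, 0.65), seed = 6)
  ours <- fit_finite_mixture(x, g_min = 2, g_max = 2, family = "normal", seed = 1)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(ours$components$mean), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.01)
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-3)
})

test_that("too few events or constant events are rejected", {
  expect_error(fit_finite_mixture(rnorm(150, 1000, 10)), ">= 200")
  expect_error(fit_finite_mixture(rep(1000, 500)), "constant")
})

test_that("components merge into classes and background is excluded", {
  fit <- structure(list(
    components = tibble::tibble(
      component = 1:4,
      weight = c(0.3, 0.25, 0.35, 0.1),
      xi = c(990, 1008, 1195, 400), omega = c(20, 20, 25, 150),
      alpha = c(0, 0, 0, 0), mean = c(995, 1005, 1200, 400)),
    g = 4, family = "skew_normal", loglik = 0, bic = 0, converged = TRUE,
    n_events = 1000, events = numeric(0), all_bic = numeric(0)),
    class = "ise_mixture")

  est <- assign_components_to_classes(fit, c(1000, 1200), window = 0.05)
  cls0 <- est[!is.na(est$class_k) & est$class_k == 0, ]
  expect_equal(cls0$proportion, 0.55)
  expect_equal(cls0$mean_fluorescence,
               (0.3 * 995 + 0.25 * 1005) / 0.55)
  expect_equal(sort(cls0$member_components[[1]]), 1:2)
  bg <- est[est$is_background, ]
  expect_equal(bg$proportion, 0.1)

  norm <- renormalize_classes(est)
  expect_equal(sum(norm$proportion), 1)
  expect_equal(norm$proportion, c(0.55, 0.35) / 0.9)

  # unresolvable class spacing errors out
  expect_error(assign_components_to_classes(fit, c(1000, 1050), window = 0.05),
               "not resolvable")
  # all-background input cannot be renormalised
  allbg <- est[est$is_background, ]
  expect_error(renormalize_classes(allbg), "background")
})

test_that("an unmatched class keeps a zero-proportion row", {
  fit <- structure(list(
    components = tibble::tibble(component = 1L, weight = 1, xi = 1000,
                                omega = 20, alpha = 0, mean = 1000),
    g = 1, family = "skew_normal", loglik = 0, bic = 0, converged = TRUE,
    n_events = 1000, events = numeric(0), all_bic = numeric(0)),
    class = "ise_mixture")
  est <- assign_components_to_classes(fit, c(1000, 1400))
  expect_equal(est$proportion[est$class_k == 1 & !is.na(est$class_k)], 0)
})

test_that("peak CV computation flags samples above the cutoff", {
  lo <- rnorm(5000, 1000, 20)
  hi <- rnorm(5000, 1000, 40)
  withr::with_seed(10, {
    q_lo <- qc_cv(lo, peak = 1000)
    q_hi <- qc_cv(hi, peak = 1000)
  })
  expect_equal(q_lo$cv_percent, 2, tolerance = 0.1)
  expect_false(q_lo$excluded)
  expect_equal(q_hi$cv_percent, 4, tolerance = 0.15)
  expect_true(q_hi$excluded)
  expect_equal(qc_cv(c(rep(1000, 200)), peak = 1000)$cv_percent, 0)
  expect_error(qc_cv(rnorm(50, 1000, 10), peak = 1000), ">= 100")
})

test_that("synthetic three-class samples are decomposed close to truth", {
  # classes at 0.25/0.5/0.25 through the full mixture path
  ky <- test_karyotype(2, ise_mb = 40)
  cfg <- sim_config(ky, tb = 0, cb = 0, n_males = 5e4, n_events = 4000,
                    cv_percent = 2, seed = 21)
  sim <- simulate_clone_sample(cfg)
  dec <- decompose_sample(sim$sample, ky, seed = 1)
  expect_equal(nrow(dec$classes), 3)
  expect_true(all(abs(dec$classes$proportion - c(0.25, 0.5, 0.25)) < 0.03))
})

test_that("class proportions are recovered across the observed CV range", {
  # several seeds spanning instrument noise levels; median error under 0.05
  cases <- list(
    list(n = 2, cv = 1.7, seed = 31), list(n = 3, cv = 2.5, seed = 32),
    list(n = 2, cv = 3.2, seed = 33), list(n = 4, cv = 3.9, seed = 34))
  errs <- vapply(cases, function(cs) {
    ky <- test_karyotype(cs$n, ise_mb = 45)
    cfg <- sim_config(ky, tb = 0.1, cb = -0.2, n_males = 5e4, n_events = 3500,
                      cv_percent = cs$cv, seed = cs$seed)
    sim <- simulate_clone_sample(cfg)
    dec <- decompose_sample(sim$sample, ky, seed = 1)
    truth <- sim$counts$count / sum(sim$counts$count)
    max(abs(dec$classes$proportion - truth))
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("female peak is located from the event density alone", {
  ky <- test_karyotype(1, ise_mb = 60)
  cfg <- sim_config(ky, n_males = 1000, n_events = 4000, cv_percent = 2.5,
                    seed = 44)
  sim <- simulate_clone_sample(cfg)
  est <- estimate_female_peak(sim$sample)
  expect_lt(abs(est - 1e5) / 1e5, 0.03)
})

test_that("mixture accessors and plots work", {
  x <- rmix_events(2000, c(900, 1100), c(30, 30), c(0.5, 0.5), seed = 8)
  fit <- fit_finite_mixture(x, g_min = 2, g_max = 2, seed = 1)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$g, 2)
  expect_s3_class(autoplot(fit), "ggplot")
})
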