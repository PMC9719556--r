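test_that("rmse follows its definition and symmetry", {
  expect_equal(class_rmse(c(0.25, 0.5, 0.25), c(0.25, 0.5, 0.25)), 0)
  expect_equal(class_rmse(c(0.25, 0.5, 0.25), c(0.175, 0.65, 0.175)),
               sqrt((0.075^2 + 0.15^2 + 0.075^2) / 3))
  # invariant under a common permutation of the classes
  p <- c(0.1, 0.6, 0.3); o <- c(0.2, 0.5, 0.3)
  expect_equal(class_rmse(p, o), class_rmse(p[c(3, 1, 2)], o[c(3, 1, 2)]))
  expect_error(class_rmse(c(0.5, 0.5), c(1, 0, 0)), "differ")
})

test_that("grid fit recovers generating parameters exactly on grid points", {
  fit <- grid_fit(class_distribution(3, tb = 0.15, cb = -0.35))
  expect_equal(fit$best_tb, 0.15)
  expect_equal(fit$best_cb, -0.35)
  expect_equal(fit$best_rmse, 0, tolerance = 1e-12)

  # null data land on the origin via the parsimony tie-break
  fit0 <- grid_fit(unbiased_distribution(4))
  expect_equal(fit0$best_tb, 0)
  expect_equal(fit0$best_cb, 0)
  expect_equal(fit0$best_rmse, 0, tolerance = 1e-12)

  # sampled grid points across n
  set.seed(42)
  grid_vals <- seq(-0.95, 0.95, by = 0.05)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    tb <- sample(grid_vals, 1); cb <- sample(grid_vals, 1)
    f <- grid_fit(class_distribution(n, tb = tb, cb = cb))
    expect_equal(c(f$best_tb, f$best_cb), c(tb, cb))
    expect_lt(f$best_rmse, 1e-12)
  }
})

test_that("grid surface covers the full parameter box", {
  fit <- grid_fit(class_distribution(2, tb = 0.1, cb = 0.1), grid_step = 0.05)
  expect_equal(nrow(fit$surface), (1.9 / 0.05 + 1)^2)
  expect_equal(range(fit$surface$tb), c(-0.95, 0.95))
  expect_equal(range(fit$surface$cb), c(-0.95, 0.95))
  expect_equal(min(fit$surface$rmse), fit$best_rmse)
  # coarser grid
  fit2 <- grid_fit(class_distribution(2, tb = 0.1, cb = 0.1), grid_step = 0.1)
  expect_equal(nrow(fit2$surface), 20^2)
})

test_that("cosegregation bias is reported as unidentifiable for one ISE", {
  fit <- grid_fit(class_distribution(1, tb = 0.2))
  expect_equal(fit$best_tb, 0.2)
  expect_true(is.na(fit$best_cb))
  expect_false("cb" %in% names(fit$surface))
})

test_that("unnormalised input is rejected", {
  expect_error(grid_fit(c(0.5, 0.6, 0.2)), "sum to 1")
})

test_that("parameters are recovered from finite multinomial samples", {
  truth <- class_distribution(4, tb = 0.1, cb = -0.4)
  counts <- withr::with_seed(7, rmultinom(1, 5e4, truth$frequency)[, 1])
  fit <- grid_fit(counts / sum(counts))
  expect_lte(abs(fit$best_tb - 0.1), 0.05 + 1e-9)
  expect_lte(abs(fit$best_cb + 0.4), 0.05 + 1e-9)
})

test_that("estimation error shrinks as the male sample grows", {
  err <- function(n_males, seed) {
    truth <- class_distribution(3, tb = 0.15, cb = -0.35)
    counts <- withr::with_seed(seed, rmultinom(1, n_males, truth$frequency)[, 1])
    fit <- grid_fit(counts / sum(counts))
    abs(fit$best_tb - 0.15) + abs(fit$best_cb + 0.35)
  }
  seeds <- 1:25
  small <- vapply(seeds, function(s) err(1e3, s), numeric(1))
  large <- vapply(seeds, function(s) err(1e5, s), numeric(1))
  expect_lte(median(large), median(small))
  expect_lte(median(large), 0.05 + 1e-9)
})

test_that("fit_many fits each clone and recovers clusters", {
  # singleton matches grid_fit
  d1 <- class_distribution(2, tb = 0.1, cb = -0.2)
  tab1 <- fit_many(dplyr::mutate(d1, clone_id = "a"))
  expect_equal(nrow(tab1), 1)
  expect_equal(tab1$best_tb, 0.1)
  expect_equal(tab1$best_cb, -0.2)

  # 11 inbred-like clones simulated at one parameter pair cluster there
  obs <- purrr::map_dfr(1:11, function(i) {
    sim <- simulate_segregation(3, seg_params(0.15, -0.35),
                                n_males = 5e4, seed = 500 + i)
    tibble::tibble(clone_id = paste0("inbred", i), class_k = sim$class_k,
                   frequency = sim$count / sum(sim$count))
  })
  fits <- fit_many(obs)
  expect_equal(nrow(fits), 11)
  expect_true(all(abs(fits$best_tb - 0.15) <= 0.05 + 1e-9))
  expect_true(all(abs(fits$best_cb + 0.35) <= 0.05 + 1e-9))

  # two generating parameter pairs give two recovered clusters
  obs2 <- purrr::map_dfr(1:6, function(i) {
    p <- if (i <= 3) seg_params(0.15, -0.35) else seg_params(-0.1, 0)
    sim <- simulate_segregation(3, p, n_males = 5e4, seed = 900 + i)
    tibble::tibble(clone_id = paste0("c", i), class_k = sim$class_k,
                   frequency = sim$count / sum(sim$count))
  })
  fits2 <- fit_many(obs2)
  expect_true(all(fits2$best_tb[1:3] > 0.05))
  expect_true(all(fits2$best_tb[4:6] < 0.05))
  expect_true(all(fits2$best_cb[1:3] < -0.2))
  expect_true(all(abs(fits2$best_cb[4:6]) <= 0.1))

  expect_error(fit_many(dplyr::bind_rows(
    dplyr::mutate(d1, clone_id = "a"), dplyr::mutate(d1, clone_id = "a"))),
    "duplicated")
})

test_that("tidy, glance and autoplot work on fits", {
  fit <- grid_fit(class_distribution(2, tb = 0.1, cb = -0.2))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(names(glance(fit)),
               c("n_ise", "best_tb", "best_cb", "best_rmse", "grid_step", "n_grid"))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(grid_fit(class_distribution(1, tb = 0.2))), "ggplot")
})
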