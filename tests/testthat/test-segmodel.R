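test_that("outcome weights follow the pairwise multiplicative law", {
  expect_equal(outcome_weight("egg", seg_params(tb = 0.1)), 1.1)
  expect_equal(outcome_weight(c("egg", "egg"), seg_params(cb = -0.3)), 0.7)
  expect_equal(outcome_weight(c("egg", "polar"), seg_params()), 1)
  # three ISEs: marginals times all three pair factors
  expect_equal(
    outcome_weight(c("egg", "egg", "polar"), seg_params(tb = 0.2, cb = 0.1)),
    1.2 * 1.2 * 0.8 * 1.1 * 0.9 * 0.9)
  # empty outcome has unit weight
  expect_equal(outcome_weight(character(0), seg_params(tb = 0.5, cb = 0.5)), 1)
})

test_that("degenerate parameters are rejected with a clear message", {
  expect_error(seg_params(tb = 1), "Degenerate")
  expect_error(seg_params(cb = -1), "Degenerate")
  expect_error(class_distribution(2, tb = 1), "Degenerate")
})

test_that("class distribution reproduces the published worked examples", {
  expect_equal(class_distribution(1, tb = 0.1)$frequency, c(0.45, 0.55))
  expect_equal(class_distribution(2)$frequency, c(0.25, 0.5, 0.25))
  expect_equal(class_distribution(2, tb = 0, cb = -0.3)$frequency,
               c(0.175, 0.650, 0.175))
  expect_equal(class_distribution(3)$frequency, dbinom(0:3, 3, 0.5))
})

test_that("class distribution equals brute-force enumeration of outcome weights", {
  cases <- expand.grid(n = 1:6, tb = c(-0.6, 0, 0.25), cb = c(-0.5, 0, 0.4))
  for (i in seq_len(nrow(cases))) {
    p <- seg_params(cases$tb[i], cases$cb[i])
    expect_equal(class_distribution(cases$n[i], p)$frequency,
                 enumerate_class_freqs(cases$n[i], p), tolerance = 1e-12)
  }
})

test_that("frequencies are normalised and obey the model symmetries", {
  grid <- expand.grid(tb = seq(-0.9, 0.9, by = 0.3),
                      cb = seq(-0.9, 0.9, by = 0.3), n = c(1, 3, 5, 8))
  for (i in seq_len(nrow(grid))) {
    f <- class_distribution(grid$n[i], tb = grid$tb[i], cb = grid$cb[i])$frequency
    expect_gte(min(f), 0)
    expect_equal(sum(f), 1, tolerance = 1e-12)
  }
  # tb = 0: symmetric in k <-> n - k
  for (cb in c(-0.7, 0.2)) {
    f <- class_distribution(5, tb = 0, cb = cb)$frequency
    expect_equal(f, rev(f), tolerance = 1e-12)
  }
})

test_that("cb = 0 collapses to Binomial(n, (1 + tb)/2)", {
  for (n in 0:8) {
    for (tb in c(-0.8, -0.1, 0, 0.3, 0.9)) {
      expect_equal(class_distribution(n, tb = tb)$frequency,
                   dbinom(0:n, n, (1 + tb) / 2), tolerance = 1e-12)
    }
  }
})

test_that("mean transmitted ISEs increases with tb; cb -> -1 empties extremes", {
  means <- vapply(seq(-0.9, 0.9, by = 0.1), function(tb) {
    f <- class_distribution(4, tb = tb)$frequency
    sum((0:4) * f)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # n = 2, tb = 0: as cb -> -1 the single-ISE class takes all the mass,
  # the regular-chromosome limit
  f <- class_distribution(2, tb = 0, cb = -0.999)$frequency
  expect_gt(f[2], 0.999)
})

test_that("negative cb depresses extreme classes and raises an intermediate one", {
  for (n in 2:5) {
    oe <- oe_ratios(class_distribution(n, tb = 0, cb = -0.4),
                    unbiased_distribution(n))$oe_ratio
    expect_lt(oe[1], 1)
    expect_lt(oe[n + 1], 1)
    expect_gt(max(oe[2:n]), 1)
  }
})

test_that("unbiased distribution is Binomial(n, 0.5)", {
  expect_equal(unbiased_distribution(0)$frequency, 1)
  expect_equal(unbiased_distribution(2)$frequency, c(0.25, 0.5, 0.25))
  expect_equal(unbiased_distribution(4)$frequency,
               c(0.0625, 0.25, 0.375, 0.25, 0.0625))
})

test_that("O/E ratios match the published cosegregation example", {
  oe <- oe_ratios(class_distribution(2, tb = 0, cb = -0.3),
                  unbiased_distribution(2))
  expect_equal(oe$oe_ratio, c(0.7, 1.3, 0.7))
  # identity and the two-class transmission example
  expect_equal(oe_ratios(c(0.3, 0.7), c(0.3, 0.7))$oe_ratio, c(1, 1))
  expect_equal(oe_ratios(c(0.54, 0.46), c(0.5, 0.5))$oe_ratio, c(1.08, 0.92))
  # zero expected mass is flagged, not divided
  oe0 <- oe_ratios(c(0.5, 0.5, 0), c(0.5, 0.5, 0))
  expect_true(oe0$undefined[3])
  expect_true(is.na(oe0$oe_ratio[3]))
  expect_error(oe_ratios(c(0.5, 0.5), c(0.25, 0.5, 0.25)), "same classes")
})

test_that("Monte-Carlo simulator is deterministic and matches enumeration", {
  a <- simulate_segregation(3, seg_params(0.15, -0.35), n_males = 2000, seed = 11)
  b <- simulate_segregation(3, seg_params(0.15, -0.35), n_males = 2000, seed = 11)
  expect_identical(a, b)
  expect_equal(sum(a$count), 2000)

  set.seed(303)
  for (rep in 1:8) {
    n <- sample(1:6, 1)
    p <- seg_params(runif(1, -0.8, 0.8), runif(1, -0.8, 0.8))
    sim <- simulate_segregation(n, p, n_males = 1e5, seed = 1000 + rep)
    truth <- class_distribution(n, p)$frequency
    se <- sqrt(truth * (1 - truth) / 1e5)
    expect_true(all(abs(sim$count / 1e5 - truth) <= 4 * pmax(se, 1e-12)))
  }
})

test_that("enumeration cap directs users to the Monte-Carlo path", {
  expect_error(class_distribution(13), "simulate_segregation")
})

test_that("male genome sizes follow the carried-ISE arithmetic", {
  ky <- ise_karyotype(n_ise = 2, core_1c_mb = 200, ise_sizes_mb = c(20, 30))
  expect_equal(ky$female_2c_mb, 450)
  gs <- male_genome_size(ky)
  expect_equal(gs$absolute_mb[1], 200)
  expect_equal(gs$relative_gs[1], 200 / 450)
  expect_true(all(diff(gs$relative_gs) > 0))
  # explicit subset: carrying only the 30 Mb element
  gs1 <- male_genome_size(ky, k = 1, carried = 2)
  expect_equal(gs1$absolute_mb, 230)
  expect_equal(gs1$relative_gs, 230 / 450)
  expect_error(male_genome_size(ky, k = 1, carried = c(1, 2)), "length")
  # uniform-size fallback from total genome sizes only
  ky2 <- ise_karyotype(n_ise = 4, core_1c_mb = 183, female_2c_mb = 506)
  expect_equal(male_genome_size(ky2)$absolute_mb,
               183 + (506 - 366) / 4 * (0:4))
  # ISE-free clone: male at exactly half the female signal
  ky0 <- ise_karyotype(n_ise = 0, core_1c_mb = 200, female_2c_mb = 400)
  expect_equal(male_genome_size(ky0)$relative_gs, 0.5)
})

test_that("karyotype accounting identity is enforced", {
  expect_error(ise_karyotype(2, core_1c_mb = 200, female_2c_mb = 500,
                             ise_sizes_mb = c(20, 30)), "!=")
  expect_error(ise_karyotype(2, core_1c_mb = 200), "at least two")
  expect_error(ise_karyotype(2, core_1c_mb = 200, ise_sizes_mb = c(20, -3)),
               "positive")
})
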