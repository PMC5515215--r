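# Half-life estimation under zero- and first-order kinetics, adsorption
# partitioning, Holm-Sidak comparisons and the chain-length trend.

test_that("noiseless lines and exponentials are recovered exactly", {
  lin <- tibble::tibble(time_h = 0:4, concentration = 10 - 2 * (0:4))
  f0 <- fit_zero_order(lin)
  expect_equal(f0$rate_k, 2, tolerance = 1e-10)
  expect_equal(f0$c0_hat, 10, tolerance = 1e-10)
  expect_equal(f0$half_life, 2.5, tolerance = 1e-10)
  expect_equal(f0$r_squared, 1, tolerance = 1e-9)
  # half-life identity
  expect_equal(f0$half_life, f0$c0_hat / (2 * f0$rate_k))

  expo <- tibble::tibble(time_h = 0:5,
                         concentration = 5 * exp(-0.6931472 * (0:5)))
  f1 <- fit_first_order(expo)
  expect_equal(f1$half_life, 1, tolerance = 1e-3)
  expect_equal(f1$r_squared, 1, tolerance = 1e-9)
  expect_equal(f1$half_life, log(2) / f1$rate_k)
})

test_that("fits refuse degenerate series with a reason", {
  too_short <- tibble::tibble(time_h = 0:1, concentration = c(5, 4))
  expect_equal(fit_zero_order(too_short)$status, "failed")
  flat <- tibble::tibble(time_h = 0:4, concentration = rep(3, 5))
  expect_equal(fit_first_order(flat)$status, "failed")
  rising <- tibble::tibble(time_h = 0:4, concentration = c(1, 2, 3, 4, 5))
  expect_equal(fit_zero_order(rising)$status, "non_degrading")
  mostly_zero <- tibble::tibble(time_h = 0:5,
                                concentration = c(5, 1, 0, 0, 0, 0))
  expect_equal(fit_first_order(mostly_zero)$status, "failed")
  expect_match(fit_first_order(mostly_zero)$reason, "zero tail")
})

test_that("select_model prefers the matching order and breaks ties first-order", {
  expo <- tibble::tibble(time_h = seq(0, 5, 0.5),
                         concentration = 4 * exp(-0.8 * seq(0, 5, 0.5)))
  f0 <- fit_zero_order(expo)
  f1 <- fit_first_order(expo)
  expect_lt(f0$r_squared, f1$r_squared)
  expect_equal(select_model(f0, f1)$order, 1)

  lin <- tibble::tibble(time_h = seq(0, 2, 0.25),
                        concentration = 10 - 3 * seq(0, 2, 0.25))
  expect_equal(select_model(fit_zero_order(lin), fit_first_order(lin))$order, 0)

  # equal r-squared within tolerance goes first-order by rule
  fa <- fit_zero_order(lin); fb <- fit_first_order(expo)
  fa$r_squared <- 0.95; fb$r_squared <- 0.95 + 1e-8
  expect_equal(select_model(fa, fb)$order, 1)
  fb$r_squared <- 0.95
  expect_equal(select_model(fa, fb)$order, 1)
})

test_that("regression agrees with the brute-force SSE oracle on noisy series", {
  withr::local_seed(7)
  for (i in 1:20) {
    k <- runif(1, 0.2, 1.5)
    c0 <- runif(1, 2, 8)
    t <- seq(0, 6, length.out = 8)
    conc <- c0 * exp(-k * t) * exp(rnorm(8, 0, 0.1))
    d <- tibble::tibble(time_h = t, concentration = conc)
    fit <- fit_first_order(d)
    oracle <- oracle_first_order_sse(t, conc)
    expect_equal(fit$rate_k, oracle$k, tolerance = 0.01)
    expect_equal(fit$c0_hat, oracle$c0, tolerance = 0.01)
  }
})

test_that("first-order half-life recovery has < 5% mean bias at CV 10%", {
  true_hl <- 1.4
  k <- log(2) / true_hl
  est <- vapply(1:200, function(s) {
    d <- gen_decay("X", order = 1, rate_constant = k,
                   adsorption_fraction = 0, noise_cv = 0.1, seed = 400 + s)
    fit_first_order(d[d$condition == "live", ])$half_life
  }, numeric(1))
  expect_lt(abs(mean(est) - true_hl) / true_hl, 0.05)
})

test_that("zero-order half-life recovery is unbiased within 5% at CV 10%", {
  est <- vapply(1:100, function(s) {
    d <- gen_decay("X", order = 0, rate_constant = 0.4, c0 = 5,
                   adsorption_fraction = 0, noise_cv = 0.1,
                   timepoints = seq(0, 6, length.out = 8), seed = 900 + s)
    fit_zero_order(d[d$condition == "live", ])$half_life
  }, numeric(1))
  expect_lt(abs(mean(est) - 5 / (2 * 0.4)) / (5 / (2 * 0.4)), 0.05)
})

test_that("adsorption_fraction compares controls at 0 and 1 h", {
  sww <- tibble::tibble(time_h = c(0, 1, 2), concentration = c(5, 5, 5))
  heat <- tibble::tibble(time_h = c(0, 1, 2), concentration = 0.8 * c(5, 5, 5))
  expect_equal(adsorption_fraction(sww, heat)$fraction, 0.2, tolerance = 1e-12)
  expect_equal(adsorption_fraction(sww, sww)$fraction, 0)
  # noise can push heat above sww: clamped to 0 with a warning
  heat_hi <- tibble::tibble(time_h = c(0, 1), concentration = c(5.5, 5.4))
  expect_warning(res <- adsorption_fraction(sww, heat_hi), "clamped")
  expect_equal(res$fraction, 0)
  no1h <- tibble::tibble(time_h = c(0, 2), concentration = c(5, 5))
  expect_error(adsorption_fraction(sww, no1h), "1 h")
})

test_that("correct_adsorption rescales only post-zero points", {
  d <- tibble::tibble(time_h = c(0, 1, 2), concentration = c(5, 2, 1))
  out <- correct_adsorption(d, 0.2)
  expect_equal(out$concentration, c(5, 2.5, 1.25))
})

test_that("Holm-Sidak adjustment matches hand computation and is monotone", {
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04),
               tolerance = 1e-12)
  withr::local_seed(31)
  for (i in 1:20) {
    p <- runif(8)
    adj <- holm_sidak(p)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj <= 1))
  }
})

test_that("compare_half_lives separates clearly different groups and handles ties", {
  set.seed(5)
  data <- tidyr::expand_grid(
    ahl = c("C6-HSL", "3OC6-HSL", "C12-HSL"),
    group = c("live", "heat"),
    rep = 1:4
  ) |>
    dplyr::mutate(half_life = ifelse(group == "live",
                                     rnorm(dplyr::n(), 2, 0.1),
                                     rnorm(dplyr::n(), 12, 0.5)))
  res <- compare_half_lives(data)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_adj < 0.05))

  same <- tibble::tibble(
    ahl = "X", group = rep(c("a", "b"), each = 3),
    half_life = rep(2, 6)
  )
  expect_equal(compare_half_lives(same)$p_raw, 1)

  unrepl <- dplyr::bind_rows(
    same,
    tibble::tibble(ahl = "Y", group = c("a", "b"), half_life = c(1, 2))
  )
  expect_message(out <- compare_half_lives(unrepl), "excluding")
  expect_equal(out$ahl, "X")
})

test_that("chain_length_trend flags the inverse half-life trend", {
  fits <- tibble::tibble(
    ahl = c("C6-HSL", "C8-HSL", "C12-HSL",
            "3OC6-HSL", "3OC8-HSL", "3OC12-HSL"),
    half_life = c(1.95, 1.4, 0.79, 2.57, 1.7, 0.66)
  )
  trend <- chain_length_trend(fits)
  expect_equal(nrow(trend), 2)
  expect_true(all(trend$spearman_rho == -1))
  expect_true(all(trend$inverse_trend))

  # shuffled half-lives show no systematic trend on average
  rhos <- vapply(1:50, function(s) {
    shuffled <- fits
    shuffled$half_life <- withr::with_seed(s, sample(fits$half_life))
    mean(chain_length_trend(shuffled)$spearman_rho, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.3)

  small <- fits[1:2, ]
  expect_message(out <- chain_length_trend(small), "skipping")
  expect_equal(nrow(out), 0)
})
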