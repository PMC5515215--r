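# The generators must honour their noise models exactly in the noiseless
# limit, be bit-reproducible under a fixed seed, and plant ground truth
# consistent with the downstream analysis rules.

test_that("gen_reads plants extractable tags and honours the filter truth", {
  tag <- withr::with_seed(11, random_tag())
  plan <- tibble::tibble(taxon_id = "tA", tag_sequence = tag, n_reads = 5)
  sim <- gen_reads(plan, seed = 1)

  expect_equal(nrow(sim$reads), 5)
  raw <- extract_v6_tags(sim$reads)
  support <- tag_support(raw)
  expect_equal(support$tag_sequence, tag)
  expect_equal(support$total_reads, 5L)

  # a single-read plan is marked removed by the >= 2-read rule
  single <- gen_reads(
    tibble::tibble(taxon_id = "tB", tag_sequence = tag, n_reads = 1),
    seed = 2
  )
  expect_false(single$truth$expect_kept)
  expect_match(single$truth$removal_reason, "2-read")
})

test_that("gen_reads is byte-identical under a fixed seed", {
  plans <- tibble::tibble(
    taxon_id = sprintf("t%02d", 1:10),
    tag_sequence = withr::with_seed(7, replicate(10, random_tag())),
    n_reads = 5:14,
    per_base_error_rate = 0.01
  )
  a <- gen_reads(plans, seed = 7)
  b <- gen_reads(plans, seed = 7)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(a$reads, f1)
  write_reads_fastq(b$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the FASTQ round-trips through the reader
  expect_equal(read_reads(f1)$sequence, a$reads$sequence)
})

test_that("gen_reads rejects invalid plans", {
  expect_error(gen_reads(tibble::tibble(
    taxon_id = "x", tag_sequence = "ACGT", n_reads = 2), seed = 1),
    "33-nt")
  expect_error(gen_reads(tibble::tibble(
    taxon_id = "x", tag_sequence = withr::with_seed(1, random_tag()),
    n_reads = 2, per_base_error_rate = 0.6), seed = 1),
    "0.5")
})

test_that("gen_decay matches the closed-form decay laws when noiseless", {
  d <- gen_decay("C6-HSL", order = 1, rate_constant = log(2), c0 = 5,
                 adsorption_fraction = 0, noise_cv = 0,
                 timepoints = 0:6, seed = 1)
  live <- d[d$condition == "live", ]
  expect_equal(live$concentration, 5 * 2^(-(0:6)), tolerance = 1e-12)
  sww <- d[d$condition == "sww_control", ]
  expect_equal(sww$concentration, rep(5, 7))

  # heat-inactivated series shows only the instantaneous adsorptive drop
  d2 <- gen_decay("C6-HSL", order = 1, rate_constant = 1, c0 = 5,
                  adsorption_fraction = 0.2, noise_cv = 0,
                  timepoints = 0:4, seed = 1)
  heat <- d2[d2$condition == "heat_inactivated", ]
  expect_equal(heat$concentration, rep(0.8 * 5, 5))

  # zero-order law, truncated at 0
  d3 <- gen_decay("C6-HSL", order = 0, rate_constant = 2, c0 = 5,
                  adsorption_fraction = 0, noise_cv = 0,
                  timepoints = 0:4, seed = 1)
  expect_equal(d3$concentration[d3$condition == "live"],
               pmax(0, 5 - 2 * (0:4)))
})

test_that("gen_decay is seed-reproducible and validates input", {
  a <- gen_decay("X", 1, 0.5, noise_cv = 0.2, seed = 9)
  b <- gen_decay("X", 1, 0.5, noise_cv = 0.2, seed = 9)
  expect_identical(a, b)
  expect_error(gen_decay("X", 1, 0.5, timepoints = numeric(0)), "non-empty")
  expect_error(gen_decay("X", 1, 0.5, timepoints = c(1, 2)), "start at 0")
  expect_error(gen_decay("X", 2, 0.5), "order")
  expect_error(gen_decay("X", 1, -1), "rate_constant")
})

test_that("gen_calibration draws the stated line and spans the working range", {
  cal <- gen_calibration(slope = 2, intercept = 1, noise_sd = 0, seed = 1)
  expect_equal(cal$area, 1 + 2 * cal$level_ugL)
  expect_equal(range(cal$level_ugL), c(0.5, 200))
  expect_equal(cal$area[cal$level_ugL == 10], 21)
  # least-squares refit recovers the generating line exactly
  m <- lm(area ~ level_ugL, data = cal)
  expect_equal(unname(coef(m)), c(1, 2), tolerance = 1e-10)
  expect_error(gen_calibration(slope = -1), "slope")
  expect_error(gen_calibration(slope = 1, levels = c(0.1, 5)), "range")
})

test_that("gen_community_series plants exact correlations in the no-noise limit", {
  signs <- matrix(0, 4, 2)
  signs[1, 1] <- 1
  signs[2, 2] <- -1
  cs <- gen_community_series(4, 20, 2, signs, effect_size = 1,
                             noise_sd = 0, seed = 5)
  pm <- pearson_matrix(cs$taxa, cs$ahls)
  expect_equal(pm$r[1, 1], 1, tolerance = 1e-12)
  expect_equal(pm$r[2, 2], -1, tolerance = 1e-12)
  expect_identical(cs, gen_community_series(4, 20, 2, signs, effect_size = 1,
                                            noise_sd = 0, seed = 5))
  expect_error(gen_community_series(4, 2, 2), "at least 3")
  expect_error(gen_community_series(4, 10, 2, matrix(2, 4, 2)), "entries")
})

test_that("planted negative correlations are recovered near the target effect size", {
  signs <- matrix(c(-1, 0), nrow = 2, ncol = 1)
  r_hat <- vapply(1:100, function(s) {
    cs <- gen_community_series(2, 50, 1, signs, effect_size = 0.9, seed = s)
    pearson_matrix(cs$taxa, cs$ahls)$r[1, 1]
  }, numeric(1))
  expect_lt(abs(mean(r_hat) - (-0.9)), 0.1)
})

test_that("an all-zero sign matrix behaves as a complete null under BH", {
  frac_sig <- vapply(1:60, function(s) {
    cs <- gen_community_series(8, 20, 3, seed = s)
    co <- correlate_community(cs$taxa, cs$ahls, alpha = 0.05)
    mean(co$q < 0.05)
  }, numeric(1))
  expect_lte(mean(frac_sig), 0.05)
})

test_that("gen_isolates honours degenerate and planted mixtures", {
  none <- gen_isolates(25, proportions = c(0, 0, 0, 1), seed = 3)
  expect_true(all(none$truth$category == "neither"))
  ph <- classify_isolate(none$assays)
  expect_true(all(ph$category == "neither"))

  expect_identical(gen_isolates(50, seed = 4), gen_isolates(50, seed = 4))
  expect_error(gen_isolates(10, proportions = c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")

  # default proportions reproduce the panel mixture within multinomial error
  iso <- gen_isolates(330, seed = 11)
  counts <- table(factor(iso$truth$category,
                         levels = c("producer", "quencher", "both", "neither")))
  expected <- 330 * c(0.052, 0.533, 0.048, 0.367)
  # 4 sd of a binomial count per category
  tol <- 4 * sqrt(expected * (1 - expected / 330))
  expect_true(all(abs(as.numeric(counts) - expected) <= tol))
})
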