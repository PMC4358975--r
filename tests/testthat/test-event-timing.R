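test_that("multiplicity assignment follows the VAF lattice", {
  aa <- allelic_state(2, 0)
  expect_equal(assign_multiplicity(100, 100, aa, 0), 2)
  expect_equal(assign_multiplicity(50, 100, aa, 0), 1)
  aabb <- allelic_state(2, 2)
  expect_equal(assign_multiplicity(26, 105, aabb, 0), 1)
  expect_equal(assign_multiplicity(52, 105, aabb, 0), 2)
  # contamination shifts the lattice: VAF 0.46 is still multiplicity 1
  ab <- allelic_state(1, 1)
  expect_equal(assign_multiplicity(46, 100, ab, 0.08), 1)
})

test_that("timing estimators are exact on expected counts over a time grid", {
  for (t in seq(0.05, 0.95, by = 0.05)) {
    lamL <- 1000
    expect_equal(time_event("cn_loh_dup", lamL * t, 2 * lamL * (1 - t)), t,
                 tolerance = 1e-12)
    expect_equal(time_event("wgd", 2 * lamL * t, 4 * lamL * (1 - t)), t,
                 tolerance = 1e-12)
    expect_equal(time_event("trisomy_gain", lamL * t,
                            lamL * t + 3 * lamL * (1 - t)), t,
                 tolerance = 1e-12)
  }
})

test_that("timing estimator matches a brute-force generative oracle", {
  # simulate the mutation-accumulation process directly: per-copy Poisson
  # arrivals before/after the event, independent of the package generator
  set.seed(41)
  lamL <- 1000
  for (t_true in c(0.25, 2 / 3)) {
    n2 <- rpois(1, 2 * lamL * t_true)       # WGD: both copies duplicated
    n1 <- rpois(1, 4 * lamL * (1 - t_true))
    expect_lt(abs(time_event("wgd", n2, n1) - t_true), 0.05)
    n2 <- rpois(1, lamL * t_true)           # trisomy
    n1 <- rpois(1, lamL * t_true + 3 * lamL * (1 - t_true))
    expect_lt(abs(time_event("trisomy_gain", n2, n1) - t_true), 0.05)
  }
  expect_equal(time_event("wgd", 100, 100), 2 / 3)
})

test_that("boundary and untimeable cases behave", {
  expect_equal(time_event("cn_loh_dup", 0, 50), 0)
  expect_equal(time_event("cn_loh_dup", 50, 0), 1)
  expect_warning(t <- time_event("cn_loh_dup", 0, 0), "untimeable")
  expect_true(is.na(t))
  expect_warning(t <- time_event("loss", 10, 10), "untimeable")
  expect_true(is.na(t))
})

test_that("bootstrap intervals cover the estimate and shrink with counts", {
  ci <- bootstrap_ci("wgd", 500, 500, seed = 42)
  expect_true(ci[1] <= 2 / 3 && 2 / 3 <= ci[2])
  expect_lt(diff(ci), 0.1)
  ci_small <- bootstrap_ci("wgd", 50, 50, seed = 42)
  expect_lt(diff(ci), diff(ci_small))
  ci0 <- bootstrap_ci("cn_loh_dup", 0, 40, seed = 42)
  expect_equal(ci0[1], 0)
  expect_gte(ci0[2], 0)
})

test_that("mutation intervals respect multiplicity and event class", {
  expect_equal(mutation_interval(2, "cn_loh_dup", 0.26), c(0, 0.26))
  expect_equal(mutation_interval(1, "cn_loh_dup", 0.26), c(0.26, 1))
  expect_equal(mutation_interval(2, "gain", 0.21), c(0, 0.21))
  expect_equal(mutation_interval(1, "trisomy_gain", 0.21), c(0, 1))
  expect_equal(mutation_interval(1, "none"), c(0, 1))
})

test_that("segment-level timing recovers simulated event times", {
  events <- list(list(chrom = "chr11", class = "cn_loh_dup", t = 0.3),
                 list(chrom = "chr8", class = "trisomy_gain", t = 0.5),
                 list(chrom = "chr3", class = "wgd", t = 0.7))
  # lambda * L >= 500 per chromosome at this scale
  sim <- simulate_tumor(test_config(seed = 404, alpha = 0.1, events = events,
                                    lambda_rate = 60, het_density = 0.05))
  segs <- sim$segments
  corr <- correct_allelic_cn(segs$cn_obs, segs$laf_obs, 0.1)
  for (ev in events) {
    i <- which(segs$chrom == ev$chrom)
    on_seg <- sim$mutations$chrom == ev$chrom
    timed <- time_segment(sim$mutations[on_seg, ], corr$cn_t[i],
                          corr$laf_t[i], alpha = 0.1, seed = 9)
    expect_equal(timed$event_class, ev$class)
    expect_lt(abs(timed$t - ev$t), 0.05)
    expect_true(timed$ci[1] <= timed$t && timed$t <= timed$ci[2])
  }
})

test_that("WGD is detected and timed concordantly; two-event histories flagged", {
  cfg <- sim_config(seed = 55, alpha = 0.16, lambda_rate = 10,
                    genome = sim_genome(scale = 0.1), het_density = 0.05,
                    events = list(list(chrom = "genome", class = "wgd",
                                       t = 0.62)))
  sim <- simulate_tumor(cfg)
  w <- detect_wgd(sim$segments, sim$mutations, alpha = 0.16)
  expect_true(w$wgd)
  expect_lt(abs(w$t_mean - 0.62), 0.05)
  expect_lt(w$concordance, 0.05)

  # two independent half-genome tetrasomies at 0.3 and 0.8: still called,
  # but the per-chromosome times disagree
  chroms <- sim_genome(scale = 0.1)$chrom
  ev2 <- c(lapply(chroms[1:11], function(ch)
             list(chrom = ch, class = "wgd", t = 0.3)),
           lapply(chroms[12:22], function(ch)
             list(chrom = ch, class = "wgd", t = 0.8)))
  sim2 <- simulate_tumor(sim_config(seed = 56, alpha = 0.16,
                                    lambda_rate = 10,
                                    genome = sim_genome(scale = 0.1),
                                    het_density = 0.05, events = ev2))
  w2 <- detect_wgd(sim2$segments, sim2$mutations, alpha = 0.16)
  expect_true(w2$wgd)
  expect_gt(w2$concordance, 0.2)

  # pure diploid: no call
  fx <- simulate_tumor(test_config(seed = 57, alpha = 0))
  w0 <- detect_wgd(fx$segments, fx$mutations, alpha = 0)
  expect_false(w0$wgd)
})

test_that("fusion junction coverage orders the fusion against WGD", {
  expect_equal(as.character(fusion_duplication_test(52, 105, wgd = TRUE)),
               "before_wgd")
  expect_equal(as.character(fusion_duplication_test(26, 105, wgd = TRUE)),
               "after_wgd")
  expect_equal(fusion_duplication_test(52, 105, wgd = FALSE), "indeterminate")
  expect_equal(fusion_duplication_test(52, 0, wgd = TRUE), "indeterminate")
})

test_that("rate consistency is high for proportional counts and breaks with an outlier", {
  len <- sim_genome()$length_mb
  counts <- len * 1.4
  rc <- rate_consistency(counts, len)
  expect_equal(rc$r_squared, 1, tolerance = 1e-9)
  expect_equal(rc$rate_per_mb, 1.4, tolerance = 1e-9)
  counts10 <- counts
  counts10[22] <- counts10[22] * 10
  expect_lt(rate_consistency(counts10, len)$r_squared, 0.9)
  expect_error(rate_consistency(1:3, 1:3))
})
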