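test_that("simulator is deterministic under a fixed seed", {
  cfg <- test_config(seed = 61, alpha = 0.1,
                     events = list(list(chrom = "chr11", class = "cn_loh_dup",
                                        t = 0.3)))
  s1 <- simulate_tumor(cfg)
  s2 <- simulate_tumor(cfg)
  expect_identical(s1$mutations, s2$mutations)
  expect_identical(s1$het_sites, s2$het_sites)
  expect_identical(s1$segments, s2$segments)
})

test_that("config validation rejects inconsistent histories", {
  expect_error(test_config(seed = 1, alpha = 0, events = list(
    list(chrom = "chr1", class = "cn_loh_dup", t = 0.2),
    list(chrom = "chr1", class = "gain", t = 0.5))),
    "more than one event")
  expect_error(sim_config(events = list(
    list(chrom = "genome", class = "gain", t = 0.5))),
    "wgd")
  expect_error(sim_config(subclones = list(list(
    branch_time = 0.9, fraction = 0.3,
    events = list(list(chrom = "chr1", class = "gain")))),
    events = list(list(chrom = "chr1", class = "loss", t = 0.5))),
    "conflicts")
})

test_that("a null diploid genome clusters at VAF 0.5 with LAF 0.5", {
  sim <- simulate_tumor(test_config(seed = 62, alpha = 0, lambda_rate = 30))
  expect_lt(abs(mean(sim$mutations$vaf_obs) - 0.5), 0.01)
  # the folded per-site LAF estimator is biased slightly below 0.5 on
  # balanced segments at ~100x depth (about -0.04); allow for it
  expect_lt(abs(mean(sim$segments$laf_obs) - 0.5), 0.05)
  expect_lt(abs(mean(sim$segments$cn_obs) - 2), 0.05)
})

test_that("WGD multiplicity ratio matches the generative algebra", {
  # at t = 0.5 the expected multiplicity-2 : multiplicity-1 ratio is
  # 2*lambda*t : 4*lambda*(1-t) = 1 : 2
  sim <- simulate_tumor(test_config(
    seed = 63, alpha = 0, lambda_rate = 120, het_density = 0.02,
    events = list(list(chrom = "genome", class = "wgd", t = 0.5))))
  tt <- sim$truth$mutation_truth
  ratio <- sum(tt$multiplicity == 2) / sum(tt$multiplicity == 1)
  expect_equal(ratio, 0.5, tolerance = 0.05)
})

test_that("observed VAF means track the forward model per stratum", {
  sim <- simulate_tumor(test_config(
    seed = 64, alpha = 0.16, lambda_rate = 60,
    events = list(list(chrom = "chr11", class = "cn_loh_dup", t = 0.4))))
  tt <- merge(sim$mutations, sim$truth$mutation_truth[, c("id", "multiplicity",
                                                          "vaf_expected")])
  for (grp in split(tt, paste(tt$chrom == "chr11", tt$multiplicity))) {
    if (nrow(grp) < 30) next
    se <- sqrt(grp$vaf_expected[1] * (1 - grp$vaf_expected[1]) /
                 (105 * nrow(grp)))
    expect_lt(abs(mean(grp$vaf_obs) - grp$vaf_expected[1]), 3 * se + 1e-3)
  }
  # diploid het-somatic VAF mean under 16% contamination: (1-0.16)/2 = 0.42
  dip <- tt[tt$chrom != "chr11", ]
  expect_equal(mean(dip$vaf_obs), 0.42, tolerance = 0.01)
})

test_that("named fixtures exercise the expected genome configurations", {
  dir <- tempfile("fix")
  null <- make_fixture("null_diploid", dir = dir)
  muts <- read_mutations(null$paths$mutations)
  segs <- read_segments(null$paths$segments)
  expect_gt(nrow(muts), 100)
  w <- detect_wgd(segs, muts, alpha = 0)
  expect_false(w$wgd)

  pfp <- make_fixture("pfp_like", dir = dir)
  w <- detect_wgd(read_segments(pfp$paths$segments),
                  read_mutations(pfp$paths$mutations), alpha = 0.16)
  expect_true(w$wgd)
  expect_lt(abs(w$t_mean - 0.62), 0.1)
  expect_equal(
    as.character(fusion_duplication_test(
      pfp$sim$truth$fusion$junction_reads,
      pfp$sim$truth$fusion$local_depth, wgd = w$wgd)),
    "before_wgd")

  pfn <- make_fixture("pfn_like", dir = dir)
  truth <- pfn$sim$truth$events
  timed <- truth[truth$event_class != "none", ]
  expect_equal(timed$chrom[which.min(timed$t)], "chr8")  # trisomy 8 at 0.08
  expect_true(all(c("chr11", "chr9") %in%
                  timed$chrom[timed$event_class == "cn_loh_dup" &
                              timed$t == 0.14]))
  expect_error(make_fixture("unknown"), "arg")
})

test_that("fixture files round-trip through the package readers", {
  dir <- tempfile("fix")
  fx <- make_fixture("pfn_like", dir = dir)
  muts <- read_mutations(fx$paths$mutations)
  expect_equal(nrow(muts), nrow(fx$sim$mutations))
  expect_equal(muts$vaf_obs, fx$sim$mutations$vaf_obs, tolerance = 1e-9)
  hets <- read_het_sites(fx$paths$het_sites)
  expect_equal(nrow(hets), nrow(fx$sim$het_sites))
  truth <- read_report(fx$paths$truth)
  expect_equal(truth$alpha, 0.12)
})
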