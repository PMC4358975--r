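test_that("allelic states validate and expose LAF", {
  st <- allelic_state(2, 1)
  expect_equal(st$label, "AAB")
  expect_equal(st$laf, 1 / 3)
  expect_equal(allelic_state(0, 0)$laf, 0)
  expect_error(allelic_state(1, 2), "n_minor")
})

test_that("segment LAF estimation is exact on noiseless counts", {
  balanced <- data.frame(ref_count = rep(50L, 20), alt_count = rep(50L, 20))
  expect_equal(estimate_laf(balanced), 0.5)
  loh <- data.frame(ref_count = rep(80L, 20), alt_count = rep(0L, 20))
  expect_equal(estimate_laf(loh), 0)
  few <- data.frame(ref_count = 50L, alt_count = 50L)
  expect_warning(laf <- estimate_laf(few), "insufficient")
  expect_true(is.na(laf))
})

test_that("segment LAF recovers 1/3 for a simulated AAB segment at depth 105", {
  set.seed(11)
  n <- 500
  d <- pmax(rpois(n, 105), 1L)
  # alt allele on the duplicated lineage for half the sites
  p <- ifelse(runif(n) < 0.5, 1 / 3, 2 / 3)
  a <- rbinom(n, d, p)
  laf <- estimate_laf(data.frame(ref_count = d - a, alt_count = a))
  expect_lt(abs(laf - 1 / 3), 0.02)
})

test_that("LAF estimate is symmetric under allele relabeling and bounded", {
  set.seed(12)
  d <- pmax(rpois(200, 105), 1L)
  a <- rbinom(200, d, 0.4)
  laf1 <- estimate_laf(data.frame(ref_count = d - a, alt_count = a))
  laf2 <- estimate_laf(data.frame(ref_count = a, alt_count = d - a))
  expect_equal(laf1, laf2)
  expect_true(laf1 >= 0 && laf1 <= 0.5)
})

test_that("nearest integer state agrees with exhaustive search", {
  lattice <- expand.grid(n_minor = 0:4, n_major = 0:8)
  lattice <- lattice[lattice$n_major >= lattice$n_minor &
                     lattice$n_major + lattice$n_minor <= 8, ]
  brute <- function(cn, laf) {
    tot <- lattice$n_major + lattice$n_minor
    lf <- ifelse(tot == 0, 0, lattice$n_minor / tot)
    d <- sqrt((cn - tot)^2 + (laf - lf)^2)
    i <- order(d, tot, -lattice$n_minor)[1]
    list(label = paste0(strrep("A", lattice$n_major[i]),
                        strrep("B", lattice$n_minor[i])),
         distance = d[i])
  }
  set.seed(3)
  for (i in 1:100) {
    cn <- runif(1, 0, 8.5)
    laf <- runif(1, 0, 0.5)
    got <- nearest_integer_state(cn, laf)
    want <- brute(cn, laf)
    expect_equal(got$state$label, want$label)
    expect_equal(got$distance, want$distance, tolerance = 1e-12)
  }
  expect_equal(nearest_integer_state(2, 0.5)$state$label, "AB")
  expect_equal(nearest_integer_state(2, 0)$state$label, "AA")
  expect_equal(nearest_integer_state(3.02, 0.33)$state$label, "AAB")
})

test_that("subclonal CNA detection solves the mixing equations", {
  clonal <- detect_subclonal_cna(2.0, 0.5)
  expect_equal(clonal$verdict, "clonal")
  expect_equal(clonal$state_major$label, "AB")

  mix <- detect_subclonal_cna(2.5, 0.4)
  expect_equal(mix$verdict, "subclonal")
  expect_setequal(c(mix$state_major$label, mix$state_minor$label),
                  c("AB", "AAB"))
  expect_equal(mix$phi, 0.5, tolerance = 1e-9)
  expect_lt(mix$residual, 1e-9)
})

test_that("subclone fraction is recovered across phi 0.2-0.5 at depth 105", {
  set.seed(21)
  for (phi in c(0.2, 0.3, 0.4, 0.5)) {
    # 30%-style trisomy subclone on a diploid background, 500 het sites
    n <- 500
    d <- pmax(rpois(n, 105), 1L)
    cmix <- 2 + phi
    p <- ifelse(runif(n) < 0.5, 1, 1 + phi) / cmix
    a <- rbinom(n, d, p)
    laf <- estimate_laf(data.frame(ref_count = d - a, alt_count = a))
    call <- detect_subclonal_cna(cmix, laf)
    expect_equal(call$verdict, "subclonal")
    expect_lt(abs(call$phi - phi), 0.05)
  }
})

test_that("table-level CNA calling flags only the subclonal segment", {
  segs <- data.frame(chrom = c("chr1", "chr8"), start = 0L,
                     end = c(1000000L, 1000000L), length_mb = 1,
                     cn_obs = c(2.0, 2.3), laf_obs = c(0.5, 1 / 2.3))
  calls <- call_subclonal_cna(segs, alpha = 0)
  expect_equal(calls$verdict, c("clonal", "subclonal"))
  expect_equal(calls$phi[2], 0.3, tolerance = 1e-6)
})
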