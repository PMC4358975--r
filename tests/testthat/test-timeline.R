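pfn_example_events <- function() {
  data.frame(
    label = c("cn_loh_dup:chr11", "cn_loh_dup:chr5", "trisomy_gain:chr13",
              "trisomy_gain:chr20"),
    chrom = c("chr11", "chr5", "chr13", "chr20"),
    event_class = c("cn_loh_dup", "cn_loh_dup", "trisomy_gain",
                    "trisomy_gain"),
    t = c(0.14, 0.26, 0.77, 0.98),
    stringsAsFactors = FALSE
  )
}

test_that("trunk orders events by molecular time with deterministic ties", {
  ev <- pfn_example_events()[c(3, 1, 4, 2), ]  # shuffled input
  tl <- build_timeline(events = ev)
  expect_equal(tl$trunk$label,
               c("cn_loh_dup:chr11", "cn_loh_dup:chr5", "trisomy_gain:chr13",
                 "trisomy_gain:chr20"))
  expect_true(all(diff(tl$trunk$time) >= 0))
  # event conservation
  expect_equal(nrow(tl$trunk), nrow(ev))
})

test_that("mutations enter the trunk at their interval midpoint", {
  mt <- data.frame(id = c("FGFR4_V550L", "late_mut"), multiplicity = c(2, 1),
                   t_lo = c(0, 0.5), t_hi = c(0.26, 1))
  tl <- build_timeline(events = pfn_example_events(), mutation_timings = mt)
  fg <- tl$trunk[tl$trunk$item == "FGFR4_V550L", ]
  expect_equal(fg$time, 0.13)
  expect_equal(tl$trunk$item[1], "FGFR4_V550L")  # 0.13 precedes chr11 at 0.14
})

test_that("no events still yields a one-clone tree; serialization is deterministic", {
  mt <- data.frame(id = "m1", multiplicity = 1, t_lo = 0, t_hi = 1)
  tl <- build_timeline(mutation_timings = mt)
  expect_equal(nrow(tl$trunk), 1)
  expect_length(tl$branches, 0)
  tl2 <- build_timeline(mutation_timings = mt)
  expect_identical(jsonlite::toJSON(unclass(tl), auto_unbox = TRUE, digits = NA),
                   jsonlite::toJSON(unclass(tl2), auto_unbox = TRUE, digits = NA))
})

test_that("conflicting subclone fractions split into sibling branches", {
  sc <- data.frame(label = c("cna:chr8", "cna:chr13"), phi = c(0.2, 0.45))
  expect_warning(tl <- build_timeline(events = pfn_example_events(),
                                      subclone_calls = sc),
                 "sibling branches")
  expect_length(tl$branches, 2)
  sc1 <- data.frame(label = c("cna:chr8", "cna:chr13"), phi = c(0.30, 0.32))
  tl1 <- build_timeline(events = pfn_example_events(), subclone_calls = sc1)
  expect_length(tl1$branches, 1)
  expect_equal(tl1$branches[[1]]$phi, 0.31)
})

test_that("newick serialization is valid and carries molecular-time lengths", {
  skip_if_not_installed("ape")
  sc <- data.frame(label = "cna:chr8", phi = 0.3)
  tl <- build_timeline(events = pfn_example_events(), subclone_calls = sc)
  nwk <- as_newick(tl)
  tree <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(tree), 2)
  expect_equal(sort(tree$tip.label),
               sort(c("dominant", "subclone_1_phi0.30")))
  # tips extend from the last trunk event (0.98) to biopsy time 1
  expect_equal(unname(tree$edge.length), rep(1 - 0.98, 2), tolerance = 1e-6)
})

test_that("cohort summary places lesions at their inferred times", {
  tl1 <- build_timeline(events = pfn_example_events())
  m <- cohort_summary(list(tumor_A = tl1))
  expect_equal(ncol(m), 1)
  expect_equal(m["cn_loh_dup:chr11", "tumor_A"], 0.14)

  # a mutation interval [0, 0.26] is summarized at its median, 0.13
  mt <- data.frame(id = "FGFR4", multiplicity = 2, t_lo = 0, t_hi = 0.26)
  tl2 <- build_timeline(events = pfn_example_events(), mutation_timings = mt)
  m2 <- cohort_summary(list(tumor_A = tl1, tumor_B = tl2))
  expect_equal(m2["FGFR4", "tumor_B"], 0.13)
  expect_true(is.na(m2["FGFR4", "tumor_A"]))

  # shared early event across tumors keeps its time in every column
  trees <- lapply(1:10, function(i) build_timeline(events = data.frame(
    label = "cn_loh_dup:chr11", chrom = "chr11",
    event_class = "cn_loh_dup", t = 0.2)))
  mm <- cohort_summary(trees)
  expect_equal(unname(stats::median(mm["cn_loh_dup:chr11", ])), 0.2)
})
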