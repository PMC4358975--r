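#' Assign mutation multiplicity on a segment with a known allelic state
#'
#' The multiplicity of a somatic mutation is the number of tumor chromosome
#' copies carrying it. On a segment with allelic state `state`, a mutation
#' can occupy `m = 1 .. n_major` copies (it arose on one parental lineage),
#' and each `m` predicts a distinct observed VAF via [expected_obs_vaf()].
#' The maximum-posterior multiplicity under a binomial read-count likelihood
#' (flat prior over m) is returned; ties go to the smaller `m`.
#'
#' @param alt_count,depth Tumor alt read count(s) and total depth(s);
#'   vectorized.
#' @param state An [allelic_state()] for the segment.
#' @param alpha Normal-cell contamination fraction.
#' @return Integer multiplicity vector.
#' @examples
#' st <- allelic_state(2, 0)            # uniparental disomy AA
#' assign_multiplicity(100, 100, st, 0) # 2: mutation predates the duplication
#' assign_multiplicity(50, 100, st, 0)  # 1: mutation postdates it
#' @export
assign_multiplicity <- function(alt_count, depth, state, alpha = 0) {
  stopifnot(inherits(state, "allelic_state"), state$n_major >= 1)
  m_grid <- seq_len(state$n_major)
  v_exp <- vapply(m_grid, function(m)
    expected_obs_vaf(alpha, state$total, m, 1), numeric(1))
  ll <- vapply(m_grid, function(j)
    stats::dbinom(alt_count, depth, v_exp[j], log = TRUE),
    numeric(length(alt_count)))
  ll <- matrix(ll, ncol = length(m_grid))
  m_grid[apply(ll, 1, which.max)]  # which.max takes the first: smaller m wins ties
}

#' Molecular time of a copy-number event from multiplicity counts
#'
#' Under a constant per-copy mutation accumulation rate, mutations acquired
#' before a duplication-type event are carried on every duplicated copy
#' (multiplicity 2) while later mutations sit on a single copy
#' (multiplicity 1). The ratio of the two cluster sizes therefore encodes
#' the event's position in molecular time `t` (fraction of the tumor's
#' mutational lifetime elapsed when the event occurred). With `N2`, `N1` the
#' multiplicity-2 and multiplicity-1 counts and rate `lambda` on a segment of
#' length `L`:
#'
#' * copy-neutral LOH + duplication (AB to AA): `E[N2] = lambda L t`,
#'   `E[N1] = 2 lambda L (1 - t)`, so `t = 2 N2 / (2 N2 + N1)`;
#' * whole-genome/segmental tetrasomy (AB to AABB): `E[N2] = 2 lambda L t`,
#'   `E[N1] = 4 lambda L (1 - t)`, same estimator `t = 2 N2 / (2 N2 + N1)`;
#' * trisomy gain (AB to AAB): `E[N2] = lambda L t`,
#'   `E[N1] = lambda L t + 3 lambda L (1 - t)`, so `t = 3 r / (1 + 2 r)` with
#'   `r = N2 / N1`.
#'
#' Estimates are clipped to `[0, 1]`. Pure losses leave no multiplicity-2
#' record and are untimeable, as are segments with no mutations.
#'
#' @param event_class One of `"cn_loh_dup"`, `"wgd"`, `"trisomy_gain"`,
#'   `"gain"` (alias of trisomy gain), `"loss"`.
#' @param n2 Count of multiplicity-2 (pre-event) mutations.
#' @param n1 Count of multiplicity-1 (post-event) mutations.
#' @return Estimated molecular time in `[0, 1]`, or `NA_real_` with a
#'   warning when the event is untimeable.
#' @examples
#' time_event("wgd", 100, 100)       # 2/3
#' time_event("cn_loh_dup", 0, 250)  # 0: event at origin
#' @export
time_event <- function(event_class, n2, n1) {
  event_class <- match.arg(event_class,
                           c("cn_loh_dup", "wgd", "trisomy_gain", "gain", "loss"))
  stopifnot(n2 >= 0, n1 >= 0)
  if (event_class == "loss") {
    warning("untimeable: pure losses leave no multiplicity-2 mutations")
    return(NA_real_)
  }
  if (n2 + n1 == 0) {
    warning("untimeable: no mutations on the segment")
    return(NA_real_)
  }
  t <- switch(event_class,
    cn_loh_dup = ,
    wgd = 2 * n2 / (2 * n2 + n1),
    trisomy_gain = ,
    gain = {
      if (n1 == 0) 1 else {
        r <- n2 / n1
        3 * r / (1 + 2 * r)
      }
    }
  )
  min(max(t, 0), 1)
}

#' Bootstrap confidence interval for an event time
#'
#' Percentile interval from multinomial resampling of the multiplicity
#' counts: `(N2, N1)` are resampled with their observed proportions at the
#' observed total, the timing estimator is re-applied, and the percentile
#' interval of the resampled times is returned.
#'
#' @inheritParams time_event
#' @param resamples Number of bootstrap resamples (default 200).
#' @param seed RNG seed.
#' @param conf Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(event_class, n2, n1, resamples = 200L, seed = 1L,
                         conf = 0.95) {
  stopifnot(n2 + n1 > 0)
  .with_seed(seed, {
    draws <- stats::rmultinom(resamples, size = n2 + n1,
                              prob = c(n2, n1) / (n2 + n1))
    ts <- suppressWarnings(vapply(seq_len(resamples), function(i)
      time_event(event_class, draws[1, i], draws[2, i]), numeric(1)))
    a <- (1 - conf) / 2
    as.numeric(stats::quantile(ts, c(a, 1 - a), na.rm = TRUE))
  })
}

#' Molecular-time interval for a single mutation
#'
#' A timed copy-number event splits molecular time for mutations on its
#' segment: a multiplicity-2 mutation must predate the duplication
#' (`[0, t]`); a multiplicity-1 mutation on a duplicated segment (CN-LOH or
#' tetrasomy) must postdate it (`[t, 1]`). On a trisomic segment a
#' multiplicity-1 mutation is uninformative (`[0, 1]`): it may postdate the
#' gain or predate it on the unduplicated allele. Mutations on unaltered
#' segments get `[0, 1]`.
#'
#' @param multiplicity Assigned mutation multiplicity (integer >= 1).
#' @param event_class Event class of the segment's timed event, or `"none"`.
#' @param t Molecular time of the event (ignored for `"none"`).
#' @return Numeric `c(t_lo, t_hi)` within `[0, 1]`.
#' @examples
#' mutation_interval(2, "cn_loh_dup", 0.26)  # [0, 0.26]
#' mutation_interval(1, "cn_loh_dup", 0.26)  # [0.26, 1]
#' @export
mutation_interval <- function(multiplicity, event_class = "none", t = NA_real_) {
  event_class <- match.arg(event_class,
                           c("none", "cn_loh_dup", "wgd", "trisomy_gain",
                             "gain", "loss"))
  stopifnot(multiplicity >= 1)
  if (event_class %in% c("none", "loss") || is.na(t)) return(c(0, 1))
  if (multiplicity >= 2) return(c(0, t))
  if (event_class %in% c("cn_loh_dup", "wgd")) c(t, 1) else c(0, 1)
}

# Drop mutations whose corrected VAF sits more than `threshold` below the
# single-copy clonal expectation: subclonal mutations postdate every clonal
# event and must not enter the multiplicity counts used for timing.
.drop_subclonal <- function(mutations, n_t, alpha, threshold = 0.10) {
  depth <- mutations$ref_count + mutations$alt_count
  v_corr <- suppressWarnings(
    as.numeric(correct_vaf(mutations$alt_count / depth, alpha, n_t)))
  mutations[!flag_subclonal(v_corr, 1 / n_t, threshold), , drop = FALSE]
}

# Map an integer allelic state reached from diploid AB by one event to the
# event class used by the timing estimators; NA when no single-event history
# or no event explains the state.
classify_event <- function(state) {
  stopifnot(inherits(state, "allelic_state"))
  key <- paste(state$n_major, state$n_minor)
  switch(key,
    "1 1" = "none",
    "2 0" = "cn_loh_dup",
    "2 1" = "trisomy_gain",
    "2 2" = "wgd",
    "1 0" = "loss",
    NA_character_
  )
}

#' Time the copy-number event on one segment
#'
#' End-to-end timing for one segment: assigns the integer allelic state from
#' the corrected copy number and LAF, classifies the single event that
#' produced it from diploid AB, assigns multiplicities to the segment's
#' mutations, and applies the closed-form timing estimator with a bootstrap
#' interval. States requiring two or more sequential events (e.g. AAAB,
#' hexasomy) are reported as `"complex"` and left untimed.
#'
#' Mutations flagged subclonal (corrected VAF more than
#' `subclonal_threshold` below the single-copy clonal expectation, see
#' [flag_subclonal()]) are excluded from the multiplicity counts: timing
#' reads the clonal mutation record, and subclonal mutations postdate the
#' clonal events by definition but would otherwise inflate the
#' multiplicity-1 count.
#'
#' @param mutations Mutation table rows lying on the segment (columns
#'   `ref_count`, `alt_count`).
#' @param cn_t,laf_t Purity-corrected segment copy number and LAF.
#' @param alpha Normal-cell contamination fraction.
#' @param subclonal_threshold Exclusion threshold on the corrected-VAF
#'   deficit (default 0.10).
#' @param resamples,seed Bootstrap parameters (see [bootstrap_ci()]).
#' @return A list of class `cn_event`: `state` ([allelic_state()]),
#'   `event_class`, `t`, `ci`, `n_by_multiplicity` (named count vector) and
#'   `multiplicities` (per-mutation assignments).
#' @export
time_segment <- function(mutations, cn_t, laf_t, alpha = 0,
                         subclonal_threshold = 0.10,
                         resamples = 200L, seed = 1L) {
  st <- nearest_integer_state(cn_t, laf_t)$state
  cls <- classify_event(st)
  out <- list(state = st, event_class = cls, t = NA_real_,
              ci = c(NA_real_, NA_real_), n_by_multiplicity = integer(0),
              multiplicities = integer(0))
  class(out) <- "cn_event"
  if (is.na(cls)) {
    out$event_class <- "complex"
    return(out)
  }
  if (nrow(mutations) > 0 && st$n_major >= 1) {
    mutations <- .drop_subclonal(mutations, st$total, alpha,
                                 subclonal_threshold)
  }
  if (nrow(mutations) > 0 && st$n_major >= 1) {
    m <- assign_multiplicity(mutations$alt_count,
                             mutations$ref_count + mutations$alt_count,
                             st, alpha)
    out$multiplicities <- m
    out$n_by_multiplicity <- table(factor(m, levels = seq_len(st$n_major)))
  }
  if (cls %in% c("cn_loh_dup", "wgd", "trisomy_gain")) {
    n2 <- sum(out$multiplicities == 2)
    n1 <- sum(out$multiplicities == 1)
    if (n1 + n2 > 0) {
      out$t <- time_event(cls, n2, n1)
      out$ci <- bootstrap_ci(cls, n2, n1, resamples = resamples, seed = seed)
    }
  }
  out
}

#' @export
print.cn_event <- function(x, ...) {
  cat(sprintf("<cn_event %s (%s): t = %s, 95%% CI [%s, %s]>\n",
              x$state$label, x$event_class,
              ifelse(is.na(x$t), "untimed", sprintf("%.3f", x$t)),
              sprintf("%.3f", x$ci[1]), sprintf("%.3f", x$ci[2])))
  invisible(x)
}

#' Detect and time whole-genome duplication
#'
#' Calls a whole-genome duplication (WGD) when at least `min_genome_frac` of
#' the autosomal genome, by length, is consistent with the balanced
#' tetraploid state AABB after purity correction (LAF near 0.5, copy number
#' near 4, somatic VAF bimodal at 0.5/0.25 through the multiplicity
#' lattice). Each consistent chromosome is timed independently with the
#' tetrasomy estimator; a single genome-wide duplication event predicts
#' concordant per-chromosome times, so their standard deviation is reported
#' as a concordance diagnostic (large values flag multi-event histories).
#'
#' @param segments Segment table ([read_segments()] columns plus `laf_obs`).
#' @param mutations Mutation table ([read_mutations()] columns).
#' @param alpha Normal-cell contamination fraction.
#' @param min_genome_frac Length fraction of autosomes that must be
#'   AABB-consistent to call WGD (default 0.5).
#' @param seed Bootstrap seed passed through to per-chromosome timing.
#' @return List with `wgd` (logical call), `genome_frac_tetraploid`,
#'   `t_by_chrom` (named vector), `t_mean`, and `concordance`
#'   (SD of per-chromosome times; NA with < 2 timed chromosomes).
#' @export
detect_wgd <- function(segments, mutations, alpha = 0, min_genome_frac = 0.5,
                       seed = 1L) {
  auto <- segments[!.is_sex_chrom(segments$chrom) & !is.na(segments$laf_obs), ,
                   drop = FALSE]
  if (nrow(auto) == 0) stop("no autosomal segments with LAF available")
  corr <- correct_allelic_cn(auto$cn_obs, auto$laf_obs, alpha)
  states <- lapply(seq_len(nrow(auto)), function(i)
    nearest_integer_state(corr$cn_t[i], corr$laf_t[i])$state)
  is_aabb <- vapply(states, function(s)
    s$n_major == 2L && s$n_minor == 2L, logical(1))
  frac <- sum(auto$length_mb[is_aabb]) / sum(auto$length_mb)
  called <- frac >= min_genome_frac

  t_by_chrom <- numeric(0)
  if (any(is_aabb)) {
    tet <- auto[is_aabb, , drop = FALSE]
    st <- allelic_state(2, 2)
    ts <- vapply(unique(tet$chrom), function(ch) {
      rows <- tet[tet$chrom == ch, , drop = FALSE]
      on_seg <- mutations$chrom == ch &
        mutations$pos >= min(rows$start) & mutations$pos < max(rows$end)
      mu <- mutations[on_seg, , drop = FALSE]
      mu <- .drop_subclonal(mu, st$total, alpha)
      if (nrow(mu) == 0) return(NA_real_)
      m <- assign_multiplicity(mu$alt_count, mu$ref_count + mu$alt_count,
                               st, alpha)
      n2 <- sum(m == 2); n1 <- sum(m == 1)
      if (n1 + n2 == 0) return(NA_real_)
      time_event("wgd", n2, n1)
    }, numeric(1))
    t_by_chrom <- ts[!is.na(ts)]
  }
  list(
    wgd = called,
    genome_frac_tetraploid = frac,
    t_by_chrom = t_by_chrom,
    t_mean = if (length(t_by_chrom)) mean(t_by_chrom) else NA_real_,
    concordance = if (length(t_by_chrom) > 1) stats::sd(t_by_chrom) else NA_real_
  )
}

#' Order a fusion junction relative to whole-genome duplication
#'
#' In a tetraploid (post-WGD) genome, a rearrangement junction formed before
#' the duplication sits on 2 of the 4 copies and is covered at about half the
#' local depth, while a junction formed afterwards sits on a single copy and
#' is covered at about a quarter. The junction read count is compared under
#' binomial likelihoods at those two expectations; classification requires a
#' likelihood ratio of at least `lr_min`, otherwise the order is
#' indeterminate. Without a WGD call the test does not apply.
#'
#' @param junction_reads Reads spanning the fusion junction.
#' @param local_depth Mean sequencing coverage around the junction.
#' @param wgd Whether the genome carries a WGD (from [detect_wgd()]).
#' @param lr_min Minimum likelihood ratio to classify (default 3).
#' @return `"before_wgd"`, `"after_wgd"` or `"indeterminate"`, with the log
#'   likelihood ratio (before vs after) as attribute `"llr"`.
#' @examples
#' fusion_duplication_test(52, 105, wgd = TRUE)  # before_wgd
#' fusion_duplication_test(26, 105, wgd = TRUE)  # after_wgd
#' @export
fusion_duplication_test <- function(junction_reads, local_depth, wgd,
                                    lr_min = 3) {
  if (!isTRUE(wgd) || local_depth <= 0) return("indeterminate")
  n <- round(local_depth)
  ll_before <- stats::dbinom(min(junction_reads, n), n, 2 / 4, log = TRUE)
  ll_after <- stats::dbinom(min(junction_reads, n), n, 1 / 4, log = TRUE)
  llr <- ll_before - ll_after
  verdict <- if (abs(llr) < log(lr_min)) "indeterminate"
  else if (llr > 0) "before_wgd" else "after_wgd"
  attr(verdict, "llr") <- llr
  verdict
}

#' Consistency of the mutation accumulation rate across chromosomes
#'
#' The molecular-time estimators assume one constant per-copy mutation rate
#' across chromosome-scale segments; under that assumption per-chromosome
#' mutation counts are proportional to chromosome lengths. This fits the
#' proportionality constant by least squares through the origin and reports
#' the squared Pearson correlation of counts versus lengths as the
#' consistency diagnostic.
#'
#' @param counts Per-chromosome mutation counts (>= 5 chromosomes).
#' @param lengths_mb Matching chromosome lengths in megabases.
#' @return List with `rate_per_mb` (fitted slope), `rates` (per-chromosome
#'   count/length) and `r_squared`.
#' @export
rate_consistency <- function(counts, lengths_mb) {
  stopifnot(length(counts) == length(lengths_mb), length(counts) >= 5,
            all(lengths_mb > 0))
  fit <- stats::lm(counts ~ 0 + lengths_mb)
  list(
    rate_per_mb = unname(stats::coef(fit)[1]),
    rates = counts / lengths_mb,
    r_squared = stats::cor(counts, lengths_mb)^2
  )
}
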