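#' Estimate segment lesser allele fraction from germline heterozygous sites
#'
#' The lesser allele fraction (LAF) of a segment is estimated from tumor read
#' counts at sites that are heterozygous in the matched normal: each site
#' contributes its lesser read fraction `min(v, 1 - v)` with
#' `v = alt / (alt + ref)`, combined as a read-count-weighted mean. The raw
#' folded mean is biased downward near 0.5 (at 105x a balanced segment folds
#' to about 0.46), so by default the binomial sampling variance is removed by
#' a moment correction: `(v - 1/2)^2 - v(1 - v)/(depth - 1)` is an unbiased
#' per-site estimate of `(p - 1/2)^2`, and the segment LAF is
#' `1/2 - sqrt(max(0, weighted mean))`. Both estimators are symmetric under
#' allele relabeling and always lie in `[0, 0.5]`.
#'
#' @param sites Data.frame of het sites (columns `ref_count`, `alt_count`),
#'   e.g. one segment's rows from [read_het_sites()].
#' @param min_sites Minimum number of sites required (default 10); below
#'   this the LAF is undefined and `NA` is returned with a warning.
#' @param debias Apply the sampling-noise moment correction (default TRUE);
#'   `FALSE` gives the raw folded read-ratio mean.
#' @return Segment LAF in `[0, 0.5]`, or `NA_real_` when there are too few
#'   informative sites.
#' @export
estimate_laf <- function(sites, min_sites = 10L, debias = TRUE) {
  total <- sites$ref_count + sites$alt_count
  keep <- total > 0
  if (sum(keep) < min_sites) {
    warning("insufficient het sites: segment LAF undefined")
    return(NA_real_)
  }
  v <- sites$alt_count[keep] / total[keep]
  w <- total[keep]
  if (!debias) return(stats::weighted.mean(pmin(v, 1 - v), w = w))
  d2 <- (v - 0.5)^2 - v * (1 - v) / pmax(w - 1, 1)
  0.5 - sqrt(max(stats::weighted.mean(d2, w = w), 0))
}

#' Detect a subclonal copy-number alteration on one segment
#'
#' A clonal segment has integer allelic copy number after purity correction;
#' a mixture of two tumor lineages with different states produces a
#' non-integer observation. Given the corrected `(cn_t, laf_t)` of a segment,
#' this classifies it as clonal when the nearest integer state lies within
#' `epsilon` in both coordinates, and otherwise fits the two-state mixture
#' `cn = (1 - phi) cn1 + phi cn2`, `minor = (1 - phi) a1 + phi a2` over
#' candidate second states within one copy per allele of the nearest state,
#' returning the candidate and mixing fraction with minimal residual.
#'
#' @param cn_t Purity-corrected total copy number.
#' @param laf_t Purity-corrected lesser allele fraction.
#' @param epsilon Integer tolerance in each coordinate (default 0.05,
#'   roughly two binomial standard deviations at ~100x depth).
#' @param phi_range Admissible minor-lineage fractions; fits outside this
#'   open interval are treated as clonal-ambiguous (default `c(0.05, 0.95)`).
#' @param max_total Largest total copy number on the state lattice.
#' @return An object of class `subclone_cna_call`: list with `verdict`
#'   (`"clonal"`, `"subclonal"` or `"unresolved"`), `state_major`,
#'   `state_minor` (NULL when clonal), `phi` (minor-lineage fraction, NA when
#'   clonal), `residual` and the input coordinates.
#' @examples
#' detect_subclonal_cna(2.0, 0.5)  # clonal AB
#' detect_subclonal_cna(2.5, 0.4)  # AB + AAB mixture, phi = 0.5
#' @export
detect_subclonal_cna <- function(cn_t, laf_t, epsilon = 0.05,
                                 phi_range = c(0.05, 0.95), max_total = 8L) {
  ns <- nearest_integer_state(cn_t, laf_t, max_total)
  st1 <- ns$state
  out <- list(verdict = "clonal", state_major = st1, state_minor = NULL,
              phi = NA_real_, residual = ns$distance,
              cn_t = cn_t, laf_t = laf_t)
  class(out) <- "subclone_cna_call"
  if (abs(cn_t - st1$total) <= epsilon && abs(laf_t - st1$laf) <= epsilon)
    return(out)

  a_t <- cn_t * laf_t
  c1 <- st1$total; a1 <- st1$n_minor
  best <- NULL
  for (dM in -1:1) for (dm in -1:1) {
    if (dM == 0 && dm == 0) next
    M2 <- st1$n_major + dM
    m2 <- st1$n_minor + dm
    if (M2 < 0 || m2 < 0) next
    st2 <- allelic_state(max(M2, m2), min(M2, m2))
    if (st2$n_major == st1$n_major && st2$n_minor == st1$n_minor) next
    if (st2$total > max_total) next
    c2 <- st2$total; a2 <- st2$n_minor
    den <- (c2 - c1)^2 + (a2 - a1)^2
    phi <- ((cn_t - c1) * (c2 - c1) + (a_t - a1) * (a2 - a1)) / den
    if (phi <= phi_range[1] || phi >= phi_range[2]) next
    mix_cn <- (1 - phi) * c1 + phi * c2
    mix_a <- (1 - phi) * a1 + phi * a2
    res <- sqrt((cn_t - mix_cn)^2 + (a_t - mix_a)^2)
    if (is.null(best) || res < best$residual)
      best <- list(state = st2, phi = phi, residual = res)
  }
  if (is.null(best)) {
    out$verdict <- "unresolved"
    return(out)
  }
  out$verdict <- "subclonal"
  out$state_minor <- best$state
  out$phi <- best$phi
  out$residual <- best$residual
  out
}

#' @export
print.subclone_cna_call <- function(x, ...) {
  if (x$verdict == "subclonal") {
    cat(sprintf(
      "Subclonal CNA: %s (major) + %s at phi = %.3f, residual %.4f\n",
      x$state_major$label, x$state_minor$label, x$phi, x$residual))
  } else {
    cat(sprintf("%s segment: nearest state %s, distance %.4f\n",
                x$verdict, x$state_major$label, x$residual))
  }
  invisible(x)
}

#' Call subclonal copy-number alterations across a segment table
#'
#' Convenience wrapper: purity-corrects each segment and runs
#' [detect_subclonal_cna()], returning one row per segment.
#'
#' @param segments Segment table from [read_segments()] (needs `laf_obs`).
#' @param alpha Normal-cell contamination fraction.
#' @param ... Passed to [detect_subclonal_cna()].
#' @return A data.frame with per-segment `chrom`, `start`, `end`, corrected
#'   `cn_t`, `laf_t`, `verdict`, major/minor state labels, `phi`, `residual`.
#' @export
call_subclonal_cna <- function(segments, alpha, ...) {
  segs <- segments[!is.na(segments$laf_obs), , drop = FALSE]
  corr <- correct_allelic_cn(segs$cn_obs, segs$laf_obs, alpha)
  calls <- lapply(seq_len(nrow(segs)), function(i)
    detect_subclonal_cna(corr$cn_t[i], corr$laf_t[i], ...))
  data.frame(
    chrom = segs$chrom, start = segs$start, end = segs$end,
    cn_t = corr$cn_t, laf_t = corr$laf_t,
    verdict = vapply(calls, `[[`, "", "verdict"),
    state_major = vapply(calls, function(x) x$state_major$label, ""),
    state_minor = vapply(calls, function(x)
      if (is.null(x$state_minor)) NA_character_ else x$state_minor$label, ""),
    phi = vapply(calls, `[[`, 0, "phi"),
    residual = vapply(calls, `[[`, 0, "residual"),
    stringsAsFactors = FALSE
  )
}
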