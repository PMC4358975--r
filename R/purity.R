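#' Expected observed VAF under normal-cell contamination
#'
#' Forward model for the variant allele fraction observed in sequencing reads
#' when a tumor sample is a mixture of tumor cells (fraction `1 - alpha`) and
#' diploid normal cells (fraction `alpha`). A somatic mutation present on `m`
#' of the `n_t` tumor copies, in a fraction `f` of tumor cells, yields
#'
#' \deqn{v = \frac{(1-\alpha) f m}{(1-\alpha) n_t + 2\alpha}}
#'
#' With no contamination and a fully clonal mutation this reduces to the
#' familiar lattice `m / n_t`: 0.5 for a heterozygous mutation on a diploid
#' segment, 0.25 for a single-copy mutation on a tetraploid segment, 2/3 and
#' 1/3 for mutations preceding/following the duplication on a trisomic
#' segment.
#'
#' @param alpha Normal-cell contamination fraction in `[0, 1)`.
#' @param n_t Tumor total copy number of the segment (>= 1).
#' @param m Mutation multiplicity, integer in `1..n_t`.
#' @param f Cancer-cell fraction carrying the mutation, in `(0, 1]`
#'   (1 = clonal).
#' @return Expected observed VAF in `(0, 1]`.
#' @examples
#' expected_obs_vaf(0, 2, 1)          # 0.5
#' expected_obs_vaf(0, 4, 1)          # 0.25
#' expected_obs_vaf(0.08, 2, 1)       # 0.46
#' @export
expected_obs_vaf <- function(alpha, n_t, m, f = 1) {
  stopifnot(all(alpha >= 0 & alpha < 1), all(n_t >= 1),
            all(f > 0 & f <= 1), all(m >= 1))
  if (any(m > n_t)) stop("multiplicity m cannot exceed tumor copy number n_t")
  (1 - alpha) * f * m / ((1 - alpha) * n_t + 2 * alpha)
}

#' Expected observed lesser allele fraction under contamination
#'
#' Forward model for the segment-level lesser allele fraction (LAF) measured
#' at germline heterozygous sites. The normal compartment contributes one
#' copy of each parental allele, so a tumor state with `n_minor` minor-allele
#' copies out of `n_t` total appears at
#'
#' \deqn{l = \frac{(1-\alpha) n_{minor} + \alpha}{(1-\alpha) n_t + 2\alpha}}
#'
#' @inheritParams expected_obs_vaf
#' @param n_minor Minor-allele copy number, `0 <= n_minor <= n_t / 2`.
#' @return Expected observed LAF in `[0, 0.5]`.
#' @examples
#' expected_obs_laf(0, 3, 1)    # 1/3, the AAB trisomy value
#' expected_obs_laf(0.2, 2, 0)  # 0.1: LOH blurred by contamination
#' @export
expected_obs_laf <- function(alpha, n_t, n_minor) {
  stopifnot(all(alpha >= 0 & alpha < 1), all(n_t >= 1), all(n_minor >= 0))
  if (any(n_minor > n_t - n_minor))
    stop("n_minor exceeds n_t - n_minor: not the lesser allele")
  ((1 - alpha) * n_minor + alpha) / ((1 - alpha) * n_t + 2 * alpha)
}

#' Correct an observed VAF for normal-cell contamination
#'
#' Inverts [expected_obs_vaf()] at the `f * m = 1` scale, mapping an observed
#' VAF back to the pure-tumor scale, i.e. to `f * m / n_t`. Values that
#' correct to more than 1 (sampling noise) are clipped to 1 with a warning.
#'
#' @param vaf_obs Observed VAF(s) in `[0, 1]`.
#' @param alpha Normal-cell contamination fraction in `[0, 1)`.
#' @param n_t Tumor total copy number of the segment the mutation lies on.
#' @return Corrected VAF(s); `attr(, "n_clipped")` counts clipped values.
#' @examples
#' correct_vaf(0.46, 0.08, 2)  # 0.5
#' @export
correct_vaf <- function(vaf_obs, alpha, n_t) {
  stopifnot(all(vaf_obs >= 0 & vaf_obs <= 1), alpha >= 0, alpha < 1,
            all(n_t >= 1))
  v <- vaf_obs * ((1 - alpha) * n_t + 2 * alpha) / ((1 - alpha) * n_t)
  n_clip <- sum(v > 1)
  if (n_clip > 0) {
    warning(sprintf("%d corrected VAF value(s) exceeded 1 and were clipped", n_clip))
    v <- pmin(v, 1)
  }
  attr(v, "n_clipped") <- n_clip
  v
}

#' Correct observed allelic copy number for normal-cell contamination
#'
#' Inverts the linear tumor/normal mixing model for segment copy number and
#' lesser allele fraction. With observed normal-scaled total copy number
#' `cn_obs` and observed LAF `laf_obs`,
#' `cn_t = (cn_obs - 2 alpha) / (1 - alpha)` and the minor-allele copy number
#' is `(cn_obs * laf_obs - alpha) / (1 - alpha)`.
#'
#' @param cn_obs Observed total copy number (real, >= 0; 2 = diploid normal).
#' @param laf_obs Observed lesser allele fraction in `[0, 0.5]`.
#' @param alpha Normal-cell contamination fraction in `[0, 1)`.
#' @return A list with `cn_t` (corrected total copy number), `laf_t`
#'   (corrected LAF, 0 when `cn_t` is 0), `minor_t` (corrected minor-allele
#'   copies) and `clipped` (TRUE where a negative corrected value was clipped
#'   to 0). All elements are vectorized over the inputs.
#' @examples
#' correct_allelic_cn(2.0, 0.10, 0.2)  # cn_t = 2, laf_t = 0 (clonal LOH)
#' @export
correct_allelic_cn <- function(cn_obs, laf_obs, alpha) {
  stopifnot(all(cn_obs >= 0), all(laf_obs >= 0 & laf_obs <= 0.5 + 1e-9))
  if (alpha >= 1) stop("alpha must be < 1")
  if (alpha < 0) stop("alpha must be >= 0")
  cn_t <- (cn_obs - 2 * alpha) / (1 - alpha)
  minor_t <- (cn_obs * laf_obs - alpha) / (1 - alpha)
  clipped <- cn_t < 0 | minor_t < 0
  cn_t <- pmax(cn_t, 0)
  minor_t <- pmin(pmax(minor_t, 0), cn_t / 2)
  laf_t <- ifelse(cn_t > 0, minor_t / cn_t, 0)
  list(cn_t = cn_t, laf_t = laf_t, minor_t = minor_t, clipped = clipped)
}

# Squared distance from a corrected (major, minor) allele copy pair to the
# nearest integer pair on the state lattice.
.int_pair_dist2 <- function(maj_t, min_t, max_total = 8L) {
  lat <- state_lattice(max_total)
  min((maj_t - lat[, "n_major"])^2 + (min_t - lat[, "n_minor"])^2)
}

.is_sex_chrom <- function(chrom) {
  grepl("^(chr)?(x|y)$", tolower(chrom))
}

# Segments consistent with pure diploid heterozygosity at ANY contamination
# level (AB is a fixed point of the mixing model), used both to select
# mutations for the VAF mode and to exclude segments from the CN objective.
.is_balanced_segment <- function(segments, cn_tol = 0.25, laf_min = 0.4) {
  abs(segments$cn_obs - 2) <= cn_tol &
    !is.na(segments$laf_obs) & segments$laf_obs >= laf_min
}

#' Estimate normal-cell contamination from allelic copy number and VAF
#'
#' Estimates the fraction `alpha` of contaminating normal cells in a tumor
#' sample by grid search. For each candidate `alpha` the objective sums
#' (a) the mean squared distance of contamination-corrected allelic copy
#' numbers of imbalanced segments to the nearest integer (major, minor) pair,
#' and (b) the squared distance of the dominant corrected VAF mode of somatic
#' mutations on balanced diploid segments to its nearest lattice value
#' `m / 2`. The mode is located by kernel density estimation (Silverman
#' bandwidth) on the observed VAFs; because the correction is linear in VAF
#' at fixed copy number, the mode is transformed analytically per candidate.
#' Ties are broken toward smaller `alpha`. Sex chromosomes are excluded.
#'
#' @param segments A segment table as returned by [read_segments()]
#'   (columns `chrom`, `cn_obs`, `laf_obs`, ...).
#' @param mutations A mutation table as returned by [read_mutations()]
#'   (columns `chrom`, `vaf_obs`, ...), or `NULL` to fit on segments alone.
#' @param grid_step Grid resolution for `alpha` in `[0, 0.5]` (default 0.005).
#' @param min_balanced_mutations Minimum number of mutations on balanced
#'   segments for the VAF term to be used (default 50).
#' @return An object of class `purity_estimate`: list with `alpha`,
#'   `objective`, `grid` (data.frame of evaluated `(alpha, objective)`
#'   pairs), `mode_vaf_obs`, `n_segments_used`, `n_mutations_used`.
#' @export
estimate_purity <- function(segments, mutations = NULL, grid_step = 0.005,
                            min_balanced_mutations = 50L) {
  segments <- segments[!.is_sex_chrom(segments$chrom), , drop = FALSE]
  balanced <- .is_balanced_segment(segments)
  imb <- segments[!balanced & !is.na(segments$laf_obs), , drop = FALSE]

  mode_obs <- NULL
  n_mut <- 0L
  if (!is.null(mutations) && nrow(mutations) > 0) {
    mutations <- mutations[!.is_sex_chrom(mutations$chrom), , drop = FALSE]
    bal_chroms <- unique(segments$chrom[balanced])
    mv <- mutations$vaf_obs[mutations$chrom %in% bal_chroms]
    mv <- mv[is.finite(mv) & mv > 0 & mv < 1]
    if (length(mv) >= min_balanced_mutations) {
      d <- stats::density(mv, bw = "nrd0")
      mode_obs <- d$x[which.max(d$y)]
      n_mut <- length(mv)
    }
  }

  if (nrow(imb) == 0 && is.null(mode_obs))
    stop("uninformative sample: no imbalanced segments and too few mutations on balanced segments")

  alphas <- seq(0, 0.5, by = grid_step)
  obj <- vapply(alphas, function(a) {
    val <- 0
    if (nrow(imb) > 0) {
      # raw (unclipped) corrected values: over-corrected alpha must be
      # penalized, so negative minor-allele copies are kept as-is here
      cn_t <- (imb$cn_obs - 2 * a) / (1 - a)
      min_t <- (imb$cn_obs * imb$laf_obs - a) / (1 - a)
      maj_t <- cn_t - min_t
      d2 <- mapply(.int_pair_dist2, maj_t, min_t)
      val <- val + mean(d2)
    }
    if (!is.null(mode_obs)) {
      mc <- suppressWarnings(as.numeric(correct_vaf(mode_obs, a, 2)))
      val <- val + min((mc - 0.5)^2, (mc - 1)^2)
    }
    val
  }, numeric(1))

  i <- which.min(obj)  # first minimum: ties go to smaller alpha
  structure(
    list(
      alpha = alphas[i],
      objective = obj[i],
      grid = data.frame(alpha = alphas, objective = obj),
      mode_vaf_obs = mode_obs,
      n_segments_used = nrow(imb),
      n_mutations_used = n_mut
    ),
    class = "purity_estimate"
  )
}

#' @export
print.purity_estimate <- function(x, ...) {
  cat(sprintf(
    "Normal-cell contamination estimate\n  alpha = %.3f (purity %.3f), objective = %.4g\n  fitted on %d imbalanced segment(s), %d mutation(s)%s\n",
    x$alpha, 1 - x$alpha, x$objective, x$n_segments_used, x$n_mutations_used,
    if (!is.null(x$mode_vaf_obs))
      sprintf("; observed VAF mode %.3f", x$mode_vaf_obs) else ""
  ))
  invisible(x)
}
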