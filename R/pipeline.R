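#' Run the full single-tumor analysis
#'
#' Convenience orchestration of the whole workflow on one tumor: estimate
#' normal-cell contamination ([estimate_purity()]), call subclonal
#' copy-number alterations ([call_subclonal_cna()]), cluster VAFs on
#' balanced diploid chromosomes ([cluster_vafs()]), time each clonal
#' copy-number event ([time_segment()]), check for whole-genome duplication
#' ([detect_wgd()]), and assemble the evolutionary timeline
#' ([build_timeline()]).
#'
#' @param mutations Mutation table (see [read_mutations()]).
#' @param het_sites Germline het-site table (see [read_het_sites()]), used to
#'   (re-)estimate segment LAF when `segments$laf_obs` is missing.
#' @param segments Segment table (see [read_segments()]).
#' @param alpha Known contamination fraction; `NULL` (default) estimates it.
#' @param seed Seed for clustering restarts and bootstrap intervals.
#' @param min_cluster_mutations Minimum mutations on balanced chromosomes for
#'   VAF clustering to be attempted (default 20).
#' @return A list of class `clonechron_result`: `purity`, `cna_calls`,
#'   `vaf_clusters` (or NULL), `events` (data.frame of timed clonal events),
#'   `wgd`, `timeline`.
#' @export
analyze_tumor <- function(mutations, het_sites = NULL, segments,
                          alpha = NULL, seed = 1L,
                          min_cluster_mutations = 20L) {
  if (any(is.na(segments$laf_obs)) && !is.null(het_sites)) {
    for (i in which(is.na(segments$laf_obs))) {
      on_seg <- het_sites$chrom == segments$chrom[i] &
        het_sites$pos >= segments$start[i] & het_sites$pos < segments$end[i]
      if (any(on_seg))
        segments$laf_obs[i] <- suppressWarnings(
          estimate_laf(het_sites[on_seg, , drop = FALSE]))
    }
  }

  purity <- if (is.null(alpha)) estimate_purity(segments, mutations) else
    structure(list(alpha = alpha, objective = NA_real_, grid = NULL,
                   mode_vaf_obs = NULL, n_segments_used = 0L,
                   n_mutations_used = 0L),
              class = "purity_estimate")
  a <- purity$alpha

  cna_calls <- call_subclonal_cna(segments, a)

  balanced <- .is_balanced_segment(segments)
  bal_chroms <- unique(segments$chrom[balanced])
  mut_bal <- mutations[mutations$chrom %in% bal_chroms, , drop = FALSE]
  clusters <- if (nrow(mut_bal) >= min_cluster_mutations)
    cluster_vafs(mut_bal, alpha = a, n_t = 2, seed = seed) else NULL

  # time clonal events on segments whose corrected state departs from AB
  corr <- correct_allelic_cn(segments$cn_obs, segments$laf_obs, a)
  ev_rows <- list()
  for (i in seq_len(nrow(segments))) {
    if (is.na(segments$laf_obs[i])) next
    if (cna_calls$verdict[i] != "clonal") next
    st <- nearest_integer_state(corr$cn_t[i], corr$laf_t[i])$state
    if (st$n_major == 1L && st$n_minor == 1L) next
    on_seg <- mutations$chrom == segments$chrom[i] &
      mutations$pos >= segments$start[i] & mutations$pos < segments$end[i]
    ev <- time_segment(mutations[on_seg, , drop = FALSE],
                       corr$cn_t[i], corr$laf_t[i], alpha = a, seed = seed)
    ev_rows[[length(ev_rows) + 1L]] <- data.frame(
      label = paste0(ev$event_class, ":", segments$chrom[i]),
      chrom = segments$chrom[i], event_class = ev$event_class,
      state = ev$state$label, t = ev$t,
      ci_lo = ev$ci[1], ci_hi = ev$ci[2],
      stringsAsFactors = FALSE)
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(label = character(0), chrom = character(0),
               event_class = character(0), state = character(0),
               t = numeric(0), ci_lo = numeric(0), ci_hi = numeric(0))

  wgd <- detect_wgd(segments, mutations, alpha = a, seed = seed)

  sub_calls <- cna_calls[cna_calls$verdict == "subclonal", , drop = FALSE]
  subclone_df <- if (nrow(sub_calls)) data.frame(
    label = paste0("cna:", sub_calls$chrom), phi = sub_calls$phi,
    stringsAsFactors = FALSE) else NULL
  timeline <- suppressWarnings(build_timeline(
    events = events[!is.na(events$t), , drop = FALSE],
    mutation_timings = NULL,
    subclone_calls = subclone_df))

  structure(
    list(purity = purity, cna_calls = cna_calls, vaf_clusters = clusters,
         events = events, wgd = wgd, timeline = timeline),
    class = "clonechron_result"
  )
}

#' @export
print.clonechron_result <- function(x, ...) {
  print(x$purity)
  cat(sprintf("WGD: %s (%.0f%% of genome tetraploid)\n",
              x$wgd$wgd, 100 * x$wgd$genome_frac_tetraploid))
  n_sub <- sum(x$cna_calls$verdict == "subclonal")
  cat(sprintf("Subclonal CNAs: %d of %d segments\n",
              n_sub, nrow(x$cna_calls)))
  print(x$timeline)
  invisible(x)
}
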