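#' Autosome template for the tumor-genome simulator
#'
#' Approximate human autosome lengths (GRCh37 scale, in megabases),
#' optionally shrunk by a common factor to trade realism for speed in tests.
#'
#' @param scale Multiplier applied to all lengths (default 1).
#' @return Data.frame with `chrom`, `start` (0), `end`, `length_mb`.
#' @export
sim_genome <- function(scale = 1) {
  mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
          115, 107, 102, 90, 81, 78, 59, 63, 48, 51) * scale
  data.frame(
    chrom = paste0("chr", 1:22),
    start = 0L,
    end = as.integer(round(mb * 1e6)),
    length_mb = mb,
    stringsAsFactors = FALSE
  )
}

#' Configuration for a synthetic tumor genome
#'
#' Encodes the generative model: somatic mutations accumulate at a constant
#' rate `lambda_rate` per megabase per chromosome copy per unit of molecular
#' time; a copy-number event at molecular time `t` changes the copy count
#' from then on and duplicates the mutations already present on the
#' duplicated copies (their multiplicity doubles); read counts are binomial
#' draws at the contamination-adjusted expected allele fractions with
#' Poisson-distributed depth.
#'
#' @param seed RNG seed; identical configs give identical output.
#' @param alpha Normal-cell contamination fraction in `[0, 1)` (purity is
#'   `1 - alpha`).
#' @param lambda_rate Mutations per Mb per copy per unit molecular time
#'   (default 0.7, giving roughly 4,000 mutations on a diploid full-scale
#'   genome).
#' @param depth_mean Mean sequencing coverage (default 105).
#' @param genome Genome template, see [sim_genome()].
#' @param events List of clonal events, each
#'   `list(chrom =, class =, t =)` with class in `"cn_loh_dup"`,
#'   `"trisomy_gain"`, `"gain"`, `"wgd"`, `"loss"`; `chrom = "genome"` with
#'   class `"wgd"` duplicates every autosome. At most one event per
#'   chromosome.
#' @param subclones List of subclones, each `list(branch_time =, fraction =,
#'   events = list(list(chrom =, class =)))`; private events must hit
#'   chromosomes without clonal events.
#' @param het_density Germline heterozygous sites per kilobase
#'   (default 0.5, typical human heterozygosity).
#' @param cn_noise_sd Gaussian noise SD on observed segment copy number
#'   (default 0.02).
#' @return Validated object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, alpha = 0.16, lambda_rate = 0.7,
                       depth_mean = 105, genome = sim_genome(),
                       events = list(), subclones = list(),
                       het_density = 0.5, cn_noise_sd = 0.02) {
  stopifnot(alpha >= 0, alpha < 1, lambda_rate > 0, depth_mean > 0,
            het_density >= 0, cn_noise_sd >= 0)
  classes <- c("cn_loh_dup", "trisomy_gain", "gain", "wgd", "loss")
  ev_chroms <- character(0)
  for (ev in events) {
    stopifnot(!is.null(ev$chrom), ev$class %in% classes,
              ev$t > 0, ev$t < 1)
    if (ev$chrom == "genome" && ev$class != "wgd")
      stop("config error: only class 'wgd' may target the whole genome")
    ev_chroms <- c(ev_chroms, if (ev$chrom == "genome") genome$chrom
                   else ev$chrom)
  }
  if (anyDuplicated(ev_chroms))
    stop("config error: inconsistent event history - more than one event on ",
         ev_chroms[duplicated(ev_chroms)][1])
  for (sc in subclones) {
    stopifnot(sc$branch_time > 0, sc$branch_time < 1,
              sc$fraction > 0, sc$fraction < 1)
    for (ev in sc$events %||% list()) {
      stopifnot(ev$class %in% classes)
      if (ev$chrom %in% ev_chroms)
        stop("config error: subclonal event on ", ev$chrom,
             " conflicts with a clonal event there")
    }
  }
  structure(
    list(seed = as.integer(seed), alpha = alpha, lambda_rate = lambda_rate,
         depth_mean = depth_mean, genome = genome, events = events,
         subclones = subclones, het_density = het_density,
         cn_noise_sd = cn_noise_sd),
    class = "sim_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Post-event allelic state (major, minor) reached from diploid AB.
.post_state <- function(class) {
  switch(class,
    none = c(1, 1), cn_loh_dup = c(2, 0), trisomy_gain = c(2, 1),
    gain = c(2, 1), wgd = c(2, 2), loss = c(1, 0))
}

# Mutation strata (multiplicity, expected count factor, time window) for one
# chromosome with a single clonal event of `class` at time t; rates are per
# lambda * L.
.mutation_strata <- function(class, t) {
  switch(class,
    none = list(list(m = 1, rate = 2, win = c(0, 1))),
    cn_loh_dup = list(
      list(m = 2, rate = t, win = c(0, t)),
      list(m = 1, rate = 2 * (1 - t), win = c(t, 1))),
    trisomy_gain = ,
    gain = list(
      list(m = 2, rate = t, win = c(0, t)),
      list(m = 1, rate = t, win = c(0, t)),
      list(m = 1, rate = 3 * (1 - t), win = c(t, 1))),
    wgd = list(
      list(m = 2, rate = 2 * t, win = c(0, t)),
      list(m = 1, rate = 4 * (1 - t), win = c(t, 1))),
    loss = list(
      list(m = 1, rate = t, win = c(0, t)),
      list(m = 1, rate = 1 - t, win = c(t, 1)))
  )
}

#' Simulate a tumor genome with known truth
#'
#' Draws a complete single-tumor dataset (somatic mutation read counts,
#' germline heterozygous-site read counts, copy-number segments) from the
#' generative model described in [sim_config()], together with the full
#' generative record needed for recovery tests.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_tumor` with `mutations`, `het_sites`,
#'   `segments` (data.frames matching the [read_mutations()],
#'   [read_het_sites()], [read_segments()] dialects) and `truth` (list:
#'   `alpha`, `events` data.frame with true times, `subclones` data.frame,
#'   `mutation_truth` data.frame with per-mutation lineage, multiplicity and
#'   true time).
#' @export
simulate_tumor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  alpha <- config$alpha
  lam <- config$lambda_rate
  genome <- config$genome

  # resolve per-chromosome clonal event
  ev_by_chrom <- stats::setNames(rep("none", nrow(genome)), genome$chrom)
  t_by_chrom <- stats::setNames(rep(NA_real_, nrow(genome)), genome$chrom)
  for (ev in config$events) {
    chroms <- if (ev$chrom == "genome") genome$chrom else ev$chrom
    ev_by_chrom[chroms] <- ev$class
    t_by_chrom[chroms] <- ev$t
  }
  # subclonal CNA per chromosome: (fraction, post-state)
  sub_cna <- list()
  for (si in seq_along(config$subclones)) {
    sc <- config$subclones[[si]]
    for (ev in sc$events %||% list())
      sub_cna[[ev$chrom]] <- list(fraction = sc$fraction, class = ev$class,
                                  subclone = si)
  }

  mut_rows <- list(); truth_rows <- list(); het_rows <- list()
  seg_rows <- list()
  mut_id <- 0L

  for (ci in seq_len(nrow(genome))) {
    ch <- genome$chrom[ci]
    L <- genome$length_mb[ci]
    len_bp <- genome$end[ci]
    cls <- ev_by_chrom[[ch]]
    t_ev <- t_by_chrom[[ch]]
    st <- .post_state(cls)

    # lineage copy numbers in the bulk tumor (trunk state, possibly mixed
    # with a subclonal CNA)
    maj <- st[1]; mnr <- st[2]
    if (!is.null(sub_cna[[ch]])) {
      phi <- sub_cna[[ch]]$fraction
      st2 <- .post_state(sub_cna[[ch]]$class)
      maj_mix <- (1 - phi) * maj + phi * st2[1]
      mnr_mix <- (1 - phi) * mnr + phi * st2[2]
    } else {
      maj_mix <- maj; mnr_mix <- mnr
    }
    cn_mix <- maj_mix + mnr_mix
    n_t <- maj + mnr

    # clonal (trunk) somatic mutations
    strata <- .mutation_strata(cls, t_ev)
    for (s in strata) {
      n <- stats::rpois(1, lam * L * s$rate)
      if (n == 0) next
      # observed denominator uses the bulk (possibly mixed) copy number
      v <- (1 - alpha) * s$m / ((1 - alpha) * cn_mix + 2 * alpha)
      d <- pmax(stats::rpois(n, config$depth_mean), 1L)
      a <- stats::rbinom(n, d, v)
      ids <- paste0("mut_", mut_id + seq_len(n)); mut_id <- mut_id + n
      mut_rows[[length(mut_rows) + 1L]] <- data.frame(
        id = ids, chrom = ch,
        pos = sample.int(len_bp, n, replace = TRUE),
        ref_count = d - a, alt_count = a, gene = NA_character_,
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        id = ids, chrom = ch, lineage = "clonal", multiplicity = s$m,
        t_true = stats::runif(n, s$win[1], s$win[2]), vaf_expected = v,
        stringsAsFactors = FALSE)
    }

    # subclone-private mutations (accumulate after the branch point at the
    # trunk's biopsy-time copy number, present in a fraction phi of cells)
    for (si in seq_along(config$subclones)) {
      sc <- config$subclones[[si]]
      n <- stats::rpois(1, lam * L * n_t * (1 - sc$branch_time))
      if (n == 0) next
      v <- (1 - alpha) * sc$fraction /
        ((1 - alpha) * cn_mix + 2 * alpha)
      d <- pmax(stats::rpois(n, config$depth_mean), 1L)
      a <- stats::rbinom(n, d, v)
      ids <- paste0("mut_", mut_id + seq_len(n)); mut_id <- mut_id + n
      mut_rows[[length(mut_rows) + 1L]] <- data.frame(
        id = ids, chrom = ch,
        pos = sample.int(len_bp, n, replace = TRUE),
        ref_count = d - a, alt_count = a, gene = NA_character_,
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        id = ids, chrom = ch, lineage = paste0("subclone_", si),
        multiplicity = 1L,
        t_true = stats::runif(n, sc$branch_time, 1), vaf_expected = v,
        stringsAsFactors = FALSE)
    }

    # germline heterozygous sites: the alt allele lands on either parental
    # lineage with equal probability
    n_het <- round(config$het_density * L * 1000)
    laf_expected <- ((1 - alpha) * mnr_mix + alpha) /
      ((1 - alpha) * cn_mix + 2 * alpha)
    if (n_het > 0) {
      d <- pmax(stats::rpois(n_het, config$depth_mean), 1L)
      on_minor <- stats::runif(n_het) < 0.5
      p_alt <- ifelse(on_minor,
                      ((1 - alpha) * mnr_mix + alpha),
                      ((1 - alpha) * maj_mix + alpha)) /
        ((1 - alpha) * cn_mix + 2 * alpha)
      a <- stats::rbinom(n_het, d, p_alt)
      het <- data.frame(chrom = ch,
                        pos = sort(sample.int(len_bp, n_het, replace = TRUE)),
                        ref_count = d - a, alt_count = a,
                        stringsAsFactors = FALSE)
      het_rows[[length(het_rows) + 1L]] <- het
      laf_obs <- suppressWarnings(estimate_laf(het))
      if (is.na(laf_obs)) laf_obs <- laf_expected
    } else {
      laf_obs <- laf_expected
    }

    cn_obs <- (1 - alpha) * cn_mix + 2 * alpha +
      stats::rnorm(1, 0, config$cn_noise_sd)
    seg_rows[[length(seg_rows) + 1L]] <- data.frame(
      chrom = ch, start = 0L, end = len_bp, length_mb = L,
      cn_obs = max(cn_obs, 0), laf_obs = min(laf_obs, 0.5),
      stringsAsFactors = FALSE)
  }

  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
    data.frame(id = character(0), chrom = character(0), pos = integer(0),
               ref_count = integer(0), alt_count = integer(0),
               gene = character(0))
  mutations$vaf_obs <- if (nrow(mutations))
    mutations$alt_count / (mutations$ref_count + mutations$alt_count) else
    numeric(0)
  mutations <- mutations[, c("id", "chrom", "pos", "ref_count", "alt_count",
                             "vaf_obs", "gene")]

  truth <- list(
    alpha = alpha,
    events = data.frame(
      chrom = genome$chrom, event_class = unname(ev_by_chrom),
      t = unname(t_by_chrom), stringsAsFactors = FALSE),
    subclones = if (length(config$subclones))
      data.frame(
        subclone = seq_along(config$subclones),
        branch_time = vapply(config$subclones, `[[`, 0, "branch_time"),
        fraction = vapply(config$subclones, `[[`, 0, "fraction"))
      else data.frame(subclone = integer(0), branch_time = numeric(0),
                      fraction = numeric(0)),
    mutation_truth = if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(id = character(0), chrom = character(0),
                 lineage = character(0), multiplicity = integer(0),
                 t_true = numeric(0), vaf_expected = numeric(0))
  )

  structure(
    list(mutations = mutations,
         het_sites = if (length(het_rows)) do.call(rbind, het_rows) else
           data.frame(chrom = character(0), pos = integer(0),
                      ref_count = integer(0), alt_count = integer(0)),
         segments = do.call(rbind, seg_rows),
         truth = truth,
         config = config),
    class = "sim_tumor"
  )
}

#' @export
print.sim_tumor <- function(x, ...) {
  cat(sprintf(
    "Synthetic tumor: %d mutations, %d het sites, %d segments, alpha = %.2f\n",
    nrow(x$mutations), nrow(x$het_sites), nrow(x$segments), x$truth$alpha))
  invisible(x)
}

#' Write a named synthetic fixture to disk
#'
#' Deterministic, seeded example tumors exercising the main genome
#' configurations:
#' * `null_diploid`: pure diploid genome, no contamination, no events;
#' * `pfn_like`: a fusion-negative-like genome with early uniparental disomy
#'   of chr11/chr9, further UPDs and trisomies at fixed times, 12%
#'   contamination, and a minority subclone contributing ~5% of mutations;
#' * `pfp_like`: a fusion-positive-like genome with 16% contamination, few
#'   mutations, a whole-genome duplication at t = 0.62 and a duplicated
#'   fusion junction read count in the truth record.
#'
#' Fixtures use a 10%-scale genome with the per-Mb mutation rate scaled up
#' so genome-wide mutation counts match the full-scale configuration.
#'
#' @param name One of `"null_diploid"`, `"pfn_like"`, `"pfp_like"`.
#' @param dir Output directory (default `tempdir()`).
#' @param seed RNG seed override (each fixture has a fixed default).
#' @return Invisibly, a list with `paths` (mutations/het_sites/segments/
#'   truth files) and the simulated `sim_tumor` object.
#' @export
make_fixture <- function(name = c("null_diploid", "pfn_like", "pfp_like"),
                         dir = tempdir(), seed = NULL) {
  name <- match.arg(name)
  genome <- sim_genome(scale = 0.1)
  config <- switch(name,
    null_diploid = sim_config(
      seed = seed %||% 101L, alpha = 0, lambda_rate = 7, genome = genome,
      het_density = 0.1),
    pfn_like = sim_config(
      seed = seed %||% 202L, alpha = 0.12, lambda_rate = 6.8, genome = genome,
      het_density = 0.1,
      events = list(
        list(chrom = "chr8", class = "trisomy_gain", t = 0.08),
        list(chrom = "chr11", class = "cn_loh_dup", t = 0.14),
        list(chrom = "chr9", class = "cn_loh_dup", t = 0.14),
        list(chrom = "chr12", class = "trisomy_gain", t = 0.21),
        list(chrom = "chr19", class = "trisomy_gain", t = 0.21),
        list(chrom = "chr5", class = "cn_loh_dup", t = 0.26),
        list(chrom = "chr7", class = "cn_loh_dup", t = 0.26),
        list(chrom = "chr17", class = "cn_loh_dup", t = 0.26),
        list(chrom = "chr13", class = "trisomy_gain", t = 0.77),
        list(chrom = "chr20", class = "trisomy_gain", t = 0.98)),
      subclones = list(list(
        branch_time = 0.95, fraction = 0.45,
        events = list(list(chrom = "chr14", class = "gain"))))),
    pfp_like = sim_config(
      seed = seed %||% 303L, alpha = 0.16, lambda_rate = 1.5, genome = genome,
      het_density = 0.1,
      events = list(list(chrom = "genome", class = "wgd", t = 0.62)))
  )
  sim <- simulate_tumor(config)
  if (name == "pfp_like") {
    # a fusion junction formed before the WGD sits on 2 of 4 copies
    sim$truth$fusion <- list(
      junction_reads = stats::rbinom(1, round(config$depth_mean), 0.5),
      local_depth = config$depth_mean)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    mutations = file.path(dir, paste0(name, "_mutations.tsv")),
    het_sites = file.path(dir, paste0(name, "_het_sites.tsv")),
    segments = file.path(dir, paste0(name, "_segments.tsv")),
    truth = file.path(dir, paste0(name, "_truth.json"))
  )
  utils::write.table(sim$mutations, paths$mutations, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$het_sites, paths$het_sites, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    sim$segments[, c("chrom", "start", "end", "cn_obs", "laf_obs")],
    paths$segments, sep = "\t", quote = FALSE, row.names = FALSE)
  write_report(sim$truth[c("alpha", "subclones")], paths$truth)
  invisible(list(paths = paths, sim = sim))
}
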