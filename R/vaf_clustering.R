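# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  code
}

.log_row_sum_exp <- function(m) {
  mx <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

# One EM fit of a k-component binomial mixture to (alt, depth) read counts.
# The binomial coefficient is constant across iterations and components, so
# the per-iteration log-likelihood reduces to two outer products.
binom_mix_em <- function(alt, depth, p0, max_iter = 500L, tol = 1e-8) {
  n <- length(alt)
  k <- length(p0)
  p <- pmin(pmax(p0, 1e-6), 1 - 1e-6)
  w <- rep(1 / k, k)
  lc <- lchoose(depth, alt)
  ref <- depth - alt
  ll_old <- -Inf
  converged <- FALSE
  r <- matrix(1 / k, n, k)
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    lmat <- lc + tcrossprod(alt, log(p)) + tcrossprod(ref, log1p(-p)) +
      rep(log(w), each = n)
    lse <- .log_row_sum_exp(lmat)
    ll <- sum(lse)
    r <- exp(lmat - lse)
    w <- pmax(colMeans(r), 1e-12)
    w <- w / sum(w)
    num <- colSums(r * alt)
    den <- colSums(r * depth)
    p <- ifelse(den > 0, num / den, p)
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(p = p, w = w, loglik = ll_old, posterior = r, converged = converged,
       iterations = iter)
}

#' Cluster somatic VAFs with a binomial mixture and BIC model selection
#'
#' Fits binomial mixture models with `k = 1..k_max` components to the tumor
#' read counts of mutations sharing one copy-number context, by
#' expectation-maximization, and selects `k` by the Bayesian information
#' criterion. The binomial likelihood uses each mutation's own sequencing
#' depth, so deeper sites carry more weight than shallow ones. Component
#' means are reported both on the observed scale and corrected for
#' normal-cell contamination via [correct_vaf()]. Initialization is
#' quantile-based with jittered restarts under a fixed seed, so results are
#' deterministic for identical inputs.
#'
#' @param mutations Data.frame with columns `id`, `ref_count`, `alt_count`
#'   (as from [read_mutations()]); at least 20 rows.
#' @param alpha Normal-cell contamination fraction used to correct the
#'   reported means (default 0).
#' @param n_t Tumor total copy number of the shared context (default 2).
#' @param k_max Largest number of components tried (default 5).
#' @param restarts EM restarts per `k` (default 10).
#' @param seed RNG seed for restart jitter (default 42).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance; non-convergence returns the best fit so far with
#'   a warning.
#' @return An object of class `vaf_clusters`: list with `clusters`
#'   (data.frame of `mean` (corrected), `mean_obs`, `weight`, `count`), `k`,
#'   `score_by_k` (BIC per candidate), `loglik`, and `assignments`
#'   (data.frame of `id`, `cluster`, `posterior`).
#' @export
cluster_vafs <- function(mutations, alpha = 0, n_t = 2, k_max = 5L,
                         restarts = 10L, seed = 42L, max_iter = 500L,
                         tol = 1e-7) {
  if (nrow(mutations) < 20)
    stop("need at least 20 mutations sharing a copy-number context")
  alt <- mutations$alt_count
  depth <- mutations$ref_count + mutations$alt_count
  stopifnot(all(depth > 0))
  vaf <- alt / depth

  if (length(unique(vaf)) == 1L) {
    # degenerate: all-identical VAFs collapse to a single cluster
    fit <- binom_mix_em(alt, depth, p0 = vaf[1], max_iter = max_iter, tol = tol)
    fits <- list(fit)
    bic <- -2 * fit$loglik + 1 * log(length(alt))
    k_grid <- 1L
  } else {
    k_grid <- seq_len(k_max)
    fits <- vector("list", k_max)
    bic <- numeric(k_max)
    .with_seed(seed, {
      for (k in k_grid) {
        # short-run strategy: each restart gets a brief EM burn-in, and only
        # the best short run is polished to convergence
        best <- NULL
        for (r in seq_len(restarts)) {
          p0 <- as.numeric(stats::quantile(vaf, probs = (seq_len(k) - 0.5) / k))
          if (r > 1) p0 <- pmin(pmax(p0 + stats::rnorm(k, 0, 0.05), 1e-3), 1 - 1e-3)
          fit <- binom_mix_em(alt, depth, p0, max_iter = 30L, tol = tol)
          if (is.null(best) || fit$loglik > best$loglik) best <- fit
        }
        best <- binom_mix_em(alt, depth, best$p, max_iter = max_iter, tol = tol)
        fits[[k]] <- best
        bic[k] <- -2 * best$loglik + (2 * k - 1) * log(length(alt))
      }
    })
  }

  k_sel <- k_grid[which.min(bic)]
  fit <- fits[[k_sel]]
  if (!fit$converged)
    warning(sprintf("EM did not converge in %d iterations for the selected k = %d; best fit so far used",
                    max_iter, k_sel))
  assign_idx <- apply(fit$posterior, 1, which.max)
  counts <- tabulate(assign_idx, nbins = length(fit$p))
  ord <- order(fit$p, decreasing = TRUE)
  rank <- match(seq_along(fit$p), ord)
  structure(
    list(
      clusters = data.frame(
        cluster = seq_along(ord),
        mean = suppressWarnings(as.numeric(correct_vaf(fit$p[ord], alpha, n_t))),
        mean_obs = fit$p[ord],
        weight = fit$w[ord],
        count = counts[ord]
      ),
      k = k_sel,
      score_by_k = stats::setNames(bic, paste0("k", k_grid)),
      loglik = fit$loglik,
      assignments = data.frame(
        id = mutations$id,
        cluster = rank[assign_idx],
        posterior = fit$posterior[cbind(seq_along(assign_idx), assign_idx)],
        stringsAsFactors = FALSE
      )
    ),
    class = "vaf_clusters"
  )
}

#' @export
print.vaf_clusters <- function(x, ...) {
  cat(sprintf("VAF clustering: k = %d (BIC-selected), logLik = %.2f\n",
              x$k, x$loglik))
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Flag a mutation as subclonal
#'
#' A mutation is flagged subclonal when its corrected VAF falls more than
#' `threshold` below the expected fully clonal VAF of its copy-number
#' context (one-sided: subclonal mutations sit below the clonal expectation;
#' VAFs above it reflect higher multiplicity or noise and are handled by
#' multiplicity assignment instead). The inequality is strict.
#'
#' @param vaf_corrected Contamination-corrected VAF(s).
#' @param expected_clonal_vaf Expected VAF of a fully clonal mutation in the
#'   same context (e.g. 0.5 on a diploid segment).
#' @param threshold Deviation threshold (default 0.10, in absolute VAF units).
#' @return Logical vector.
#' @examples
#' flag_subclonal(0.2, 0.5)   # TRUE
#' flag_subclonal(0.40, 0.5)  # FALSE: boundary, strict inequality
#' @export
flag_subclonal <- function(vaf_corrected, expected_clonal_vaf,
                           threshold = 0.10) {
  (expected_clonal_vaf - vaf_corrected) > threshold
}

#' Minimum detectable subclonal VAF at a given sequencing depth
#'
#' Estimates by simulation the smallest subclonal VAF that the mixture
#' clustering reliably separates from the clonal cluster. For each candidate
#' VAF on a descending grid, `replicates` synthetic cohorts of `n_clonal`
#' clonal mutations (true VAF 0.5) plus `n_sub` subclonal mutations at the
#' candidate VAF are drawn with per-site depths Poisson(`depth`), clustered
#' with [cluster_vafs()], and counted as recovered when a cluster mean lies
#' within 0.05 of the candidate. The limit is the smallest candidate still
#' recovered in at least `success_frac` of replicates, walking down the grid
#' until the first failure.
#'
#' @param depth Mean sequencing coverage (e.g. 105).
#' @param n_clonal,n_sub Numbers of clonal and subclonal mutations simulated.
#' @param replicates Replicates per candidate VAF (default 20).
#' @param seed Base RNG seed.
#' @param grid Descending candidate subclonal VAFs.
#' @param success_frac Required recovery fraction (default 0.9).
#' @return The detection limit (smallest reliably recovered VAF), with the
#'   per-candidate recovery fractions as attribute `"recovery"`. `NA` if even
#'   the largest candidate is not recovered.
#' @export
detection_limit <- function(depth = 105, n_clonal = 1000L, n_sub = 100L,
                            replicates = 20L, seed = 1L,
                            grid = c(0.30, 0.25, 0.20, 0.15, 0.10, 0.05),
                            success_frac = 0.9) {
  grid <- sort(grid, decreasing = TRUE)
  recovery <- stats::setNames(numeric(length(grid)), format(grid))
  limit <- NA_real_
  for (gi in seq_along(grid)) {
    v <- grid[gi]
    hits <- 0L
    for (rep in seq_len(replicates)) {
      muts <- .with_seed(seed + 1000L * gi + rep, {
        n <- n_clonal + n_sub
        d <- pmax(stats::rpois(n, depth), 1L)
        p <- c(rep(0.5, n_clonal), rep(v, n_sub))
        a <- stats::rbinom(n, d, p)
        data.frame(id = paste0("m", seq_len(n)),
                   ref_count = d - a, alt_count = a)
      })
      cl <- suppressWarnings(
        cluster_vafs(muts, alpha = 0, n_t = 2, seed = seed + rep))
      if (cl$k >= 2 && any(abs(cl$clusters$mean_obs - v) <= 0.05))
        hits <- hits + 1L
    }
    recovery[gi] <- hits / replicates
    if (recovery[gi] >= success_frac) limit <- v else break
  }
  attr(limit, "recovery") <- recovery
  limit
}
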