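#' Integer allelic copy-number state
#'
#' An allelic state records how many copies of each parental allele a tumor
#' segment carries, e.g. `AB` for normal diploid, `AA` for uniparental disomy
#' (copy-neutral LOH with duplication), `AAB` for trisomy, `AABB` for
#' tetrasomy after whole-genome duplication.
#'
#' @param n_major Copies of the more abundant parental allele (integer >= 0).
#' @param n_minor Copies of the less abundant parental allele
#'   (integer, `0 <= n_minor <= n_major`).
#'
#' @return An object of class `allelic_state`: a list with elements
#'   `n_major`, `n_minor`, `total`, `laf` (lesser allele fraction
#'   `n_minor / total`, 0 for the null state) and `label` (e.g. `"AAB"`).
#' @examples
#' allelic_state(2, 1)  # trisomy AAB, LAF 1/3
#' @export
allelic_state <- function(n_major, n_minor) {
  stopifnot(length(n_major) == 1L, length(n_minor) == 1L)
  n_major <- as.integer(n_major)
  n_minor <- as.integer(n_minor)
  if (is.na(n_major) || is.na(n_minor) || n_major < 0L || n_minor < 0L)
    stop("allele copy numbers must be non-negative integers")
  if (n_minor > n_major)
    stop("n_minor must not exceed n_major")
  total <- n_major + n_minor
  structure(
    list(
      n_major = n_major,
      n_minor = n_minor,
      total   = total,
      laf     = if (total == 0L) 0 else n_minor / total,
      label   = paste0(strrep("A", n_major), strrep("B", n_minor))
    ),
    class = "allelic_state"
  )
}

#' @export
format.allelic_state <- function(x, ...) {
  lab <- if (nzchar(x$label)) x$label else "null (0 copies)"
  sprintf("<allelic_state %s: total=%d, LAF=%.3f>", lab, x$total, x$laf)
}

#' @export
print.allelic_state <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Enumerate all allelic states with total copy number <= max_total, ordered so
# that which.min() on a distance vector resolves ties toward the smaller
# total, then the larger n_minor.
state_lattice <- function(max_total = 8L) {
  rows <- list()
  for (total in 0:max_total) {
    for (n_minor in seq(total %/% 2L, 0L)) {
      rows[[length(rows) + 1L]] <-
        c(total - n_minor, n_minor, total,
          if (total == 0L) 0 else n_minor / total)
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c("n_major", "n_minor", "total", "laf")
  m
}

#' Nearest integer allelic state
#'
#' Finds the integer allelic state closest to a purity-corrected
#' (total copy number, lesser allele fraction) observation, by Euclidean
#' distance in the (copy number, LAF) plane over all states with total copy
#' number up to `max_total`. Integer states are the expected positions of
#' clonal segments; a large distance indicates a subclonal copy-number
#' mixture (see [detect_subclonal_cna()]).
#'
#' @param cn_t Purity-corrected total copy number (>= 0).
#' @param laf_t Purity-corrected lesser allele fraction in `[0, 0.5]`.
#' @param max_total Largest total copy number considered (default 8).
#'
#' @return A list with `state` (an [allelic_state()]) and `distance`
#'   (Euclidean distance to it). Ties are broken toward the smaller total
#'   copy number, then the larger minor-allele count.
#' @examples
#' nearest_integer_state(2.0, 0.5)   # AB, distance 0
#' nearest_integer_state(3.02, 0.33) # AAB
#' @export
nearest_integer_state <- function(cn_t, laf_t, max_total = 8L) {
  stopifnot(is.finite(cn_t), cn_t >= 0, is.finite(laf_t))
  lat <- state_lattice(max_total)
  d2 <- (cn_t - lat[, "total"])^2 + (laf_t - lat[, "laf"])^2
  i <- which.min(d2)
  list(
    state = allelic_state(lat[i, "n_major"], lat[i, "n_minor"]),
    distance = sqrt(d2[i])
  )
}
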