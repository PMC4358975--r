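#' Assemble a per-tumor evolutionary timeline (clone tree)
#'
#' Orders the tumor's timed copy-number events and mutation intervals along
#' the trunk (the dominant clone's history) and hangs subclonal items on
#' branches with their cell fractions. Trunk items are sorted by point time:
#' the event's estimated molecular time, or the interval midpoint for
#' mutations; ties break deterministically by (time, label, id). Subclone
#' calls are grouped into branches by cell fraction; fractions spreading more
#' than 0.1 within what would be one branch are split into sibling branches
#' with a warning. The branch point along the trunk is not identifiable from
#' a single biopsy, so branches attach at the end of the trunk.
#'
#' @param events Data.frame of clonal copy-number events: columns `label`
#'   (e.g. `"cn_loh_dup:chr11"`), `chrom`, `event_class`, `t` (molecular
#'   time; untimed events allowed with NA). May be empty or NULL.
#' @param mutation_timings Data.frame of mutation timings: columns `id`,
#'   `multiplicity`, `t_lo`, `t_hi` (from [mutation_interval()]). May be
#'   empty or NULL.
#' @param subclone_calls Data.frame of subclonal items: columns `label`,
#'   `phi` (cell fraction), optional `type`. May be NULL.
#' @param phi_merge Maximum distance from a branch's mean fraction for an
#'   item to join it (default 0.05).
#' @return An object of class `clone_tree`: list with `trunk` (data.frame of
#'   ordered items: `item`, `type`, `label`, `time`, `t_lo`, `t_hi`),
#'   `branches` (list of `phi` + `items`), and `n_items`.
#' @export
build_timeline <- function(events = NULL, mutation_timings = NULL,
                           subclone_calls = NULL, phi_merge = 0.05) {
  rows <- list()
  if (!is.null(events) && nrow(events) > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      item = events$label, type = "cn_event", label = events$label,
      time = events$t, t_lo = events$t, t_hi = events$t,
      stringsAsFactors = FALSE)
  }
  if (!is.null(mutation_timings) && nrow(mutation_timings) > 0) {
    mid <- (mutation_timings$t_lo + mutation_timings$t_hi) / 2
    rows[[length(rows) + 1L]] <- data.frame(
      item = mutation_timings$id, type = "mutation",
      label = mutation_timings$id, time = mid,
      t_lo = mutation_timings$t_lo, t_hi = mutation_timings$t_hi,
      stringsAsFactors = FALSE)
  }
  trunk <- if (length(rows)) do.call(rbind, rows) else
    data.frame(item = character(0), type = character(0),
               label = character(0), time = numeric(0),
               t_lo = numeric(0), t_hi = numeric(0))
  trunk <- trunk[order(trunk$time, trunk$label, trunk$item,
                       na.last = TRUE), , drop = FALSE]
  rownames(trunk) <- NULL

  branches <- list()
  if (!is.null(subclone_calls) && nrow(subclone_calls) > 0) {
    sc <- subclone_calls[order(subclone_calls$phi, subclone_calls$label), ,
                         drop = FALSE]
    cur <- NULL
    for (i in seq_len(nrow(sc))) {
      if (is.null(cur) || abs(sc$phi[i] - mean(cur$phi)) > phi_merge) {
        if (!is.null(cur)) branches[[length(branches) + 1L]] <- cur
        cur <- sc[i, , drop = FALSE]
      } else {
        cur <- rbind(cur, sc[i, , drop = FALSE])
      }
    }
    branches[[length(branches) + 1L]] <- cur
    spread <- diff(range(sc$phi))
    if (length(branches) > 1 && spread > 0.1)
      warning(sprintf(
        "subclone fractions spread %.2f (> 0.1): emitting %d sibling branches",
        spread, length(branches)))
    branches <- lapply(branches, function(b)
      list(phi = mean(b$phi), items = b))
  }

  structure(
    list(trunk = trunk, branches = branches,
         n_items = nrow(trunk) +
           sum(vapply(branches, function(b) nrow(b$items), integer(1)))),
    class = "clone_tree"
  )
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("Clone tree: %d trunk item(s), %d branch(es)\n",
              nrow(x$trunk), length(x$branches)))
  if (nrow(x$trunk)) {
    ev <- x$trunk[x$trunk$type == "cn_event", , drop = FALSE]
    if (nrow(ev)) {
      cat("Trunk copy-number events (molecular time):\n")
      for (i in seq_len(nrow(ev)))
        cat(sprintf("  %5.2f  %s\n", ev$time[i], ev$label[i]))
    }
  }
  for (b in x$branches)
    cat(sprintf("Branch (phi = %.2f): %s\n", b$phi,
                paste(b$items$label, collapse = ", ")))
  invisible(x)
}

#' Serialize a clone tree to Newick
#'
#' Branch lengths are molecular-time spans: the trunk runs from 0 to the time
#' of its last timed event, the dominant clone continues to biopsy (time 1),
#' and each subclone branch (attached at the end of the trunk) also runs to
#' biopsy. Tip labels carry the subclone cell fraction.
#'
#' @param tree A [build_timeline()] result.
#' @return A Newick string (terminated by `;`), readable by
#'   `ape::read.tree`.
#' @export
as_newick <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  times <- tree$trunk$time[tree$trunk$type == "cn_event"]
  t_trunk <- if (length(times) && any(!is.na(times)))
    max(times, na.rm = TRUE) else 0
  tip_len <- 1 - t_trunk
  if (length(tree$branches) == 0)
    return(sprintf("(dominant:%.6g):%.6g;", tip_len, t_trunk))
  tips <- c(sprintf("dominant:%.6g", tip_len),
            vapply(seq_along(tree$branches), function(i)
              sprintf("subclone_%d_phi%.2f:%.6g", i, tree$branches[[i]]$phi,
                      tip_len), character(1)))
  sprintf("(%s):%.6g;", paste(tips, collapse = ","), t_trunk)
}

#' Summarize recurrent lesions across a cohort of clone trees
#'
#' Builds a lesion-by-tumor matrix of occurrence times: a timed copy-number
#' event contributes its point estimate, a mutation the median (midpoint) of
#' its inferred time interval; absent lesions are NA. Copy-number lesions
#' are keyed by their label (use arm- or chromosome-level labels upstream
#' for arm-level aggregation).
#'
#' @param trees Named list of [build_timeline()] results (names = tumor ids).
#' @return A numeric matrix, rows = lesions, columns = tumors, entries =
#'   occurrence time or NA.
#' @export
cohort_summary <- function(trees) {
  stopifnot(length(trees) > 0)
  if (is.null(names(trees)))
    names(trees) <- paste0("tumor", seq_along(trees))
  lesions <- sort(unique(unlist(lapply(trees, function(tr) tr$trunk$label))))
  mat <- matrix(NA_real_, nrow = length(lesions), ncol = length(trees),
                dimnames = list(lesions, names(trees)))
  for (j in seq_along(trees)) {
    tr <- trees[[j]]$trunk
    mat[tr$label, j] <- tr$time
  }
  mat
}
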