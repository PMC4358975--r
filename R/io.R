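#' Read somatic mutations with tumor read counts
#'
#' Reads a somatic SNV table from either a tab-separated file with header
#' `chrom, pos, ref_count, alt_count` (optional `id`, `gene`; `#`-prefixed
#' comment lines allowed) or an uncompressed VCF 4.x file whose genotype
#' field carries per-sample allelic depths (`AD`). Records with zero total
#' depth are dropped with a warning; row order is otherwise preserved.
#'
#' @param path Path to the input file.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @param sample For VCF input, name or index of the tumor sample column
#'   (default 1, the first sample).
#' @return A data.frame with columns `id`, `chrom`, `pos`, `ref_count`,
#'   `alt_count`, `vaf_obs` (`alt / (ref + alt)`) and `gene` (NA when
#'   unannotated).
#' @export
read_mutations <- function(path, dialect = c("tsv", "vcf"), sample = 1L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    req <- c("chrom", "pos", "ref_count", "alt_count")
    if (!all(req %in% names(df)))
      stop("mutation TSV must have header columns: ",
           paste(req, collapse = ", "))
    if (!"id" %in% names(df) || all(is.na(df$id)))
      df$id <- if (nrow(df)) paste0(df$chrom, ":", df$pos) else character(0)
    if (!"gene" %in% names(df)) df$gene <- rep(NA_character_, nrow(df))
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the 'vcfR' package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    ad <- vcfR::extract.gt(v, element = "AD")
    if (is.null(ad) || all(is.na(ad)))
      stop("format error: VCF records carry no AD (allelic depth) field")
    ad <- ad[, sample, drop = TRUE]
    bad <- which(is.na(ad))
    if (length(bad))
      stop("format error: missing AD in record ",
           paste0(fix[bad[1], "CHROM"], ":", fix[bad[1], "POS"]))
    counts <- do.call(rbind, lapply(strsplit(ad, ","), function(x)
      as.integer(x[1:2])))
    df <- data.frame(
      id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                  paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
      chrom = fix[, "CHROM"],
      pos = as.integer(fix[, "POS"]),
      ref_count = counts[, 1],
      alt_count = counts[, 2],
      gene = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  df$pos <- as.integer(df$pos)
  total <- df$ref_count + df$alt_count
  n_zero <- sum(total == 0)
  if (n_zero > 0) {
    warning(sprintf("dropped %d record(s) with zero total depth", n_zero))
    df <- df[total > 0, , drop = FALSE]
    total <- total[total > 0]
  }
  df$vaf_obs <- if (nrow(df)) df$alt_count / total else numeric(0)
  rownames(df) <- NULL
  df[, c("id", "chrom", "pos", "ref_count", "alt_count", "vaf_obs", "gene")]
}

#' Read germline heterozygous sites with tumor read counts
#'
#' Tab-separated file with header `chrom, pos, ref_count, alt_count`, one row
#' per site heterozygous in the matched normal, counts taken from the tumor
#' reads. Zero-depth rows are dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `chrom`, `pos`, `ref_count`,
#'   `alt_count`.
#' @export
read_het_sites <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref_count", "alt_count")
  if (!all(req %in% names(df)))
    stop("het-site TSV must have header columns: ", paste(req, collapse = ", "))
  total <- df$ref_count + df$alt_count
  n_zero <- sum(total == 0)
  if (n_zero > 0) {
    warning(sprintf("dropped %d site(s) with zero total depth", n_zero))
    df <- df[total > 0, , drop = FALSE]
  }
  df$pos <- as.integer(df$pos)
  rownames(df) <- NULL
  df[, req]
}

#' Read copy-number segments
#'
#' Tab-separated file with header `chrom, start, end, cn_obs` and optional
#' `laf_obs`. Coordinates are 0-based half-open. Segments on one chromosome
#' must not overlap. A `laf_obs` above 0.5 is mirrored to `1 - laf_obs` with
#' a warning (the lesser allele fraction is symmetric under allele
#' relabeling).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `length_mb`,
#'   `cn_obs`, `laf_obs` (NA when absent).
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "cn_obs")
  if (!all(req %in% names(df)))
    stop("segment TSV must have header columns: ", paste(req, collapse = ", "))
  if (!"laf_obs" %in% names(df)) df$laf_obs <- rep(NA_real_, nrow(df))
  if (any(df$end <= df$start)) {
    i <- which(df$end <= df$start)[1]
    stop(sprintf("segment with non-positive length: %s:%d-%d",
                 df$chrom[i], df$start[i], df$end[i]))
  }
  if (any(df$cn_obs < 0)) stop("cn_obs must be >= 0")
  hi <- !is.na(df$laf_obs) & df$laf_obs > 0.5
  if (any(hi)) {
    warning(sprintf("%d laf_obs value(s) > 0.5 mirrored to 1 - value", sum(hi)))
    df$laf_obs[hi] <- 1 - df$laf_obs[hi]
  }
  if (any(!is.na(df$laf_obs) & df$laf_obs < 0)) stop("laf_obs must be >= 0")
  # overlap check per chromosome (0-based half-open: touching is allowed)
  for (ch in unique(df$chrom)) {
    s <- df[df$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1) {
      ov <- which(s$start[-1] < s$end[-nrow(s)])
      if (length(ov)) {
        i <- ov[1]
        stop(sprintf(
          "overlapping segments on %s: [%d, %d) and [%d, %d)",
          ch, s$start[i], s$end[i], s$start[i + 1], s$end[i + 1]))
      }
    }
  }
  df$length_mb <- (df$end - df$start) / 1e6
  rownames(df) <- NULL
  df[, c("chrom", "start", "end", "length_mb", "cn_obs", "laf_obs")]
}

#' Write (and re-read) an analysis report
#'
#' Serializes a result object to JSON (arbitrary nested lists/data.frames,
#' written via jsonlite with full numeric precision) or TSV (data.frame
#' only). Reading the written file back reproduces all numeric fields to at
#' least 6 decimals; JSON round-trips are exact to double precision.
#'
#' @param results A list or data.frame of results.
#' @param path Output file path.
#' @param format `"json"` (default) or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(results, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
  } else {
    if (!is.data.frame(results))
      stop("TSV reports require a data.frame")
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
}
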