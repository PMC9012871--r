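#' Depth profiles and fragment lengths
#'
#' A depth profile holds one non-negative count per bin for one sample; the
#' counting unit is the read pair (cfDNA fragment), assigned to the bin
#' containing its leftmost mapped base. Fragment lengths are absolute
#' template lengths of proper pairs.
#'
#' @name coverage
NULL

new_depth_profile <- function(sample_id, counts, scheme) {
  if (length(counts) != n_bins(scheme))
    stop("counts length does not match bin scheme (", length(counts),
         " vs ", n_bins(scheme), ")")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  structure(list(sample_id = sample_id, counts = as.numeric(counts)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth_profile '%s': %d bins, %.0f fragments\n",
              x$sample_id, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Count read pairs per bin from an indexed BAM
#'
#' Each properly paired, MAPQ-passing, non-duplicate pair is counted once in
#' the bin containing the pair's leftmost mapped base (the record with
#' positive template length). Masked bins are still counted; masking is
#' applied downstream.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param scheme a \code{bin_scheme}; chromosome names must match the BAM.
#' @param min_mapq minimum mapping quality (default 20).
#' @param dedup drop duplicate-flagged reads (default TRUE).
#' @param sample_id sample name; defaults to the BAM base name.
#' @return A \code{depth_profile}.
#' @export
count_reads_per_bin <- function(bam, scheme, min_mapq = 20, dedup = TRUE,
                                sample_id = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("count_reads_per_bin requires the Rsamtools package")
  if (is.null(sample_id)) sample_id <- sub("\\.bam$", "", basename(bam))
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  miss <- setdiff(scheme$layout$chrom, names(hdr))
  if (length(miss))
    stop("chromosomes in scheme absent from BAM header: ",
         paste(miss, collapse = ", "))
  flag <- Rsamtools::scanBamFlag(
    isProperPair = TRUE, isUnmappedQuery = FALSE,
    isDuplicate = if (dedup) FALSE else NA,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "mapq", "isize"))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(x$isize) & x$isize > 0 &
    (is.na(x$mapq) | x$mapq >= min_mapq)
  chrom <- as.character(x$rname[keep])
  pos0 <- x$pos[keep] - 1L                      # BAM pos is 1-based
  counts <- numeric(n_bins(scheme))
  for (ch in unique(chrom)) {
    idx <- which(scheme$bins$chrom == ch)
    if (!length(idx)) next
    p <- pos0[chrom == ch]
    j <- findInterval(p, scheme$bins$start[idx])
    j <- j[j >= 1 & p < scheme$bins$end[idx][pmax(j, 1)]]
    tab <- tabulate(j, nbins = length(idx))
    counts[idx] <- counts[idx] + tab
  }
  new_depth_profile(sample_id, counts, scheme)
}

#' Extract cfDNA fragment lengths from an indexed BAM
#'
#' Absolute template lengths of properly paired reads, one per pair (taken
#' from the mate with positive template length), filtered to
#' (0, \code{max_length}].
#'
#' @param bam path to a BAM file with paired-end alignments.
#' @param min_mapq minimum mapping quality (default 20).
#' @param max_length maximum fragment length kept, bases (default 1000,
#'   excluding chimeric artifacts).
#' @param sample_id sample name; defaults to the BAM base name.
#' @return A \code{fragment_lengths} object (sample_id, integer lengths).
#' @export
extract_fragment_lengths <- function(bam, min_mapq = 20, max_length = 1000,
                                     sample_id = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("extract_fragment_lengths requires the Rsamtools package")
  if (is.null(sample_id)) sample_id <- sub("\\.bam$", "", basename(bam))
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE, isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("mapq", "isize", "flag"))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (!length(x$isize) || all(is.na(x$isize) | x$isize == 0))
    stop("no paired-end template lengths found; fragment length undefined ",
         "for single-end data")
  keep <- !is.na(x$isize) & x$isize > 0 & (is.na(x$mapq) | x$mapq >= min_mapq)
  len <- x$isize[keep]
  len <- len[len <= max_length]
  fragment_lengths(sample_id, len)
}

#' Construct a fragment-lengths container
#' @param sample_id sample name.
#' @param lengths integer fragment lengths in bases (> 0).
#' @export
fragment_lengths <- function(sample_id, lengths) {
  lengths <- as.integer(lengths)
  if (any(lengths <= 0)) stop("fragment lengths must be positive")
  structure(list(sample_id = sample_id, lengths = lengths),
            class = "fragment_lengths")
}

#' @export
print.fragment_lengths <- function(x, ...) {
  cat(sprintf("fragment_lengths '%s': %d fragments, median %d bp\n",
              x$sample_id, length(x$lengths),
              as.integer(stats::median(x$lengths))))
  invisible(x)
}

#' Write / read a depth matrix TSV
#'
#' The table has bin key columns (chrom, start, end) followed by one numeric
#' column per sample; the round trip is lossless and the bin order is
#' validated against the scheme on read.
#'
#' @param profiles list of \code{depth_profile}s on one scheme.
#' @param scheme the shared \code{bin_scheme}.
#' @param path output path.
#' @export
write_depth_table <- function(profiles, scheme, path) {
  if (inherits(profiles, "depth_profile")) profiles <- list(profiles)
  df <- scheme$bins[, c("chrom", "start", "end")]
  for (p in profiles) {
    if (length(p$counts) != n_bins(scheme)) stop("profile/scheme mismatch")
    df[[p$sample_id]] <- p$counts
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_table
#' @return \code{load_depth_table}: a named list of \code{depth_profile}s in
#'   column order.
#' @export
load_depth_table <- function(path, scheme) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(x) != n_bins(scheme))
    stop("depth table has ", nrow(x), " rows but scheme has ",
         n_bins(scheme), " bins")
  same <- x$chrom == scheme$bins$chrom & x$start == scheme$bins$start &
    x$end == scheme$bins$end
  if (!all(same)) {
    bad <- which(!same)[1]
    stop("bin mismatch at row ", bad, ": ", x$chrom[bad], ":", x$start[bad],
         "-", x$end[bad])
  }
  samples <- setdiff(colnames(x), c("chrom", "start", "end"))
  out <- lapply(samples, function(s) {
    v <- x[[s]]
    if (!is.numeric(v)) stop("non-numeric counts in column ", s)
    new_depth_profile(s, v, scheme)
  })
  names(out) <- samples
  out
}

#' Write / read fragment lengths as a one-column TSV
#' @param fl a \code{fragment_lengths} object.
#' @param path file path.
#' @export
write_fragment_lengths <- function(fl, path) {
  writeLines(c("length", as.character(fl$lengths)), path)
  invisible(path)
}

#' @rdname write_fragment_lengths
#' @param sample_id sample name for the loaded object.
#' @export
load_fragment_lengths <- function(path, sample_id = basename(path)) {
  x <- utils::read.table(path, header = TRUE)
  fragment_lengths(sample_id, x$length)
}
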