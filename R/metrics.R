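#' Method-comparison segment metrics
#'
#' Quantifies how the two segmentation arms differ: number of segments,
#' segment-length distribution, and the precision of copy-number assignment
#' measured as the standard deviation of log2 depth across the bins assigned
#' to one segment (smaller = more internally homogeneous segments).
#'
#' @name segment_metrics
NULL

#' Summarize segments of one sample
#'
#' @param profile the \code{normalized_profile} the segments were fit on.
#' @param segset a \code{segment_set} carrying \code{bin_from}/\code{bin_to}
#'   member-bin indices.
#' @return A \code{segment_summary}: sample_id, method_tag, n_segments,
#'   segment_lengths (bases), within_segment_sds (sample SD, denominator
#'   n-1; single-bin segments contribute SD 0 and are counted in
#'   \code{n_single_bin}).
#' @export
summarize_segments <- function(profile, segset) {
  s <- segset$segments
  if (!all(c("bin_from", "bin_to") %in% names(s)))
    stop("segment set lacks member-bin indices (bin_from/bin_to)")
  sds <- vapply(seq_len(nrow(s)), function(i) {
    mem <- s$bin_from[i]:s$bin_to[i]
    mem <- mem[profile$valid[mem]]
    if (!length(mem)) stop("segment ", i, " covers only masked bins")
    if (length(mem) == 1) return(0)
    stats::sd(profile$log2_ratio[mem])
  }, 0)
  structure(list(sample_id = segset$sample_id,
                 method_tag = segset$method_tag,
                 n_segments = nrow(s),
                 segment_lengths = s$end - s$start,
                 within_segment_sds = sds,
                 n_single_bin = sum(s$n_bins == 1)),
            class = "segment_summary")
}

#' @export
print.segment_summary <- function(x, ...) {
  cat(sprintf(paste0("segment_summary '%s' [%s]: %d segments, median ",
                     "length %.0f, median within-segment SD %.4f\n"),
              x$sample_id, x$method_tag, x$n_segments,
              stats::median(x$segment_lengths),
              stats::median(x$within_segment_sds)))
  invisible(x)
}

#' Compare within-segment variability between two methods
#'
#' Pools one SD per segment from each method and applies a two-sided
#' Mann-Whitney U test; reports both medians.
#'
#' @param sds_a,sds_b within-segment SDs for methods A and B (either bare
#'   numeric vectors or lists of \code{segment_summary} objects to pool).
#' @return A test result (see \code{\link{rank_sum_test}}) with an extra
#'   \code{medians} field \code{c(a = ..., b = ...)}.
#' @export
compare_methods <- function(sds_a, sds_b) {
  pool <- function(x) {
    if (is.numeric(x)) return(x)
    if (inherits(x, "segment_summary")) x <- list(x)
    unlist(lapply(x, function(s) s$within_segment_sds), use.names = FALSE)
  }
  a <- pool(sds_a); b <- pool(sds_b)
  res <- rank_sum_test(a, b)
  res$medians <- c(a = stats::median(a), b = stats::median(b))
  res
}
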