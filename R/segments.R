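#' Segment sets
#'
#' A segment set holds contiguous runs of bins sharing one copy state for
#' one sample: chrom, genomic span, number of member bins, mean log2 ratio,
#' and copy state. \code{bin_from}/\code{bin_to} index the member bins in
#' the scheme's genome-wide bin order (1-based, inclusive) and make
#' within-segment statistics exact even when masked bins interleave.
#'
#' @param sample_id sample name.
#' @param method_tag \code{"cbs_arm"} or \code{"hmm_arm"}.
#' @param segments data.frame with columns chrom, start, end, n_bins,
#'   mean_log2, copy_state (and optionally bin_from, bin_to, copy_number).
#' @return An object of class \code{segment_set}.
#' @export
segment_set <- function(sample_id, method_tag, segments) {
  stopifnot(method_tag %in% c("cbs_arm", "hmm_arm"))
  need <- c("chrom", "start", "end", "n_bins", "mean_log2", "copy_state")
  if (!all(need %in% names(segments)))
    stop("segments missing columns: ",
         paste(setdiff(need, names(segments)), collapse = ", "))
  rownames(segments) <- NULL
  structure(list(sample_id = sample_id, method_tag = method_tag,
                 segments = segments),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  s <- x$segments
  cat(sprintf("segment_set '%s' [%s]: %d segments (%d gain, %d loss)\n",
              x$sample_id, x$method_tag, nrow(s),
              sum(s$copy_state == "gain"), sum(s$copy_state == "loss")))
  invisible(x)
}

#' Assign copy states to segments by log2 thresholds
#'
#' @param segset a \code{segment_set}.
#' @param gain_threshold log2 at or above which a segment is a gain
#'   (default 0.2, roughly one copy gained at ~30\% tumor fraction).
#' @param loss_threshold log2 at or below which a segment is a loss
#'   (default -0.2).
#' @return The set with \code{copy_state} in {loss, neutral, gain}.
#' @export
assign_copy_states <- function(segset, gain_threshold = 0.2,
                               loss_threshold = -0.2) {
  if (!(loss_threshold < 0 && 0 < gain_threshold))
    stop("need loss_threshold < 0 < gain_threshold")
  m <- segset$segments$mean_log2
  segset$segments$copy_state <-
    ifelse(m >= gain_threshold, "gain",
           ifelse(m <= loss_threshold, "loss", "neutral"))
  segset
}

#' Merge adjacent same-state segments
#'
#' Adjacent segments on one chromosome with the same copy state are merged;
#' the merged mean is the bin-count-weighted mean. Idempotent.
#'
#' @param segset a \code{segment_set} with states assigned.
#' @return A \code{segment_set}.
#' @export
merge_adjacent_same_state <- function(segset) {
  s <- segset$segments
  if (nrow(s) < 2) return(segset)
  new_run <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)] |
                 s$copy_state[-1] != s$copy_state[-nrow(s)])
  run <- cumsum(new_run)
  merged <- do.call(rbind, lapply(split(seq_len(nrow(s)), run), function(i) {
    part <- s[i, , drop = FALSE]
    out <- part[1, , drop = FALSE]
    out$end <- part$end[nrow(part)]
    out$n_bins <- sum(part$n_bins)
    out$mean_log2 <- sum(part$mean_log2 * part$n_bins) / out$n_bins
    if ("bin_to" %in% names(part)) out$bin_to <- part$bin_to[nrow(part)]
    out
  }))
  rownames(merged) <- NULL
  segset$segments <- merged
  segset
}

#' Write segment sets in SEG format
#'
#' Standard SEG columns (sample, chrom, start, end, markers, mean log2) with
#' 1-based inclusive coordinates, plus a copy_state column.
#'
#' @param segsets a \code{segment_set} or list of them.
#' @param path output path.
#' @export
write_seg <- function(segsets, path) {
  if (inherits(segsets, "segment_set")) segsets <- list(segsets)
  rows <- do.call(rbind, lapply(segsets, function(ss) {
    s <- ss$segments
    data.frame(ID = ss$sample_id, chrom = s$chrom,
               loc.start = format(s$start + 1, scientific = FALSE, trim = TRUE),
               loc.end = format(s$end, scientific = FALSE, trim = TRUE),
               num.mark = s$n_bins, seg.mean = round(s$mean_log2, 6),
               copy_state = s$copy_state, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a (possibly multi-sample) SEG file
#' @param path SEG path as written by \code{write_seg}.
#' @param method_tag tag to attach to each returned set.
#' @return A named list of \code{segment_set}s.
#' @export
read_seg <- function(path, method_tag = "cbs_arm") {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  lapply(split(x, x$ID)[unique(x$ID)], function(part) {
    segment_set(part$ID[1], method_tag,
                data.frame(chrom = part$chrom,
                           start = as.numeric(part$loc.start) - 1,
                           end = as.numeric(part$loc.end),
                           n_bins = part$num.mark,
                           mean_log2 = part$seg.mean,
                           copy_state = if ("copy_state" %in% names(part))
                             part$copy_state else "neutral",
                           stringsAsFactors = FALSE))
  })
}
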