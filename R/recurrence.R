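#' Cohort recurrence scoring
#'
#' GISTIC-style analysis of recurrent gains and losses over per-sample
#' segment sets: the per-bin G score is frequency times mean amplitude
#' (equivalently, the sum over samples of the matching-direction amplitude
#' divided by cohort size), and significance comes from a cyclic-shift
#' permutation null that preserves each sample's segment-length structure.
#'
#' @name recurrence
NULL

#' Pick the highest-tumor-fraction sample per subject
#'
#' @param samples data.frame with columns \code{dog_id}, \code{sample_id},
#'   \code{tumor_fraction}, and optionally \code{date} (tie-break: earliest
#'   date, then sample_id).
#' @return One row per dog: the argmax-tumor-fraction sample.
#' @export
select_max_tf_sample <- function(samples) {
  need <- c("dog_id", "sample_id", "tumor_fraction")
  if (!all(need %in% names(samples)))
    stop("need columns: ", paste(need, collapse = ", "))
  if (!"date" %in% names(samples)) samples$date <- 0
  picked <- lapply(split(samples, samples$dog_id), function(part) {
    part <- part[order(-part$tumor_fraction, part$date, part$sample_id), ]
    part[1, , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

# per-bin amplitude of one sample in one direction: the covering segment's
# |mean_log2| when its state matches the direction, else 0
sample_amplitude <- function(segset, scheme, direction) {
  amp <- numeric(n_bins(scheme))
  s <- segset$segments
  match_state <- s$copy_state == direction
  for (i in which(match_state)) {
    if (all(c("bin_from", "bin_to") %in% names(s))) {
      mem <- s$bin_from[i]:s$bin_to[i]
    } else {
      mem <- which(scheme$bins$chrom == s$chrom[i] &
                     scheme$bins$start >= s$start[i] &
                     scheme$bins$end <= s$end[i])
    }
    a <- if (direction == "gain") max(s$mean_log2[i], 0)
         else max(-s$mean_log2[i], 0)
    amp[mem] <- a
  }
  amp
}

#' Per-bin G scores for one direction
#'
#' @param segment_sets list of \code{segment_set}s with states assigned, all
#'   on one scheme (one set per subject).
#' @param scheme the shared \code{bin_scheme}.
#' @param direction \code{"gain"} or \code{"loss"}.
#' @return A \code{recurrence_track}: per-bin g_score, the per-sample
#'   amplitude matrix (bins x samples, retained for the permutation null),
#'   and bin coordinates.
#' @export
gscore <- function(segment_sets, scheme, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  if (!length(segment_sets)) stop("empty cohort")
  ids <- vapply(segment_sets, function(s) s$sample_id, "")
  segment_sets <- segment_sets[order(ids)]   # deterministic sample order
  amp <- vapply(segment_sets,
                function(s) sample_amplitude(s, scheme, direction),
                numeric(n_bins(scheme)))
  structure(list(direction = direction,
                 chrom = scheme$bins$chrom,
                 start = scheme$bins$start, end = scheme$bins$end,
                 g_score = rowMeans(amp), amp = amp,
                 sample_ids = sort(ids),
                 perm_p = NULL, q_value = NULL, significant_regions = NULL),
            class = "recurrence_track")
}

#' @export
print.recurrence_track <- function(x, ...) {
  cat(sprintf("recurrence_track [%s]: %d bins, %d samples, max G = %.3f\n",
              x$direction, length(x$g_score), ncol(x$amp), max(x$g_score)))
  if (!is.null(x$significant_regions))
    cat(sprintf("  %d significant regions (q <= threshold)\n",
                nrow(x$significant_regions)))
  invisible(x)
}

#' Permutation significance for a recurrence track
#'
#' The null cyclically shifts each sample's per-bin amplitude vector within
#' each chromosome by an independent uniform offset, preserving segment
#' lengths and amplitudes while destroying positional recurrence. Per-bin
#' p = (1 + #{null G >= observed G}) / (1 + n_perm); q by Benjamini-Hochberg
#' across bins; significant regions are maximal runs of bins with
#' q <= \code{q_threshold}.
#'
#' @param track a \code{recurrence_track} from \code{\link{gscore}}.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed RNG seed.
#' @param q_threshold FDR threshold for region extraction (default 0.25).
#' @return The track with perm_p, q_value, significant_regions filled.
#' @export
permutation_significance <- function(track, n_perm = 1000, seed = 1,
                                     q_threshold = 0.25) {
  if (n_perm < 100) stop("need at least 100 permutations")
  amp <- track$amp
  nb <- nrow(amp); ns <- ncol(amp)
  chrom_idx <- split(seq_len(nb), factor(track$chrom, unique(track$chrom)))
  obs <- track$g_score
  exceed <- numeric(nb)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      gnull <- numeric(nb)
      for (s in seq_len(ns)) {
        v <- amp[, s]
        for (ci in chrom_idx) {
          k <- length(ci)
          off <- sample.int(k, 1) - 1L
          if (off > 0) v[ci] <- v[ci][c((k - off + 1):k, 1:(k - off))]
        }
        gnull <- gnull + v
      }
      gnull <- gnull / ns
      exceed <- exceed + (gnull >= obs - 1e-12)
    }
  })
  track$perm_p <- (1 + exceed) / (1 + n_perm)
  track$q_value <- stats::p.adjust(track$perm_p, method = "BH")
  sig <- track$q_value <= q_threshold & obs > 0
  track$significant_regions <- extract_regions(track, sig)
  track
}

extract_regions <- function(track, sig) {
  if (!any(sig)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), peak_g = numeric()))
  }
  brk <- cumsum(c(TRUE, diff(which(sig)) != 1 |
                    track$chrom[which(sig)][-1] !=
                    track$chrom[which(sig)][-sum(sig)]))
  runs <- split(which(sig), brk)
  out <- do.call(rbind, lapply(runs, function(i) {
    data.frame(chrom = track$chrom[i[1]], start = track$start[i[1]],
               end = track$end[i[length(i)]],
               peak_g = max(track$g_score[i]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a recurrence track as per-bin TSV (and regions as BED)
#' @param track a scored \code{recurrence_track}.
#' @param path per-bin TSV output path.
#' @param bed_path optional BED path for significant regions.
#' @export
write_recurrence_tsv <- function(track, path, bed_path = NULL) {
  df <- data.frame(chrom = track$chrom, start = track$start,
                   end = track$end, g_score = track$g_score)
  if (!is.null(track$perm_p)) {
    df$perm_p <- track$perm_p
    df$q_value <- track$q_value
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path) && !is.null(track$significant_regions)) {
    r <- track$significant_regions
    utils::write.table(
      data.frame(r$chrom, format(r$start, scientific = FALSE, trim = TRUE),
                 format(r$end, scientific = FALSE, trim = TRUE),
                 sprintf("%s_region_%d", track$direction, seq_len(nrow(r))),
                 r$peak_g),
      bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  invisible(path)
}
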