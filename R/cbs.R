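#' Circular binary segmentation
#'
#' Recursive changepoint detection on ordered bin log2 ratios. At each step
#' the maximal two-sample t statistic over circular arcs of the current
#' segment is compared against its permutation distribution; a significant
#' arc splits the segment (into up to three pieces) and the pieces are
#' re-examined until no significant split remains.
#'
#' @name cbs
NULL

# run body with a deterministic RNG stream, restoring the caller's stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# significance of the best arc of x by permutation, with early stopping
cbs_test_split <- function(x, alpha, n_perm) {
  obs <- .cbs_max_t(x)
  n <- length(x)
  # exceedances at which p = (1+exceed)/(1+n_perm) is guaranteed > alpha
  stop_at <- floor(alpha * (1 + n_perm))
  if (stop_at < 1) stop_at <- 1
  idx <- vapply(seq_len(n_perm), function(i) sample.int(n) - 1L,
                integer(n))
  r <- .cbs_perm_count(x, idx, obs$t, stop_at)
  significant <- r$used == n_perm && (1 + r$exceed) / (1 + n_perm) <= alpha
  list(significant = significant, i = obs$i, j = obs$j, t = obs$t)
}

# recursively segment one chromosome's value vector; returns a list of
# (from, to) index ranges into x
cbs_recurse <- function(x, from, to, alpha, n_perm) {
  n <- to - from + 1
  if (n < 2) return(list(c(from, to)))
  r <- cbs_test_split(x[from:to], alpha, n_perm)
  if (!r$significant) return(list(c(from, to)))
  cuts <- sort(unique(c(0, r$i, r$j, n)))
  pieces <- list()
  for (k in seq_len(length(cuts) - 1)) {
    a <- from + cuts[k]
    b <- from + cuts[k + 1] - 1
    pieces <- c(pieces, cbs_recurse(x, a, b, alpha, n_perm))
  }
  pieces
}

#' Segment a normalized profile by CBS
#'
#' @param profile a \code{normalized_profile}.
#' @param scheme the matching \code{bin_scheme}.
#' @param alpha permutation significance level for accepting a split
#'   (default 0.01).
#' @param n_perm permutations per tested split (default 1000).
#' @param seed RNG seed for the permutation stream (default 1).
#' @param merge_threshold optional pruning: after state assignment, adjacent
#'   segments whose means differ by less than this are merged. NULL (default)
#'   disables pruning.
#' @return A \code{segment_set} (method_tag \code{"cbs_arm"}) whose segments
#'   cover every valid bin of every analyzed chromosome; copy_state is
#'   \code{"neutral"} pending \code{\link{assign_copy_states}}.
#' @export
segment_cbs <- function(profile, scheme, alpha = 0.01, n_perm = 1000,
                        seed = 1, merge_threshold = NULL) {
  stopifnot(inherits(profile, "normalized_profile"))
  valid <- which(profile$valid)
  if (!length(valid)) stop("no valid bins to segment")
  segs <- with_seed(seed, {
    out <- list()
    for (ch in unique(scheme$bins$chrom[valid])) {
      idx <- valid[scheme$bins$chrom[valid] == ch]
      x <- profile$log2_ratio[idx]
      ranges <- if (length(x) < 2) list(c(1, length(x)))
        else cbs_recurse(x, 1, length(x), alpha, n_perm)
      for (rg in ranges) {
        mem <- idx[rg[1]:rg[2]]
        out[[length(out) + 1]] <- data.frame(
          chrom = ch,
          start = scheme$bins$start[mem[1]],
          end = scheme$bins$end[mem[length(mem)]],
          n_bins = length(mem),
          mean_log2 = mean(profile$log2_ratio[mem]),
          copy_state = "neutral",
          bin_from = mem[1], bin_to = mem[length(mem)],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  ss <- segment_set(profile$sample_id, "cbs_arm", segs)
  if (!is.null(merge_threshold)) {
    s <- ss$segments
    if (nrow(s) > 1) {
      # merge adjacent segments with near-equal means (optional pruning)
      repeat {
        d <- abs(diff(s$mean_log2))
        same_chr <- s$chrom[-1] == s$chrom[-nrow(s)]
        cand <- which(d < merge_threshold & same_chr)
        if (!length(cand)) break
        k <- cand[1]
        nb <- s$n_bins[k] + s$n_bins[k + 1]
        s$mean_log2[k] <- (s$mean_log2[k] * s$n_bins[k] +
                             s$mean_log2[k + 1] * s$n_bins[k + 1]) / nb
        s$n_bins[k] <- nb
        s$end[k] <- s$end[k + 1]
        s$bin_to[k] <- s$bin_to[k + 1]
        s <- s[-(k + 1), , drop = FALSE]
        if (nrow(s) < 2) break
      }
      rownames(s) <- NULL
      ss$segments <- s
    }
  }
  ss
}
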