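#' Bin schemes
#'
#' A bin scheme is the coordinate scaffold for all depth analysis: an ordered
#' set of non-overlapping genomic bins annotated with GC fraction and
#' mappable-base counts. Two scheme kinds are supported, mirroring the two
#' informatic arms compared here: \code{fixed_width} bins (the HMM arm) and
#' \code{equal_mappable} bins, a fixed total number of bins whose boundaries
#' are placed so every bin holds approximately the same number of usable
#' (mappable) bases.
#'
#' Coordinates are 0-based half-open throughout; SEG export converts to
#' 1-based inclusive.
#'
#' @name bin_scheme
NULL

new_bin_scheme <- function(layout, bins, scheme_kind) {
  stopifnot(scheme_kind %in% c("fixed_width", "equal_mappable"))
  rownames(bins) <- NULL
  structure(list(layout = layout, bins = bins, scheme_kind = scheme_kind),
            class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("bin_scheme <%s>: %d bins over %d chromosomes (%d masked)\n",
              x$scheme_kind, nrow(x$bins), nrow(x$layout),
              sum(x$bins$masked)))
  invisible(x)
}

#' Number of bins in a scheme
#' @param scheme a \code{bin_scheme}.
#' @export
n_bins <- function(scheme) nrow(scheme$bins)

empty_bin_cols <- function(df) {
  df$gc <- NA_real_
  df$mappable_bases <- df$end - df$start
  df$masked <- FALSE
  df
}

#' Tile a genome with fixed-width bins
#'
#' Each chromosome is tiled left to right with \code{width}-sized bins; the
#' final bin of a chromosome may be shorter. This is the scaffold used by the
#' HMM arm (500 kb default in the pipeline configuration).
#'
#' @param layout a \code{genome_layout}.
#' @param width bin width in bases (> 0).
#' @return A \code{bin_scheme} with \code{scheme_kind = "fixed_width"}.
#' @examples
#' build_fixed_bins(genome_layout("chr1", 1234567), 500000)
#' @export
build_fixed_bins <- function(layout, width = 500000) {
  if (!inherits(layout, "genome_layout")) stop("layout must be a genome_layout")
  if (length(width) != 1L || !is.finite(width) || width <= 0)
    stop("width must be a single positive number")
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    starts <- seq(0, len - 1, by = width)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = pmin(starts + width, len), stringsAsFactors = FALSE)
  })
  bins <- empty_bin_cols(do.call(rbind, pieces))
  new_bin_scheme(layout, bins, "fixed_width")
}

# cumulative usable bases per chromosome from a mappability track;
# returns list(starts, ends, rates, cum) with cum[i] = usable bases before
# interval i
usable_cumsum <- function(tr) {
  o <- order(tr$start)
  tr <- tr[o, , drop = FALSE]
  w <- (tr$end - tr$start) * tr$value
  list(start = tr$start, end = tr$end, rate = tr$value,
       cum = c(0, cumsum(w)), total = sum(w))
}

# position (whole base) where cumulative usable bases first reaches target;
# inside a zero-mappability run the cumsum is flat, so the position returned
# is the run's left edge
position_at_usable <- function(cs, target) {
  if (target <= 0) return(cs$start[1])
  i <- findInterval(target, cs$cum, left.open = TRUE)
  i <- min(i, length(cs$start))
  need <- target - cs$cum[i]
  if (cs$rate[i] <= 0) return(cs$start[i])
  min(cs$start[i] + ceiling(need / cs$rate[i]), cs$end[i])
}

#' Build equal-mappable-base bins
#'
#' Places exactly \code{n_bins} bins genome-wide so that every bin contains
#' as close as achievable to (total usable bases)/\code{n_bins} usable bases,
#' given whole-base boundaries and chromosome breaks. Bins never span
#' chromosomes. Bins are apportioned to chromosomes proportionally to their
#' usable bases (largest-remainder rounding, ties broken by chromosome
#' order); boundaries within a chromosome are placed at cumulative
#' usable-base quantiles. Chromosomes with zero usable bases receive no bins
#' (a message is emitted).
#'
#' @param layout a \code{genome_layout}.
#' @param mappability track data.frame (chrom, start, end, value in [0,1]),
#'   usable bases per base; see \code{\link{read_track}}.
#' @param n_bins total number of bins requested (returned exactly).
#' @return A \code{bin_scheme} with \code{scheme_kind = "equal_mappable"};
#'   \code{mappable_bases} is filled from the track.
#' @export
build_adaptive_bins <- function(layout, mappability, n_bins = 5500) {
  if (!inherits(layout, "genome_layout")) stop("layout must be a genome_layout")
  trs <- track_by_chrom(mappability, layout)
  css <- lapply(trs, function(tr) if (nrow(tr)) usable_cumsum(tr) else NULL)
  totals <- vapply(css, function(cs) if (is.null(cs)) 0 else cs$total, 0)
  grand <- sum(totals)
  if (grand <= 0) stop("mappability track has no usable bases")
  if (n_bins > grand) stop("n_bins exceeds total usable bases")
  usable_chroms <- which(totals > 0)
  if (n_bins < length(usable_chroms))
    stop("n_bins smaller than the number of chromosomes with usable bases")
  if (length(usable_chroms) < nrow(layout))
    message("chromosomes with zero usable bases receive no bins: ",
            paste(layout$chrom[totals <= 0], collapse = ", "))

  # largest-remainder apportionment, >= 1 bin per usable chromosome
  quota <- totals / grand * n_bins
  alloc <- pmax(floor(quota), ifelse(totals > 0, 1, 0))
  rem <- quota - floor(quota)
  short <- n_bins - sum(alloc)
  if (short > 0) {
    ord <- order(-rem, seq_along(rem))    # ties broken by chromosome order
    ord <- ord[totals[ord] > 0]
    add <- ord[seq_len(short)]
    alloc[add] <- alloc[add] + 1
  } else if (short < 0) {
    ord <- order(rem, -seq_along(rem))
    ord <- ord[alloc[ord] > 1]
    take <- ord[seq_len(-short)]
    alloc[take] <- alloc[take] - 1
  }
  stopifnot(sum(alloc) == n_bins)

  pieces <- lapply(usable_chroms, function(i) {
    cs <- css[[i]]
    k <- alloc[i]
    targets <- cs$total * seq_len(k - 1) / k
    cuts <- vapply(targets, function(t) position_at_usable(cs, t), 0)
    lo <- cs$start[1]
    hi <- cs$end[length(cs$end)]
    starts <- c(lo, cuts)
    ends <- c(cuts, hi)
    keep <- ends > starts
    data.frame(chrom = layout$chrom[i], start = starts[keep],
               end = ends[keep], stringsAsFactors = FALSE)
  })
  bins <- empty_bin_cols(do.call(rbind, pieces))
  if (nrow(bins) != n_bins)
    stop("degenerate mappability track: boundary collisions left ",
         nrow(bins), " bins instead of ", n_bins)
  sc <- new_bin_scheme(layout, bins, "equal_mappable")
  # fill mappable_bases from the track so the scheme is self-describing
  sc$bins$mappable_bases <- bin_track_sum(sc, mappability)
  sc
}

# sum of value*overlap over track intervals for every bin
bin_track_sum <- function(scheme, track) {
  out <- numeric(nrow(scheme$bins))
  trs <- split(track, track$chrom)
  for (ch in names(trs)) {
    idx <- which(scheme$bins$chrom == ch)
    if (!length(idx)) next
    tr <- trs[[ch]]
    o <- order(tr$start)
    ts <- tr$start[o]; te <- tr$end[o]; tv <- tr$value[o]
    bs <- scheme$bins$start[idx]; be <- scheme$bins$end[idx]
    # intervals are short relative to bins in practice: loop over bins,
    # vectorized overlap with the interval range each bin touches
    lo <- findInterval(bs, te, left.open = TRUE) + 1L
    hi <- findInterval(be - 1e-9, ts)
    out[idx] <- vapply(seq_along(idx), function(j) {
      if (lo[j] > hi[j]) return(0)
      k <- lo[j]:hi[j]
      sum(tv[k] * (pmin(te[k], be[j]) - pmax(ts[k], bs[j])))
    }, 0)
  }
  out
}

#' Annotate bins with GC fraction and mappable bases
#'
#' GC per bin is the overlap-weighted mean of the GC track over the bin;
#' mappable bases are the integral of the mappability track. Bins with no GC
#' coverage (e.g. all-N sequence) are flagged \code{masked}.
#'
#' @param scheme a \code{bin_scheme}.
#' @param gc_track track data.frame with per-interval GC fraction in [0,1].
#' @param mappability_track track data.frame with usable-base fraction.
#' @return The scheme with \code{gc}, \code{mappable_bases}, \code{masked}
#'   filled in.
#' @export
annotate_bins <- function(scheme, gc_track, mappability_track) {
  covered <- bin_track_sum(scheme, transform(gc_track, value = 1))
  gcsum <- bin_track_sum(scheme, gc_track)
  gc <- ifelse(covered > 0, gcsum / covered, NA_real_)
  if (any(gc < -1e-9 | gc > 1 + 1e-9, na.rm = TRUE))
    stop("GC track yields bin GC outside [0,1]; coordinate mismatch?")
  scheme$bins$gc <- pmin(pmax(gc, 0), 1)
  scheme$bins$mappable_bases <- bin_track_sum(scheme, mappability_track)
  scheme$bins$masked <- scheme$bins$masked | is.na(gc)
  scheme
}

#' Mask bins by mappable fraction
#'
#' Bins whose mappable fraction falls below \code{min_mappable_fraction} are
#' flagged masked. Masked bins are excluded from all downstream statistics
#' but retained in coordinates.
#'
#' @param scheme a \code{bin_scheme} with \code{mappable_bases} filled.
#' @param min_mappable_fraction threshold in [0,1]; default 0.9.
#' @return The scheme with \code{masked} updated (previous masks are kept).
#' @export
mask_bins <- function(scheme, min_mappable_fraction = 0.9) {
  if (min_mappable_fraction < 0 || min_mappable_fraction > 1)
    stop("min_mappable_fraction must lie in [0,1]")
  frac <- scheme$bins$mappable_bases / (scheme$bins$end - scheme$bins$start)
  scheme$bins$masked <- scheme$bins$masked | (frac < min_mappable_fraction)
  scheme
}

#' Write bins as BED4+
#'
#' Columns: chrom, start, end, name, gc, mappable_bases, masked (0/1).
#' @param scheme a \code{bin_scheme}.
#' @param path output path.
#' @export
write_bins_bed <- function(scheme, path) {
  b <- scheme$bins
  df <- data.frame(b$chrom,
                   format(b$start, scientific = FALSE, trim = TRUE),
                   format(b$end, scientific = FALSE, trim = TRUE),
                   sprintf("bin_%06d", seq_len(nrow(b))),
                   ifelse(is.na(b$gc), ".", format(b$gc, digits = 6)),
                   format(b$mappable_bases, scientific = FALSE, trim = TRUE),
                   as.integer(b$masked))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#scheme_kind=%s", scheme$scheme_kind), con)
  for (i in seq_len(nrow(scheme$layout)))
    writeLines(sprintf("#chrom\t%s\t%s", scheme$layout$chrom[i],
                       format(scheme$layout$length[i], scientific = FALSE)),
               con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read bins written by \code{write_bins_bed}
#' @param path BED4+ path.
#' @return A \code{bin_scheme}.
#' @export
read_bins_bed <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kind <- sub("#scheme_kind=", "", hdr[startsWith(hdr, "#scheme_kind=")])
  chrlines <- strsplit(hdr[startsWith(hdr, "#chrom")], "\t")
  layout <- genome_layout(vapply(chrlines, `[`, "", 2),
                          as.numeric(vapply(chrlines, `[`, "", 3)))
  body <- lines[!startsWith(lines, "#")]
  x <- utils::read.table(text = body, sep = "\t", stringsAsFactors = FALSE)
  bins <- data.frame(chrom = x[[1]], start = as.numeric(x[[2]]),
                     end = as.numeric(x[[3]]),
                     gc = suppressWarnings(as.numeric(x[[5]])),
                     mappable_bases = as.numeric(x[[6]]),
                     masked = as.logical(as.integer(x[[7]])),
                     stringsAsFactors = FALSE)
  new_bin_scheme(layout, bins, kind)
}

# indices of bins used for analysis: unmasked, autosomes only if requested
analyzed_bins <- function(scheme, autosomes_only = TRUE) {
  keep <- !scheme$bins$masked
  if (autosomes_only) {
    sex <- grepl("^(chr)?[XYxy]$", scheme$bins$chrom)
    keep <- keep & !sex
  }
  which(keep)
}
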