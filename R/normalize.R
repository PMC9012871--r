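#' GC correction and panel-of-normals normalization
#'
#' Raw bin counts carry a smooth bias with GC content and bin-specific
#' systematic effects (mappability, replication timing). GC bias is removed
#' by dividing out a local-regression curve of count versus GC; systematic
#' bin effects are removed by the panel of normals, a per-bin reference level
#' built from healthy-plasma control samples. The result is a per-bin log2
#' depth ratio, median-centered over unmasked autosomal bins.
#'
#' @name normalize
NULL

#' Correct GC bias in a depth profile
#'
#' Fits a loess curve (span \code{span}) of count versus GC over unmasked
#' autosomal bins, divides predictions out, and rescales so the total count
#' is conserved. If all bins share one GC value the correction is the
#' identity (with a warning).
#'
#' @param profile a \code{depth_profile}.
#' @param scheme the \code{bin_scheme} with GC annotated.
#' @param span loess span (default 0.3).
#' @return A GC-corrected \code{depth_profile}.
#' @export
correct_gc <- function(profile, scheme, span = 0.3) {
  idx <- analyzed_bins(scheme)
  idx <- idx[!is.na(scheme$bins$gc[idx])]
  if (length(idx) < 50) stop("need at least 50 unmasked bins for GC fitting")
  gc <- scheme$bins$gc[idx]
  y <- profile$counts[idx]
  if (diff(range(gc)) < 1e-9) {
    warning("all bins share one GC value; GC correction is the identity")
    return(profile)
  }
  fit <- stats::loess(y ~ gc, span = span, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  pred_at <- function(g) {
    g <- pmin(pmax(g, min(gc)), max(gc))    # clamp extrapolation
    p <- stats::predict(fit, data.frame(gc = g))
    pmax(p, 1e-3 * mean(y))                 # clamp to positive
  }
  pred <- rep(mean(y), length(profile$counts))
  has_gc <- !is.na(scheme$bins$gc)
  pred[has_gc] <- pred_at(scheme$bins$gc[has_gc])
  corrected <- profile$counts / pred * mean(y)
  total_in <- sum(profile$counts[idx])
  total_out <- sum(corrected[idx])
  if (total_out > 0) corrected <- corrected * total_in / total_out
  new_depth_profile(profile$sample_id, corrected, scheme)
}

#' Build a panel of normals
#'
#' Each control is GC-corrected and scaled to the mean library size; the
#' panel stores a per-bin reference level and dispersion. Two modes mirror
#' the two arms of the pipeline: \code{"median"} takes the per-bin median
#' and MAD across controls; \code{"merged"} pools the controls (per-bin sum,
#' equivalent to merging the control alignments before counting).
#'
#' @param controls list of \code{depth_profile}s (at least 2) on one scheme.
#' @param scheme the shared \code{bin_scheme}.
#' @param mode \code{"median"} (default) or \code{"merged"}.
#' @param gc_correct GC-correct the controls first (default TRUE).
#' @return A \code{panel_of_normals}: reference (per-bin level on the mean
#'   library scale), dispersion (MAD), n_controls, masked bins, library_size.
#' @export
build_panel <- function(controls, scheme, mode = c("median", "merged"),
                        gc_correct = TRUE) {
  mode <- match.arg(mode)
  if (length(controls) < 2) stop("need at least 2 controls for a panel")
  sizes <- vapply(controls, function(p) {
    if (length(p$counts) != n_bins(scheme)) stop("control/scheme mismatch")
    sum(p$counts[analyzed_bins(scheme)])
  }, 0)
  target <- mean(sizes)
  mat <- vapply(controls, function(p) {
    q <- if (gc_correct) correct_gc(p, scheme) else p
    q$counts / sum(q$counts[analyzed_bins(scheme)]) * target
  }, numeric(n_bins(scheme)))
  ref <- switch(mode,
                median = apply(mat, 1, stats::median),
                merged = rowMeans(mat))
  disp <- apply(mat, 1, stats::mad)
  zero <- apply(mat, 1, function(v) any(v <= 0))
  masked <- scheme$bins$masked | zero | ref <= 0
  structure(list(reference = ref, dispersion = disp,
                 n_controls = length(controls), masked = masked,
                 library_size = target, mode = mode),
            class = "panel_of_normals")
}

#' @export
print.panel_of_normals <- function(x, ...) {
  cat(sprintf("panel_of_normals (%s): %d controls, %d bins (%d masked)\n",
              x$mode, x$n_controls, length(x$reference), sum(x$masked)))
  invisible(x)
}

#' Convert a depth profile to log2 ratios against a panel
#'
#' The profile is GC-corrected, scaled to the panel's library size, and
#' converted bin-wise to \code{log2((count + eps)/(reference + eps))}, then
#' centered over unmasked autosomal bins. Default centering is on the mode
#' of the log2 distribution (the copy-neutral peak, located by kernel
#' density): when a sizeable genome fraction is altered the median is pulled
#' toward the alterations, which biases tumor-fraction inference downward,
#' while the mode stays on the neutral level as long as neutral remains the
#' most common state. \code{"median"} centering is available for profiles
#' expected to be mostly neutral; degenerate or small inputs (< 200 valid
#' bins) fall back to the median automatically.
#'
#' @param profile a \code{depth_profile}.
#' @param pon a \code{panel_of_normals}.
#' @param scheme the shared \code{bin_scheme}.
#' @param eps pseudo-count before the log (default 1).
#' @param gc_correct GC-correct the sample first (default TRUE).
#' @param center \code{"mode"} (default) or \code{"median"}.
#' @return A \code{normalized_profile}: sample_id, log2_ratio per bin,
#'   valid mask, chrom vector.
#' @export
to_log2_ratio <- function(profile, pon, scheme, eps = 1, gc_correct = TRUE,
                          center = c("mode", "median")) {
  center <- match.arg(center)
  p <- if (gc_correct) correct_gc(profile, scheme) else profile
  idx <- analyzed_bins(scheme)
  scaled <- p$counts / sum(p$counts[idx]) * pon$library_size
  valid <- !pon$masked & !scheme$bins$masked
  if (!any(valid)) stop("all bins masked; cannot normalize")
  r <- log2((scaled + eps) / (pon$reference + eps))
  r[!valid] <- NA_real_
  auto <- valid & !grepl("^(chr)?[XYxy]$", scheme$bins$chrom)
  v <- r[auto]
  shift <- stats::median(v)
  if (center == "mode" && sum(auto) >= 200 && stats::mad(v) > 0) {
    d <- stats::density(v, n = 1024)
    shift <- d$x[which.max(d$y)]
  }
  r <- r - shift
  structure(list(sample_id = profile$sample_id, log2_ratio = r,
                 valid = valid, chrom = scheme$bins$chrom),
            class = "normalized_profile")
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf("normalized_profile '%s': %d bins (%d valid), sd %.3f\n",
              x$sample_id, length(x$log2_ratio), sum(x$valid),
              stats::sd(x$log2_ratio[x$valid])))
  invisible(x)
}

#' Serialize a panel of normals / normalized profile as TSV
#' @param pon a \code{panel_of_normals}.
#' @param scheme the \code{bin_scheme} keying the rows.
#' @param path file path.
#' @export
write_panel_tsv <- function(pon, scheme, path) {
  df <- cbind(scheme$bins[, c("chrom", "start", "end")],
              reference = pon$reference, dispersion = pon$dispersion,
              masked = as.integer(pon$masked))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("#n_controls=%d\tlibrary_size=%.6f\tmode=%s",
                     pon$n_controls, pon$library_size, pon$mode), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- strsplit(sub("^#", "", hdr), "\t")[[1]]
  kv <- strsplit(meta, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  x <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  structure(list(reference = x$reference, dispersion = x$dispersion,
                 n_controls = as.integer(vals[["n_controls"]]),
                 masked = as.logical(x$masked),
                 library_size = as.numeric(vals[["library_size"]]),
                 mode = vals[["mode"]]),
            class = "panel_of_normals")
}

#' Write / read a normalized profile TSV (bin key, log2_ratio, valid)
#' @param np a \code{normalized_profile}.
#' @param scheme the \code{bin_scheme}.
#' @param path file path.
#' @export
write_normalized_tsv <- function(np, scheme, path) {
  df <- cbind(scheme$bins[, c("chrom", "start", "end")],
              log2_ratio = np$log2_ratio, valid = as.integer(np$valid))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("#sample_id=%s", np$sample_id), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_normalized_tsv
#' @export
read_normalized_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  sid <- sub("^#sample_id=", "", hdr)
  x <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  structure(list(sample_id = sid, log2_ratio = x$log2_ratio,
                 valid = as.logical(x$valid), chrom = x$chrom),
            class = "normalized_profile")
}
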