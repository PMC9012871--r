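# shared fixtures, all built in code

tiny_layout <- function() {
  genome_layout(c("chrA", "chrB", "chrC"), c(1e6, 8e5, 6e5))
}

# single-interval track covering a layout
uniform_track <- function(layout, value = 1) {
  data.frame(chrom = layout$chrom, start = 0, end = layout$length,
             value = value)
}

# fixed-width scheme over the tiny layout, uniform gc 0.5, fully mappable
tiny_scheme <- function(width = 1e5, gc = 0.5) {
  layout <- tiny_layout()
  annotate_bins(build_fixed_bins(layout, width),
                uniform_track(layout, gc), uniform_track(layout, 1))
}

# wrap bare values into a normalized_profile on a single chromosome
fake_profile <- function(values, chrom = rep("chr1", length(values)),
                         sample_id = "fake") {
  structure(list(sample_id = sample_id, log2_ratio = values,
                 valid = !is.na(values), chrom = chrom),
            class = "normalized_profile")
}

# matching single-chromosome scheme for fake_profile (1 kb bins)
fake_scheme <- function(n, chrom = "chr1") {
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n)
  layout <- genome_layout(unique(chrom),
                          vapply(unique(chrom),
                                 function(ch) sum(chrom == ch) * 1000, 0))
  bins <- do.call(rbind, lapply(unique(chrom), function(ch) {
    k <- sum(chrom == ch)
    data.frame(chrom = ch, start = seq(0, by = 1000, length.out = k),
               end = seq(1000, by = 1000, length.out = k),
               gc = 0.5, mappable_bases = 1000, masked = FALSE,
               stringsAsFactors = FALSE)
  }))
  cfCNA:::new_bin_scheme(layout, bins, "fixed_width")
}

# small simulated world shared by several module tests: one reference,
# annotated 500 kb scheme, 9-control panel (cached per session)
small_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(seed = 101, n_chromosomes = 6,
                      chromosome_length = 3e7)
    ref <- simulate_reference(cfg)
    scheme <- mask_bins(annotate_bins(build_fixed_bins(ref$layout, 5e5),
                                      ref$gc_track, ref$mappability_track),
                        0.9)
    controls <- lapply(1:9, function(i)
      simulate_depth(cfg, scheme, 0, NULL, sprintf("ctl%02d", i),
                     seed = 7000 + i))
    pon <- build_panel(controls, scheme)
    cache <<- list(cfg = cfg, ref = ref, scheme = scheme,
                   controls = controls, pon = pon)
    cache
  }
})

# minimal coordinate-sorted SAM with proper pairs; returns indexed BAM path
make_test_bam <- function(pairs, dir = tempdir(), chroms = c(chr1 = 1e6)) {
  # pairs: data.frame(chrom, pos1 (1-based leftmost), isize, mapq, dup)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), as.integer(chroms)))
  recs <- character(0)
  if (nrow(pairs)) {
    pairs$dup <- if (is.null(pairs$dup)) FALSE else pairs$dup
    for (i in seq_len(nrow(pairs))) {
      p <- pairs[i, ]
      mpos <- p$pos1 + p$isize - 50
      f1 <- 99L + if (isTRUE(p$dup)) 1024L else 0L
      f2 <- 147L + if (isTRUE(p$dup)) 1024L else 0L
      recs <- c(recs,
        sprintf("p%03d\t%d\t%s\t%d\t%d\t50M\t=\t%d\t%d\t*\t*",
                i, f1, p$chrom, p$pos1, p$mapq, mpos, p$isize),
        sprintf("p%03d\t%d\t%s\t%d\t%d\t50M\t=\t%d\t%d\t*\t*",
                i, f2, p$chrom, mpos, p$mapq, p$pos1, -p$isize))
    }
  }
  # coordinate order within chromosome
  sam <- tempfile(tmpdir = dir, fileext = ".sam")
  if (length(recs)) {
    pos <- as.integer(sub("^[^\t]*\t[^\t]*\t[^\t]*\t([0-9]+)\t.*", "\\1",
                          recs))
    chr <- sub("^[^\t]*\t[^\t]*\t([^\t]*)\t.*", "\\1", recs)
    recs <- recs[order(match(chr, names(chroms)), pos)]
  }
  writeLines(c(hdr, recs), sam)
  bam <- Rsamtools::asBam(sam, sub("\\.sam$", "", sam), overwrite = TRUE)
  bam
}
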