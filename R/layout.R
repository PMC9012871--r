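#' Genome layout
#'
#' An ordered set of chromosomes with lengths. The order is stable and
#' defines genome-wide bin order for every downstream container.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer-ish vector of chromosome lengths in bases (> 0).
#' @return An object of class \code{genome_layout}: a data.frame with
#'   columns \code{chrom} and \code{length}.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 2e6))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) stop("empty genome layout")
  if (anyDuplicated(chrom)) stop("duplicate chromosome names in layout")
  if (length(chrom) != length(length)) stop("chrom and length differ in length")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive and finite")
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Read a genome layout from a two-column chrom/length TSV
#'
#' @param path file with two columns: chromosome name, length in bases.
#'   A header line is detected automatically (non-numeric second field).
#' @return A \code{genome_layout}.
#' @export
read_layout_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 2L) stop("layout TSV needs two columns: chrom, length")
  if (is.character(x[[2]]) && is.na(suppressWarnings(as.numeric(x[1, 2])))) {
    x <- x[-1, , drop = FALSE]
  }
  genome_layout(x[[1]], as.numeric(x[[2]]))
}

#' Write a genome layout as a chrom/length TSV
#' @param layout a \code{genome_layout}.
#' @param path output path.
#' @export
write_layout_tsv <- function(layout, path) {
  utils::write.table(layout[, c("chrom", "length")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track
#'
#' Coordinates are 0-based half-open, as in BED. Fixed-step wiggle input is
#' also accepted (detected by a leading \code{fixedStep} declaration).
#'
#' @param path bedGraph (chrom, start, end, value) or fixed-step wiggle file.
#' @return data.frame with columns chrom, start, end, value.
#' @export
read_track <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^fixedStep", first)) return(read_fixedstep_wig(path))
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "value"))
  x$start <- as.numeric(x$start); x$end <- as.numeric(x$end)
  x$value <- as.numeric(x$value)
  if (any(x$end <= x$start)) stop("track has empty or inverted intervals")
  x
}

read_fixedstep_wig <- function(path) {
  lines <- readLines(path)
  decl <- grep("^fixedStep", lines)
  if (!length(decl)) stop("no fixedStep declaration in wiggle file")
  out <- vector("list", length(decl))
  bounds <- c(decl, length(lines) + 1L)
  for (i in seq_along(decl)) {
    hdr <- lines[decl[i]]
    get <- function(key, default = NA) {
      m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
      if (!length(m)) return(default)
      sub(paste0(key, "="), "", m)
    }
    chrom <- get("chrom")
    start1 <- as.numeric(get("start"))   # wiggle is 1-based
    step <- as.numeric(get("step"))
    span <- as.numeric(get("span", step))
    vals <- as.numeric(lines[(decl[i] + 1L):(bounds[i + 1L] - 1L)])
    vals <- vals[!is.na(vals)]
    starts0 <- start1 - 1 + step * (seq_along(vals) - 1)
    out[[i]] <- data.frame(chrom = chrom, start = starts0,
                           end = starts0 + span, value = vals,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a track as bedGraph
#' @param track data.frame chrom/start/end/value (0-based half-open).
#' @param path output path.
#' @export
write_track <- function(track, path) {
  utils::write.table(
    data.frame(track$chrom, format(track$start, scientific = FALSE, trim = TRUE),
               format(track$end, scientific = FALSE, trim = TRUE), track$value),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# split a track into a per-chromosome list, validated against a layout
track_by_chrom <- function(track, layout) {
  miss <- setdiff(unique(track$chrom), layout$chrom)
  if (length(miss))
    stop("track chromosomes absent from layout: ", paste(miss, collapse = ", "))
  split(track[, c("start", "end", "value")], factor(track$chrom, layout$chrom))
}
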