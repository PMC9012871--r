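#' Synthetic shallow-WGS cfDNA data with known ground truth
#'
#' Generates every input the pipeline consumes: a genome layout with smooth
#' GC and dropout-run mappability tracks, healthy-panel depth profiles,
#' case profiles carrying segmental copy-number alterations diluted by a
#' known tumor fraction, fragment-length samples with nucleosome modes and
#' 10 bp periodicity, and a cohort table emulating a benign/malignant
#' splenic-lesion study design. Everything is seeded and reproducible.
#'
#' Depth model: the count of bin i is negative binomial with mean
#' coverage_target * 2^expected_log2(tf, c_i, 2) * (1 + gc_bias_slope *
#' (gc_i - 0.5)) * mappable_fraction_i, with dispersion chosen so the total
#' log2-scale bin noise is about \code{noise_sd}. When the Poisson noise at
#' the requested coverage already exceeds \code{noise_sd}, counts are
#' Poisson (the attainable minimum).
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults state a desk-scale analogue of a canine sWGS plasma study: a
#' 20-chromosome x 60 Mb genome (~1.2 Gb), 9 healthy controls, ~400
#' fragments per 500 kb bin (~0.5x coverage equivalents), log2 bin noise
#' 0.06 (the scale of observed within-segment SDs), and cohort tumor
#' fractions of 3.2\% (sd 3.4) for benign and 11.2\% (sd 9.1) for malignant
#' subjects with group sizes 14 and 25.
#'
#' @param seed integer RNG seed; fixed seed gives identical output.
#' @param n_chromosomes,chromosome_length genome shape.
#' @param gc_window bp resolution of the GC track (default 50000).
#' @param gc_range GC field bounds (default c(0.3, 0.6)).
#' @param gc_smooth autocorrelation of the GC field in windows (default 20).
#' @param mappability_dropout fraction of the genome in unusable runs
#'   (default 0.02).
#' @param dropout_run_length mean unusable-run length, bp (default 2e5).
#' @param n_controls healthy controls for the panel (default 9).
#' @param coverage_target mean fragments per bin (default 400).
#' @param noise_sd target log2-scale bin noise (default 0.06).
#' @param gc_bias_slope linear depth-vs-GC coefficient (default 0.3).
#' @param bin_width fixed-bin width (default 5e5).
#' @param gain_fraction,loss_fraction genome fractions at copy 3 / copy 1
#'   for default case truth (defaults 0.25, 0.10).
#' @param fragment_modes,fragment_weights,fragment_sds mono/di/tri-nucleosome
#'   mixture (defaults 166/332/498 bp, weights 0.8/0.15/0.05, sds 10/18/25).
#' @param sub_mode_fraction fraction of fragments in the sub-mononucleosomal
#'   ladder below the main mode (default 0.08), drawn as (mode - 10) minus
#'   an exponential (mean \code{sub_mode_decay} bp); this is the population
#'   whose lengths carry the 10 bp periodicity.
#' @param sub_mode_decay mean decay of the sub-mode ladder, bp (default 25).
#' @param periodicity_amplitude 10 bp comb amplitude below 150 bp
#'   (default 0.25).
#' @param cohort_design per-group tumor-fraction design: a data.frame with
#'   columns group, n, tf_mean, tf_sd.
#' @param post_reduction multiplicative tumor-fraction reduction after
#'   surgery (default 0.7, the scale of the observed 11.0 -> 7.9\% drop).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1, n_chromosomes = 20,
                       chromosome_length = 6e7, gc_window = 5e4,
                       gc_range = c(0.3, 0.6), gc_smooth = 20,
                       mappability_dropout = 0.02,
                       dropout_run_length = 2e5,
                       n_controls = 9, coverage_target = 400,
                       noise_sd = 0.06, gc_bias_slope = 0.3,
                       bin_width = 5e5,
                       gain_fraction = 0.25, loss_fraction = 0.10,
                       fragment_modes = c(166, 332, 498),
                       fragment_weights = c(0.8, 0.15, 0.05),
                       fragment_sds = c(10, 18, 25),
                       sub_mode_fraction = 0.08,
                       sub_mode_decay = 25,
                       periodicity_amplitude = 0.25,
                       cohort_design = data.frame(
                         group = c("benign", "malignant"),
                         n = c(14, 25),
                         tf_mean = c(0.032, 0.112),
                         tf_sd = c(0.034, 0.091)),
                       post_reduction = 0.7) {
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a reference: layout plus GC and mappability tracks
#'
#' The GC field is a smoothed Gaussian field squashed into
#' \code{gc_range}; mappability is 1 outside seeded unusable runs of
#' geometric length.
#'
#' @param config a \code{sim_config}.
#' @return list(layout, gc_track, mappability_track).
#' @export
simulate_reference <- function(config) {
  with_seed(config$seed, {
    layout <- genome_layout(paste0("chr", seq_len(config$n_chromosomes)),
                            rep(config$chromosome_length,
                                config$n_chromosomes))
    gc <- list(); mp <- list()
    for (i in seq_len(nrow(layout))) {
      len <- layout$length[i]
      nw <- ceiling(len / config$gc_window)
      z <- as.numeric(stats::filter(stats::rnorm(nw + 2 * config$gc_smooth),
                                    rep(1, config$gc_smooth),
                                    sides = 2))
      z <- z[config$gc_smooth + seq_len(nw)]
      z <- (z - mean(z)) / max(stats::sd(z), 1e-9)
      gcv <- config$gc_range[1] + diff(config$gc_range) * stats::pnorm(z)
      starts <- (seq_len(nw) - 1) * config$gc_window
      gc[[i]] <- data.frame(chrom = layout$chrom[i], start = starts,
                            end = pmin(starts + config$gc_window, len),
                            value = gcv, stringsAsFactors = FALSE)
      # unusable runs totalling ~mappability_dropout of the chromosome
      target <- config$mappability_dropout * len
      runs <- data.frame(start = numeric(), end = numeric())
      placed <- 0
      while (placed < target) {
        w <- min(stats::rgeom(1, 1 / config$dropout_run_length) + 1,
                 target - placed + config$dropout_run_length)
        s <- floor(stats::runif(1, 0, len - w))
        runs <- rbind(runs, data.frame(start = s, end = s + w))
        placed <- placed + w
      }
      runs <- runs[order(runs$start), , drop = FALSE]
      # flatten overlaps into a 0/1 track
      bounds <- sort(unique(c(0, len, pmin(pmax(c(runs$start, runs$end),
                                               0), len))))
      vals <- vapply(seq_len(length(bounds) - 1), function(k) {
        mid <- (bounds[k] + bounds[k + 1]) / 2
        as.numeric(!any(runs$start <= mid & mid < runs$end))
      }, 0)
      mp[[i]] <- data.frame(chrom = layout$chrom[i],
                            start = bounds[-length(bounds)],
                            end = bounds[-1], value = vals,
                            stringsAsFactors = FALSE)
    }
    list(layout = layout, gc_track = do.call(rbind, gc),
         mappability_track = do.call(rbind, mp))
  })
}

#' Draw a random non-overlapping CNA truth set
#'
#' Places gain (copy 3) and loss (copy 1) segments of 15-60 Mb
#' (chromosome-arm to whole-chromosome scale, the breadth typical of the
#' vascular-tumor copy-number landscape emulated here) until the requested
#' genome fractions are covered.
#'
#' @param config a \code{sim_config}.
#' @param layout the \code{genome_layout} to place CNAs on.
#' @param seed RNG seed (default: config seed).
#' @return data.frame (chrom, start, end, copy_number).
#' @export
simulate_cna_truth <- function(config, layout, seed = config$seed) {
  with_seed(seed, {
    genome <- sum(layout$length)
    placed <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), copy_number = integer(),
                         stringsAsFactors = FALSE)
    for (spec in list(c(3, config$gain_fraction),
                      c(1, config$loss_fraction))) {
      target <- spec[2] * genome
      tot <- 0
      tries <- 0
      while (tot < target && tries < 1000) {
        tries <- tries + 1
        ci <- sample.int(nrow(layout), 1)
        w <- stats::runif(1, 1.5e7, 6e7)
        w <- min(w, target - tot + 1.5e7, layout$length[ci])
        s <- floor(stats::runif(1, 0, layout$length[ci] - w))
        clash <- placed$chrom == layout$chrom[ci] &
          placed$start < s + w & s < placed$end
        if (any(clash)) next
        placed <- rbind(placed,
                        data.frame(chrom = layout$chrom[ci], start = s,
                                   end = s + w, copy_number = spec[1],
                                   stringsAsFactors = FALSE))
        tot <- tot + w
      }
    }
    placed[order(match(placed$chrom, layout$chrom), placed$start), ]
  })
}

#' Simulate one depth profile
#'
#' @param config a \code{sim_config}.
#' @param scheme an annotated \code{bin_scheme} over the simulated
#'   reference.
#' @param tf tumor fraction (0 for controls).
#' @param cna_truth data.frame (chrom, start, end, copy_number) or NULL for
#'   a copy-neutral genome.
#' @param sample_id sample name.
#' @param seed RNG seed (default: config seed).
#' @return A \code{depth_profile}.
#' @export
simulate_depth <- function(config, scheme, tf = 0, cna_truth = NULL,
                           sample_id = "sim", seed = config$seed) {
  b <- scheme$bins
  copy <- rep(2L, nrow(b))
  if (!is.null(cna_truth) && nrow(cna_truth)) {
    mid <- (b$start + b$end) / 2
    for (i in seq_len(nrow(cna_truth))) {
      hit <- b$chrom == cna_truth$chrom[i] & mid >= cna_truth$start[i] &
        mid < cna_truth$end[i]
      copy[hit] <- cna_truth$copy_number[i]
    }
  }
  mu_log2 <- expected_log2(tf, copy, 2)
  gc <- ifelse(is.na(b$gc), 0.5, b$gc)
  frac_map <- b$mappable_bases / (b$end - b$start)
  m <- config$coverage_target * 2^mu_log2 *
    pmax(1 + config$gc_bias_slope * (gc - 0.5), 0.05) * frac_map
  extra <- (config$noise_sd * log(2))^2 - 1 / pmax(m, 1e-9)
  with_seed(seed, {
    counts <- ifelse(m <= 0, 0,
                     ifelse(extra > 1e-9,
                            stats::rnbinom(length(m), mu = m,
                                           size = 1 / pmax(extra, 1e-9)),
                            stats::rpois(length(m), m)))
    new_depth_profile(sample_id, counts, scheme)
  })
}

#' Simulate cfDNA fragment lengths
#'
#' Mixture of discretized normals at the mono-/di-/tri-nucleosome modes
#' plus a sub-mononucleosomal ladder (fraction \code{sub_mode_fraction},
#' decaying below the main mode); lengths under 150 bp are modulated by a
#' 10 bp-period cosine comb of amplitude \code{periodicity_amplitude}
#' (rejection sampling).
#'
#' @param config a \code{sim_config}.
#' @param n number of fragments.
#' @param sample_id sample name.
#' @param seed RNG seed (default: config seed).
#' @return A \code{fragment_lengths} object.
#' @export
simulate_fragments <- function(config, n, sample_id = "sim_frags",
                               seed = config$seed) {
  with_seed(seed, {
    out <- integer(0)
    amp <- config$periodicity_amplitude
    wts <- config$fragment_weights / sum(config$fragment_weights)
    while (length(out) < n) {
      todo <- n - length(out)
      comp <- sample.int(length(wts), todo, replace = TRUE, prob = wts)
      l <- round(stats::rnorm(todo, config$fragment_modes[comp],
                              config$fragment_sds[comp]))
      ladder <- stats::runif(todo) < config$sub_mode_fraction & comp == 1L
      if (any(ladder))
        l[ladder] <- round(config$fragment_modes[1] - 10 -
                             stats::rexp(sum(ladder),
                                         1 / config$sub_mode_decay))
      l <- l[l >= 30 & l <= 1000]
      if (amp > 0 && length(l)) {
        sub <- l < 150
        keep_p <- rep(1, length(l))
        keep_p[sub] <- (1 + amp * cos(2 * pi * l[sub] / 10)) / (1 + amp)
        l <- l[stats::runif(length(l)) <= keep_p]
      }
      out <- c(out, l)
    }
    fragment_lengths(sample_id, out[seq_len(n)])
  })
}

rtruncnorm0 <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    v <- stats::rnorm(n, mean, sd)
    out <- c(out, v[v >= 0])
  }
  out[seq_len(n)]
}

#' Simulate a full cohort bundle
#'
#' Builds the reference, an annotated fixed-width bin scheme, the control
#' panel profiles, and per-dog case samples (pre-surgery, and post-surgery
#' for malignant dogs) with tumor fractions drawn from the per-group
#' truncated-normal design (truncation at 0). Each dog receives its own
#' random CNA truth.
#'
#' @param config a \code{sim_config}.
#' @param timepoints simulate post-surgery samples too (default TRUE).
#' @return A \code{sim_bundle}: reference, scheme, controls, cases (list of
#'   dog records with truth), and a cohort table (dog_id, sample_id, group,
#'   timepoint, true_tf).
#' @export
simulate_cohort <- function(config, timepoints = TRUE) {
  ref <- simulate_reference(config)
  scheme <- build_fixed_bins(ref$layout, config$bin_width)
  scheme <- annotate_bins(scheme, ref$gc_track, ref$mappability_track)
  scheme <- mask_bins(scheme, 0.9)
  controls <- lapply(seq_len(config$n_controls), function(i) {
    simulate_depth(config, scheme, tf = 0, cna_truth = NULL,
                   sample_id = sprintf("control_%02d", i),
                   seed = config$seed * 1000L + i)
  })
  design <- config$cohort_design
  dogs <- list(); rows <- list()
  dog_no <- 0
  for (g in seq_len(nrow(design))) {
    tfs <- with_seed(config$seed * 100L + g,
                     rtruncnorm0(design$n[g], design$tf_mean[g],
                                 design$tf_sd[g]))
    for (d in seq_len(design$n[g])) {
      dog_no <- dog_no + 1
      dog_id <- sprintf("dog_%02d", dog_no)
      truth <- simulate_cna_truth(config, ref$layout,
                                  seed = config$seed * 10000L + dog_no)
      tf_pre <- tfs[d]
      samples <- list(pre = simulate_depth(
        config, scheme, tf_pre, truth,
        sample_id = paste0(dog_id, "_pre"),
        seed = config$seed * 100000L + dog_no * 2L))
      rows[[length(rows) + 1]] <- data.frame(
        dog_id = dog_id, sample_id = paste0(dog_id, "_pre"),
        group = design$group[g], timepoint = "pre", true_tf = tf_pre,
        stringsAsFactors = FALSE)
      if (timepoints && design$group[g] == "malignant") {
        tf_post <- tf_pre * config$post_reduction
        samples$post <- simulate_depth(
          config, scheme, tf_post, truth,
          sample_id = paste0(dog_id, "_post"),
          seed = config$seed * 100000L + dog_no * 2L + 1L)
        rows[[length(rows) + 1]] <- data.frame(
          dog_id = dog_id, sample_id = paste0(dog_id, "_post"),
          group = design$group[g], timepoint = "post", true_tf = tf_post,
          stringsAsFactors = FALSE)
      }
      dogs[[dog_id]] <- list(dog_id = dog_id, group = design$group[g],
                             truth = truth, tf_pre = tf_pre,
                             samples = samples)
    }
  }
  structure(list(reference = ref, scheme = scheme, controls = controls,
                 cases = dogs, cohort_table = do.call(rbind, rows),
                 config = config),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("sim_bundle: %d controls, %d dogs, %d samples, %d bins\n",
              length(x$controls), length(x$cases), nrow(x$cohort_table),
              n_bins(x$scheme)))
  invisible(x)
}
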