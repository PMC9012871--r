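#' HMM tumor-fraction inference
#'
#' The HMM arm models per-bin log2 depth ratios as emissions from hidden
#' integer copy-number states and infers the circulating tumor DNA fraction
#' directly from the magnitude of the detected alterations: at tumor
#' fraction tf, a clonal state with copy number c shifts the expected log2
#' ratio to log2((tf*c + (1-tf)*P)/P) for ploidy P. Parameter ranges are
#' deliberately restricted — ploidy fixed at 2, copy numbers 0..3, subclonal
#' copy options {1,3} — because without these restrictions spurious
#' high-tumor-fraction solutions with inferred ploidy 3 are common in
#' shallow-WGS plasma data.
#'
#' @name hmm_tf
NULL

#' HMM configuration
#'
#' @param normal_grid initial normal proportions for the grid search
#'   (default \code{c(0.7, 0.8, 0.9, 0.95, 0.99)}).
#' @param ploidy fixed ploidy (2).
#' @param states clonal copy numbers (default 0:3; max copy 3).
#' @param subclone_states subclonal copy-number options (default c(1, 3)).
#' @param self_transition self-transition probability (default 0.999:
#'   alterations span many consecutive bins, but the stay probability must
#'   not price moderate-length segments out of being called — at 500 kb
#'   bins a segment is only decoded when its emission gain exceeds twice
#'   the switch cost).
#' @param emission_df Student-t degrees of freedom (default 3, robust to
#'   outlier bins).
#' @param max_iter maximum EM iterations (default 50).
#' @param tol EM convergence tolerance on the log-likelihood (default 1e-3).
#' @param use_autosomes_only exclude sex chromosomes from the likelihood
#'   (default TRUE; cohorts mix sexes).
#' @param tf_range search range for tumor fraction (default c(0.005, 0.6)).
#' @param sp_range search range for subclone prevalence (default c(0.1, 0.9)).
#' @param scale_range search range for the emission scale.
#' @param center_range search range for the baseline shift, the residual
#'   centering offset of the neutral level left by median-centering when a
#'   sizeable genome fraction is altered (default c(-0.1, 0.1)).
#' @param state_prior per-state occupancy prior weights (normalized
#'   internally; order: clonal states then subclonal states). Acts as a
#'   per-bin log-prior added to the emissions — a penalized EM that breaks
#'   two likelihood degeneracies of the restricted-state model: a
#'   single-copy loss at tumor fraction t is emission-identical to a
#'   homozygous deletion at t/2, and a subclonal state at low prevalence
#'   duplicates the neutral level. Defaults strongly down-weight homozygous
#'   deletion and subclonal states, mirroring the biological rarity of
#'   multi-megabase homozygous loss in circulating DNA.
#' @return A list of class \code{hmm_config}.
#' @export
hmm_config <- function(normal_grid = c(0.7, 0.8, 0.9, 0.95, 0.99),
                       ploidy = 2, states = 0:3, subclone_states = c(1, 3),
                       self_transition = 0.999, emission_df = 3,
                       max_iter = 50, tol = 1e-3,
                       use_autosomes_only = TRUE,
                       tf_range = c(0.005, 0.6), sp_range = c(0.1, 0.9),
                       scale_range = c(1e-4, 1),
                       center_range = c(-0.1, 0.1),
                       state_prior = NULL) {
  stopifnot(all(normal_grid > 0 & normal_grid < 1),
            self_transition > 0 && self_transition < 1,
            ploidy %in% states)
  n_state <- length(states) + length(subclone_states)
  if (is.null(state_prior)) {
    w <- ifelse(states == 0, 0.02, 0.3)
    state_prior <- c(w, rep(0.04, length(subclone_states)))
  }
  stopifnot(length(state_prior) == n_state, all(state_prior > 0))
  state_prior <- state_prior / sum(state_prior)
  structure(list(state_prior = state_prior,normal_grid = normal_grid, ploidy = ploidy, states = states,
                 subclone_states = subclone_states,
                 self_transition = self_transition,
                 emission_df = emission_df, max_iter = max_iter, tol = tol,
                 use_autosomes_only = use_autosomes_only,
                 tf_range = tf_range, sp_range = sp_range,
                 scale_range = scale_range, center_range = center_range),
            class = "hmm_config")
}

#' Expected log2 ratio of a copy-number state at a tumor fraction
#'
#' \code{log2((tf*c + (1-tf)*ploidy)/ploidy)}: the depth shift produced by a
#' clonal alteration to copy number \code{c} in a sample whose fraction
#' \code{tf} of DNA is tumor-derived.
#'
#' @param tf tumor fraction in [0,1].
#' @param c copy number (>= 0).
#' @param ploidy normal copy number (> 0, default 2).
#' @return log2 ratio (0 when \code{tf = 0} or \code{c = ploidy}).
#' @examples
#' expected_log2(0.5, 1)  # log2(0.75)
#' expected_log2(0.2, 3)  # log2(1.1)
#' @export
expected_log2 <- function(tf, c, ploidy = 2) {
  if (any(tf < 0 | tf > 1)) stop("tf must lie in [0,1]")
  if (any(c < 0) || ploidy <= 0) stop("need c >= 0 and ploidy > 0")
  if (any(tf == 1 & c == 0))
    stop("tf = 1 with c = 0: no DNA present, log ratio undefined")
  log2((tf * c + (1 - tf) * ploidy) / ploidy)
}

# state layout: clonal copy numbers then subclonal options
hmm_state_table <- function(config) {
  data.frame(copy = c(config$states, config$subclone_states),
             subclonal = c(rep(FALSE, length(config$states)),
                           rep(TRUE, length(config$subclone_states))))
}

hmm_state_means <- function(tf, sp, config) {
  st <- hmm_state_table(config)
  eff <- ifelse(st$subclonal, tf * sp, tf)
  expected_log2(eff, st$copy, config$ploidy)
}

# log Student-t density with location/scale, vectorized; constant cached
log_t_density <- function(z, df, scale, const) {
  const - log(scale) - (df + 1) / 2 * log1p(z * z / df)
}

hmm_logemit <- function(x, mu, scale, df, const) {
  ne <- length(x)
  out <- matrix(0, ne, length(mu))
  for (k in seq_along(mu))
    out[, k] <- log_t_density((x - mu[k]) / scale, df, scale, const)
  out
}

#' Fit the copy-number HMM from one initialization
#'
#' EM alternates forward-backward posteriors over the clonal + subclonal
#' states (Student-t emissions centered at \code{\link{expected_log2}}) with
#' 1-D maximization of tumor fraction, subclone prevalence, and emission
#' scale on the expected complete-data log-likelihood. The Viterbi path is
#' grouped into a \code{segment_set}.
#'
#' @param profile a \code{normalized_profile}.
#' @param scheme the matching \code{bin_scheme}.
#' @param config an \code{hmm_config}.
#' @param init_n initial normal proportion (tumor fraction starts at
#'   \code{1 - init_n}).
#' @return list(segments = segment_set, estimate = tumor_fraction_estimate).
#' @export
run_hmm <- function(profile, scheme, config = hmm_config(), init_n = 0.9) {
  idx <- which(profile$valid)
  if (config$use_autosomes_only)
    idx <- idx[!grepl("^(chr)?[XYxy]$", profile$chrom[idx])]
  if (!length(idx)) stop("no usable bins for HMM fitting")
  if (length(idx) < 100)
    warning("fewer than 100 usable bins; tumor-fraction estimate unstable")
  x <- profile$log2_ratio[idx]
  chrom <- profile$chrom[idx]
  runs <- split(seq_along(x), factor(chrom, unique(chrom)))
  df <- config$emission_df
  const <- lgamma((df + 1) / 2) - lgamma(df / 2) - 0.5 * log(df * pi)

  lprior <- log(config$state_prior)
  lprior <- matrix(lprior, length(x), length(lprior), byrow = TRUE)
  tf <- min(max(1 - init_n, config$tf_range[1]), config$tf_range[2])
  sp <- 0.5
  scale <- min(max(stats::mad(x), config$scale_range[1]),
               config$scale_range[2])

  cb <- 0   # baseline shift: residual centering offset of the neutral level
  estep <- function(tf, sp, scale, cb) {
    le <- hmm_logemit(x, hmm_state_means(tf, sp, config) + cb, scale, df,
                      const) + lprior
    gamma <- matrix(0, length(x), ncol(le))
    ll <- 0
    for (r in runs) {
      f <- .fb_rank1(le[r, , drop = FALSE], config$self_transition)
      gamma[r, ] <- f$gamma
      ll <- ll + f$loglik
    }
    list(gamma = gamma, loglik = ll)
  }
  # the state prior is constant in the continuous parameters, so it drops
  # out of the coordinate-ascent objective
  qfun <- function(gamma, tf, sp, scale, cb) {
    le <- hmm_logemit(x, hmm_state_means(tf, sp, config) + cb, scale, df,
                      const)
    sum(gamma * le)
  }

  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(config$max_iter)) {
    e <- estep(tf, sp, scale, cb)
    ll_trace <- c(ll_trace, e$loglik)
    if (iter > 1 && abs(e$loglik - ll_trace[iter - 1]) < config$tol) {
      converged <- TRUE
      break
    }
    g <- e$gamma
    tf <- stats::optimize(function(v) qfun(g, v, sp, scale, cb),
                          config$tf_range, maximum = TRUE,
                          tol = 1e-4)$maximum
    if (any(hmm_state_table(config)$subclonal))
      sp <- stats::optimize(function(v) qfun(g, tf, v, scale, cb),
                            config$sp_range, maximum = TRUE,
                            tol = 1e-3)$maximum
    scale <- exp(stats::optimize(function(v) qfun(g, tf, sp, exp(v), cb),
                                 log(config$scale_range), maximum = TRUE,
                                 tol = 1e-3)$maximum)
    cb <- stats::optimize(function(v) qfun(g, tf, sp, scale, v),
                          config$center_range, maximum = TRUE,
                          tol = 1e-4)$maximum
  }
  final <- estep(tf, sp, scale, cb)

  # Viterbi decode with the converged parameters. States whose expected
  # shift is within half an emission scale of neutral are indistinguishable
  # from it at the data's noise level and are collapsed into neutral for
  # decoding (the path would otherwise flip arbitrarily between duplicates).
  st <- hmm_state_table(config)
  mu <- hmm_state_means(tf, sp, config) + cb
  neutral <- which(st$copy == config$ploidy & !st$subclonal)[1]
  keep <- which(abs(mu - mu[neutral]) >= 0.5 * scale |
                  seq_along(mu) == neutral)
  if (length(keep) == 1L) {
    path <- rep(neutral, length(x))
  } else {
    le <- hmm_logemit(x, mu[keep], scale, df, const) +
      lprior[, keep, drop = FALSE]
    path <- integer(length(x))
    for (r in runs)
      path[r] <- .viterbi_rank1(le[r, , drop = FALSE],
                                config$self_transition)
    path <- keep[path]
  }
  copy <- st$copy[path]
  fga <- mean(copy != config$ploidy)

  # collapse the path into segments over the analyzed bins
  segs <- do.call(rbind, lapply(runs, function(r) {
    cp <- copy[r]
    brk <- cumsum(c(TRUE, cp[-1] != cp[-length(cp)]))
    do.call(rbind, lapply(split(seq_along(r), brk), function(i) {
      mem <- idx[r[i]]
      data.frame(chrom = chrom[r[1]],
                 start = scheme$bins$start[mem[1]],
                 end = scheme$bins$end[mem[length(mem)]],
                 n_bins = length(mem),
                 mean_log2 = mean(profile$log2_ratio[mem]),
                 copy_state = c("loss", "neutral", "gain")[
                   sign(cp[i[1]] - config$ploidy) + 2],
                 copy_number = cp[i[1]],
                 bin_from = mem[1], bin_to = mem[length(mem)],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(segs) <- NULL

  est <- structure(list(
    tumor_fraction = tf, normal_proportion = 1 - tf,
    subclone_prevalence = sp, emission_scale = scale, baseline_shift = cb,
    log_likelihood = final$loglik, fraction_genome_altered = fga,
    ll_trace = ll_trace, converged = converged, init_n = init_n,
    n_bins_used = length(x)), class = "tumor_fraction_estimate")
  list(segments = segment_set(profile$sample_id, "hmm_arm", segs),
       estimate = est)
}

#' @export
print.tumor_fraction_estimate <- function(x, ...) {
  cat(sprintf(paste0("tumor_fraction_estimate: tf = %.4f (n = %.4f), ",
                     "FGA = %.3f, logLik = %.2f%s\n"),
              x$tumor_fraction, x$normal_proportion,
              x$fraction_genome_altered, x$log_likelihood,
              if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}

# grid-solution selection: highest log-likelihood, ties (within tol)
# broken toward the lower tumor fraction
pick_grid_solution <- function(ll, tf, tol = 1e-6) {
  cand <- which(ll >= max(ll) - tol)
  cand[which.min(tf[cand])]
}

#' Estimate tumor fraction with the initialization grid
#'
#' Runs \code{\link{run_hmm}} once per value of the normal-proportion grid
#' and keeps the solution with the highest log-likelihood; likelihood ties
#' are broken toward the lower tumor fraction. The full grid trace is
#' retained in the estimate.
#'
#' @inheritParams run_hmm
#' @return list(segments, estimate); the estimate carries
#'   \code{grid_trace}, a data.frame of (init_n, tumor_fraction,
#'   log_likelihood, converged).
#' @export
estimate_tumor_fraction <- function(profile, scheme, config = hmm_config()) {
  fits <- lapply(config$normal_grid,
                 function(n0) run_hmm(profile, scheme, config, init_n = n0))
  ll <- vapply(fits, function(f) f$estimate$log_likelihood, 0)
  tf <- vapply(fits, function(f) f$estimate$tumor_fraction, 0)
  pick <- pick_grid_solution(ll, tf)
  out <- fits[[pick]]
  out$estimate$grid_trace <- data.frame(
    init_n = config$normal_grid, tumor_fraction = tf, log_likelihood = ll,
    converged = vapply(fits, function(f) f$estimate$converged, TRUE))
  out
}

#' Serialize a tumor-fraction estimate as JSON
#' @param est a \code{tumor_fraction_estimate}.
#' @param path output path.
#' @export
write_tf_json <- function(est, path) {
  jsonlite::write_json(
    list(tumor_fraction = est$tumor_fraction,
         normal_proportion = est$normal_proportion,
         subclone_prevalence = est$subclone_prevalence,
         log_likelihood = est$log_likelihood,
         fraction_genome_altered = est$fraction_genome_altered,
         grid_trace = est$grid_trace),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
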