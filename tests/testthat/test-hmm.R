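test_that("expected_log2 matches hand arithmetic", {
  expect_equal(expected_log2(0, 3), 0)
  expect_equal(expected_log2(0, 0), 0)
  expect_equal(expected_log2(0.5, 1, 2), log2(0.75))
  expect_equal(expected_log2(0.2, 3, 2), log2(1.1))
  expect_error(expected_log2(1, 0), "undefined")
  expect_error(expected_log2(-0.1, 2), "\\[0,1\\]")
})

test_that("forward-backward posteriors normalize and match enumeration", {
  set.seed(14)
  for (rep in 1:3) {
    T_ <- 6; K <- 4
    le <- matrix(stats::rnorm(T_ * K), T_, K)
    self_p <- 0.9
    r <- cfCNA:::.fb_rank1(le, self_p)
    expect_equal(rowSums(r$gamma), rep(1, T_), tolerance = 1e-12)

    # brute-force marginal likelihood over all K^T paths
    A <- matrix((1 - self_p) / (K - 1), K, K); diag(A) <- self_p
    paths <- as.matrix(expand.grid(rep(list(1:K), T_)))
    lp <- log(1 / K) + le[1, paths[, 1]]
    for (t in 2:T_)
      lp <- lp + log(A[cbind(paths[, t - 1], paths[, t])]) +
        le[t, paths[, t]]
    m <- max(lp)
    expect_equal(r$loglik, m + log(sum(exp(lp - m))), tolerance = 1e-9)

    # posterior by enumeration at a middle position
    post <- vapply(1:K, function(k)
      sum(exp(lp[paths[, 3] == k] - m)), 0)
    expect_equal(r$gamma[3, ], post / sum(post), tolerance = 1e-9)
  }
})

test_that("Viterbi equals exhaustive path enumeration with 6 states", {
  set.seed(15)
  for (rep in 1:4) {
    T_ <- 8; K <- 6
    le <- matrix(stats::rnorm(T_ * K, sd = 2), T_, K)
    self_p <- 0.999
    got <- cfCNA:::.viterbi_rank1(le, self_p)
    A <- matrix((1 - self_p) / (K - 1), K, K); diag(A) <- self_p
    paths <- as.matrix(expand.grid(rep(list(1:K), T_)))
    lp <- log(1 / K) + le[1, paths[, 1]]
    for (t in 2:T_)
      lp <- lp + log(A[cbind(paths[, t - 1], paths[, t])]) +
        le[t, paths[, t]]
    expect_equal(as.integer(got), as.integer(paths[which.max(lp), ]))
  }
})

test_that("noise-free profiles recover tf and the state path", {
  cfgh <- hmm_config()
  tf <- 0.3
  chrom <- rep(paste0("chr", 1:4), each = 75)
  copy <- rep(2, 300)
  copy[31:90] <- 3      # spans chr1/chr2 boundary
  copy[181:220] <- 1
  x <- expected_log2(tf, copy)
  np <- fake_profile(x, chrom)
  sc <- fake_scheme(300, chrom)
  fit <- run_hmm(np, sc, cfgh, init_n = 0.8)
  expect_equal(fit$estimate$tumor_fraction, tf, tolerance = 0.01)
  got_copy <- rep(NA_integer_, 300)
  for (i in seq_len(nrow(fit$segments$segments))) {
    s <- fit$segments$segments[i, ]
    got_copy[s$bin_from:s$bin_to] <- s$copy_number
  }
  expect_equal(got_copy, copy)
  expect_equal(fit$estimate$fraction_genome_altered, mean(copy != 2),
               tolerance = 1e-9)
})

test_that("an all-zero noiseless profile gives tf at the floor", {
  chrom <- rep(c("chr1", "chr2"), each = 100)
  np <- fake_profile(rep(0, 200), chrom)
  sc <- fake_scheme(200, chrom)
  fit <- run_hmm(np, sc, hmm_config(), init_n = 0.9)
  expect_lte(fit$estimate$tumor_fraction, 0.01)
  expect_equal(nrow(fit$segments$segments), 2)
  expect_true(all(fit$segments$segments$copy_state == "neutral"))
})

test_that("EM log-likelihood is non-decreasing", {
  w <- small_world()
  truth <- simulate_cna_truth(w$cfg, w$ref$layout, seed = 55)
  dp <- simulate_depth(w$cfg, w$scheme, 0.15, truth, "s", seed = 56)
  np <- to_log2_ratio(dp, w$pon, w$scheme)
  for (n0 in c(0.7, 0.95)) {
    fit <- run_hmm(np, w$scheme, hmm_config(), init_n = n0)
    expect_true(all(diff(fit$estimate$ll_trace) > -1e-6))
  }
})

test_that("grid selection breaks likelihood ties toward lower tf", {
  expect_equal(cfCNA:::pick_grid_solution(c(-100, -100), c(0.31, 0.08)), 2)
  expect_equal(cfCNA:::pick_grid_solution(c(-100, -100 + 1e-9),
                                          c(0.31, 0.08)), 2)
  expect_equal(cfCNA:::pick_grid_solution(c(-90, -100), c(0.31, 0.08)), 1)
})

test_that("estimate_tumor_fraction keeps the grid trace", {
  w <- small_world()
  truth <- simulate_cna_truth(w$cfg, w$ref$layout, seed = 57)
  dp <- simulate_depth(w$cfg, w$scheme, 0.2, truth, "s", seed = 58)
  np <- to_log2_ratio(dp, w$pon, w$scheme)
  fit <- estimate_tumor_fraction(np, w$scheme)
  tr <- fit$estimate$grid_trace
  expect_equal(tr$init_n, c(0.7, 0.8, 0.9, 0.95, 0.99))
  expect_equal(fit$estimate$log_likelihood, max(tr$log_likelihood))
  expect_lt(abs(fit$estimate$tumor_fraction - 0.2), 0.05)
  expect_equal(fit$estimate$normal_proportion,
               1 - fit$estimate$tumor_fraction)

  # JSON serialization keeps the headline numbers
  p <- tempfile(fileext = ".json")
  write_tf_json(fit$estimate, p)
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(j$tumor_fraction, fit$estimate$tumor_fraction)
  expect_equal(nrow(j$grid_trace), 5)
})

test_that("monotone recovery across true tumor fractions", {
  # reduced-scale version of the full acceptance sweep: 3 replicates per
  # level on the small world
  w <- small_world()
  meds <- vapply(c(0.05, 0.2, 0.4), function(tf) {
    est <- vapply(1:2, function(i) {
      truth <- simulate_cna_truth(w$cfg, w$ref$layout, seed = 600 + i)
      dp <- simulate_depth(w$cfg, w$scheme, tf, truth, "s",
                           seed = 700 + i + round(tf * 1000))
      estimate_tumor_fraction(to_log2_ratio(dp, w$pon, w$scheme),
                              w$scheme)$estimate$tumor_fraction
    }, 0)
    stats::median(est)
  }, 0)
  expect_true(all(diff(meds) > 0))
})
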