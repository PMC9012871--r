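test_that("GC correction is the identity for unbiased counts", {
  w <- small_world()
  sc <- w$scheme
  flat <- cfCNA:::new_depth_profile("flat", rep(400, n_bins(sc)), sc)
  out <- correct_gc(flat, sc)
  expect_equal(out$counts, flat$counts, tolerance = 1e-3)
  # conservation of the total count
  idx <- cfCNA:::analyzed_bins(sc)
  expect_equal(sum(out$counts[idx]), sum(flat$counts[idx]),
               tolerance = 1e-3)
})

test_that("GC correction removes a linear bias", {
  w <- small_world()
  sc <- w$scheme
  set.seed(21)
  gc <- sc$bins$gc
  mu <- 100 * (1 + (gc - 0.5))
  counts <- stats::rpois(n_bins(sc), mu)
  biased <- cfCNA:::new_depth_profile("b", counts, sc)
  idx <- cfCNA:::analyzed_bins(sc)
  r_before <- stats::cor(biased$counts[idx], gc[idx])
  out <- correct_gc(biased, sc)
  r_after <- stats::cor(out$counts[idx], gc[idx])
  expect_gt(abs(r_before), 0.3)
  expect_lt(abs(r_after), 0.05)
})

test_that("degenerate GC warns and returns input", {
  layout <- genome_layout("chr1", 1e8)
  sc <- annotate_bins(build_fixed_bins(layout, 1e6),
                      uniform_track(layout, 0.5), uniform_track(layout, 1))
  p <- cfCNA:::new_depth_profile("s", rep(10, n_bins(sc)), sc)
  expect_warning(out <- correct_gc(p, sc), "identity")
  expect_equal(out$counts, p$counts)
})

test_that("panel reference is the per-bin median of scaled controls", {
  sc <- fake_scheme(300)
  base <- rep(100, 300)
  mk <- function(id, v5, v6) {
    x <- base; x[5] <- v5; x[6] <- v6
    cfCNA:::new_depth_profile(id, x, sc)
  }
  # equal library sizes so scaling is a no-op
  controls <- list(mk("a", 8, 12), mk("b", 10, 10), mk("c", 12, 8))
  pon <- build_panel(controls, sc, gc_correct = FALSE)
  expect_equal(pon$reference[5], 10)
  expect_equal(pon$reference[6], 10)
  expect_equal(pon$n_controls, 3)

  # identical controls: reference equals the profile, MAD 0
  same <- list(mk("a", 100, 100), mk("b", 100, 100))
  pon2 <- build_panel(same, sc, gc_correct = FALSE)
  expect_equal(pon2$reference, base)
  expect_equal(pon2$dispersion, rep(0, 300))

  # merged mode pools the controls
  ponm <- build_panel(controls, sc, mode = "merged", gc_correct = FALSE)
  expect_equal(ponm$reference[5], 10)

  expect_error(build_panel(controls[1], sc), "at least 2")
})

test_that("panel medians on simulated controls match direct recomputation", {
  w <- small_world()
  mat <- vapply(w$controls, function(p) {
    q <- correct_gc(p, w$scheme)
    q$counts / sum(q$counts[cfCNA:::analyzed_bins(w$scheme)])
  }, numeric(n_bins(w$scheme)))
  target <- mean(vapply(w$controls, function(p)
    sum(p$counts[cfCNA:::analyzed_bins(w$scheme)]), 0))
  oracle <- apply(mat * target, 1, stats::median)
  expect_equal(w$pon$reference, oracle, tolerance = 1e-8)
})

test_that("log2 ratios are zero for a sample equal to the reference", {
  sc <- fake_scheme(300)
  counts <- rep(1000, 300)
  controls <- list(cfCNA:::new_depth_profile("a", counts, sc),
                   cfCNA:::new_depth_profile("b", counts, sc))
  pon <- build_panel(controls, sc, gc_correct = FALSE)
  np <- to_log2_ratio(cfCNA:::new_depth_profile("s", counts, sc), pon, sc,
                      gc_correct = FALSE)
  expect_equal(np$log2_ratio, rep(0, 300), tolerance = 1e-9)
})

test_that("a doubled bin gives log2 ratio 1 and the oracle matches", {
  sc <- fake_scheme(400)
  ref <- rep(1e5, 400)
  controls <- list(cfCNA:::new_depth_profile("a", ref, sc),
                   cfCNA:::new_depth_profile("b", ref, sc))
  pon <- build_panel(controls, sc, gc_correct = FALSE)
  x <- ref; x[10] <- 2e5
  np <- to_log2_ratio(cfCNA:::new_depth_profile("s", x, sc), pon, sc,
                      gc_correct = FALSE)
  # library scaling spreads the extra bin across all bins; undo the shift
  expect_equal(np$log2_ratio[10] - np$log2_ratio[11], 1, tolerance = 0.01)

  # elementwise oracle on a random profile
  set.seed(31)
  y <- round(stats::runif(400, 500, 2000))
  npy <- to_log2_ratio(cfCNA:::new_depth_profile("r", y, sc), pon, sc,
                       gc_correct = FALSE, center = "median")
  scaled <- y / sum(y) * pon$library_size
  oracle <- log2((scaled + 1) / (pon$reference + 1))
  oracle <- oracle - stats::median(oracle)
  expect_equal(npy$log2_ratio, oracle, tolerance = 1e-12)
})

test_that("normalizing a control against the panel is flat", {
  w <- small_world()
  for (p in w$controls[1:3]) {
    np <- to_log2_ratio(p, w$pon, w$scheme)
    expect_lt(abs(stats::median(np$log2_ratio[np$valid])), 0.02)
  }
})

test_that("panel and normalized profiles round-trip as TSV", {
  w <- small_world()
  p <- tempfile(); p2 <- tempfile()
  write_panel_tsv(w$pon, w$scheme, p)
  back <- read_panel_tsv(p)
  expect_equal(back$reference, w$pon$reference, tolerance = 1e-9)
  expect_equal(back$masked, w$pon$masked)
  expect_equal(back$n_controls, w$pon$n_controls)

  np <- to_log2_ratio(w$controls[[1]], w$pon, w$scheme)
  write_normalized_tsv(np, w$scheme, p2)
  np2 <- read_normalized_tsv(p2)
  expect_identical(np2$sample_id, np$sample_id)
  expect_equal(np2$log2_ratio, np$log2_ratio, tolerance = 1e-9)
  expect_equal(np2$valid, np$valid)
})
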