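mk_cohort_set <- function(id, gains = NULL, losses = NULL, n = 100) {
  # gains/losses: list of c(from_bin, to_bin, amplitude)
  segs <- list()
  add <- function(lst, state, sign) {
    for (g in lst) {
      segs[[length(segs) + 1]] <<- data.frame(
        chrom = "chr1", start = (g[1] - 1) * 1000, end = g[2] * 1000,
        n_bins = g[2] - g[1] + 1, mean_log2 = sign * g[3],
        copy_state = state, bin_from = g[1], bin_to = g[2],
        stringsAsFactors = FALSE)
    }
  }
  add(gains, "gain", 1)
  add(losses, "loss", -1)
  if (!length(segs)) {
    segs[[1]] <- data.frame(chrom = "chr1", start = 0, end = n * 1000,
                            n_bins = n, mean_log2 = 0,
                            copy_state = "neutral", bin_from = 1,
                            bin_to = n, stringsAsFactors = FALSE)
  }
  segment_set(id, "hmm_arm", do.call(rbind, segs))
}

test_that("per-dog maximum tumor fraction selection", {
  tab <- data.frame(dog_id = c("d1", "d1", "d2", "d3", "d3"),
                    sample_id = c("a", "b", "c", "d", "e"),
                    tumor_fraction = c(0.05, 0.21, 0.08, 0.3, 0.3),
                    date = c(1, 2, 1, 5, 2))
  got <- select_max_tf_sample(tab)
  expect_equal(got$sample_id[got$dog_id == "d1"], "b")
  expect_equal(got$sample_id[got$dog_id == "d2"], "c")
  # tie broken by earliest date
  expect_equal(got$sample_id[got$dog_id == "d3"], "e")
  # brute-force oracle on random cohorts
  set.seed(33)
  tab2 <- data.frame(dog_id = sample(paste0("d", 1:6), 30, TRUE),
                     sample_id = paste0("s", 1:30),
                     tumor_fraction = stats::runif(30))
  got2 <- select_max_tf_sample(tab2)
  oracle <- tapply(tab2$tumor_fraction, tab2$dog_id, max)
  expect_equal(got2$tumor_fraction[order(got2$dog_id)],
               as.numeric(oracle[sort(names(oracle))]))
})

test_that("G score is the mean matching-direction amplitude", {
  sc <- fake_scheme(100)
  one <- mk_cohort_set("s1", gains = list(c(11, 20, 0.5)))
  tr <- gscore(list(one), sc, "gain")
  expect_equal(tr$g_score[11:20], rep(0.5, 10))
  expect_equal(tr$g_score[-(11:20)], rep(0, 90))

  # two identical samples double the score relative to the mean of one
  # sample plus an empty one
  two <- list(one, mk_cohort_set("s2", gains = list(c(11, 20, 0.5))))
  mixed <- list(one, mk_cohort_set("s3"))
  expect_equal(gscore(two, sc, "gain")$g_score[15], 0.5)
  expect_equal(gscore(mixed, sc, "gain")$g_score[15], 0.25)

  # loss amplitudes never leak into the gain track
  both <- mk_cohort_set("s4", gains = list(c(1, 10, 0.4)),
                        losses = list(c(51, 60, 0.3)))
  tg <- gscore(list(both), sc, "gain")$g_score
  tl <- gscore(list(both), sc, "loss")$g_score
  expect_true(all(tg >= 0) && all(tl >= 0))
  expect_equal(sum(tg > 0 & tl > 0), 0)   # disjoint supports
  expect_equal(tl[51:60], rep(0.3, 10))
})

test_that("G equals a brute-force per-bin summation on random cohorts", {
  sc <- fake_scheme(80)
  set.seed(34)
  sets <- lapply(1:6, function(i) {
    from <- sample(1:60, 1); to <- from + sample(5:15, 1)
    mk_cohort_set(paste0("s", i), gains = list(c(from, min(to, 80),
                                                 stats::runif(1, 0.2, 0.6))),
                  n = 80)
  })
  tr <- gscore(sets, sc, "gain")
  oracle <- numeric(80)
  for (s in sets) {
    seg <- s$segments[s$segments$copy_state == "gain", ]
    oracle[seg$bin_from:seg$bin_to] <-
      oracle[seg$bin_from:seg$bin_to] + seg$mean_log2
  }
  expect_equal(tr$g_score, oracle / 6, tolerance = 1e-12)
})

test_that("permutation significance conventions hold", {
  sc <- fake_scheme(100)
  one <- mk_cohort_set("s1", gains = list(c(11, 20, 0.5)))
  tr <- permutation_significance(gscore(list(one), sc, "gain"),
                                 n_perm = 100, seed = 5)
  expect_equal(tr$perm_p[1], 1)              # observed G = 0 there
  expect_true(all(tr$perm_p >= 1 / 101 & tr$perm_p <= 1))
  expect_true(all(tr$q_value >= tr$perm_p - 1e-12))

  # all-zero amplitudes: no significant regions
  null <- mk_cohort_set("s1")
  trn <- permutation_significance(gscore(list(null), sc, "gain"),
                                  n_perm = 100, seed = 5)
  expect_equal(nrow(trn$significant_regions), 0)
  expect_error(permutation_significance(trn, n_perm = 10), "100")
})

test_that("permutation p-values are invariant to sample order", {
  sc <- fake_scheme(60)
  set.seed(35)
  sets <- lapply(1:5, function(i) {
    from <- sample(1:40, 1)
    mk_cohort_set(paste0("s", i),
                  gains = list(c(from, from + 9, stats::runif(1, 0.2, 0.5))),
                  n = 60)
  })
  t1 <- permutation_significance(gscore(sets, sc, "gain"),
                                 n_perm = 150, seed = 9)
  t2 <- permutation_significance(gscore(rev(sets), sc, "gain"),
                                 n_perm = 150, seed = 9)
  expect_equal(t1$perm_p, t2$perm_p)
})

test_that("recurrence TSV/BED outputs are written", {
  sc <- fake_scheme(50)
  cohort <- list(mk_cohort_set("a", gains = list(c(5, 14, 0.6)), n = 50),
                 mk_cohort_set("b", gains = list(c(6, 15, 0.5)), n = 50))
  tr <- permutation_significance(gscore(cohort, sc, "gain"),
                                 n_perm = 200, seed = 2, q_threshold = 0.5)
  p <- tempfile(); pb <- tempfile()
  write_recurrence_tsv(tr, p, pb)
  tab <- utils::read.table(p, header = TRUE)
  expect_equal(nrow(tab), 50)
  expect_true(all(c("g_score", "perm_p", "q_value") %in% names(tab)))
})
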