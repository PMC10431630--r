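test_that("subsequence scores are exact mean edge weights along the path", {
  # hand-built path: weights of its transitions are fixed by construction
  grid <- list(n_c = 2L, n_cell = 4L)
  path <- c(0L, 0L, 1L, 1L, 1L, 0L)
  g <- build_graph(path, grid)
  # transitions: (0,0)=1, (0,1)=1, (1,1)=2, (1,1)=2, (1,0)=1
  expect_equal(subsequence_score(g, path, 0, 2), (1 + 1) / 2)
  expect_equal(subsequence_score(g, path, 1, 3), (1 + 2 + 2) / 3)
  expect_equal(subsequence_score(g, path, 0, 5), (1 + 1 + 2 + 2 + 1) / 5)
  expect_error(subsequence_score(g, path, 5, 2), "start index")
  expect_error(subsequence_score(g, path, -1, 2), "start index")

  # constant path: every traversed edge has the same weight
  pc <- rep(3L, 12)
  gc <- build_graph(pc, list(n_c = 2L, n_cell = 4L))
  expect_equal(subsequence_score(gc, pc, 2, 5), 11)
})

test_that("score profiles equal per-index brute-force recomputation", {
  for (seed in 1:6) {
    set.seed(seed)
    n_c <- sample(3:8, 1)
    path <- sample(0:(n_c^2 - 1L), 150, replace = TRUE)
    g <- build_graph(path, list(n_c = n_c, n_cell = n_c^2))
    l <- sample(2:20, 1)
    prof <- score_profile(g, path, l)
    expect_length(prof$scores, length(path) - l)
    ref <- vapply(0:(length(path) - l - 1L), function(i) score_naive(g, path, i, l), 0)
    expect_lt(max(abs(prof$scores - ref)), 1e-12)
  }
})

test_that("profile scores scale linearly with uniform edge-weight scaling", {
  set.seed(4)
  path <- sample(0:8, 300, replace = TRUE)
  g <- build_graph(path, list(n_c = 3L, n_cell = 9L))
  prof <- score_profile(g, path, 15)
  g3 <- g
  g3$edges$weight <- 3L * g3$edges$weight
  prof3 <- score_profile(g3, path, 15)
  expect_equal(prof3$scores, 3 * prof$scores, tolerance = 1e-12)
})

test_that("moving-average smoothing matches the windowed-mean oracle and keeps length", {
  set.seed(2)
  prof <- structure(list(scores = rnorm(80, 50, 10), l = 10L, smoothed = FALSE),
                    class = "tsg_profile")
  for (w in c(1, 3, 5, 8, 21)) {
    sm <- smooth_scores(prof, w)
    expect_length(sm$scores, 80L)
    expect_true(sm$smoothed)
    expect_equal(sm$scores, moving_avg_naive(prof$scores, w), tolerance = 1e-12)
  }
  # constant profile unchanged
  cprof <- structure(list(scores = rep(7, 30), l = 5L, smoothed = FALSE),
                     class = "tsg_profile")
  expect_equal(smooth_scores(cprof, 9)$scores, rep(7, 30))
  # interior unit impulse spreads to 1/w over w positions
  iprof <- structure(list(scores = c(rep(0, 20), 1, rep(0, 20)), l = 5L,
                          smoothed = FALSE), class = "tsg_profile")
  sm5 <- smooth_scores(iprof, 5)
  expect_equal(sm5$scores[19:23], rep(1 / 5, 5))
  expect_equal(sum(sm5$scores > 0), 5L)
})

test_that("top-k selection is greedy with exclusion zones and deterministic ties", {
  prof <- structure(list(scores = c(5, 1, 4, 4, 4, 4, 4, 4, 4, 4, 4, 2, 9),
                         l = 3L, smoothed = TRUE), class = "tsg_profile")
  rep1 <- detect_topk(prof, k = 2, l = 3)
  expect_equal(rep1$start, c(1L, 11L))        # 0-based minima
  expect_equal(rep1$rank, 1:2)
  expect_true(all(diff(sort(rep1$start)) > 3))

  # two minima 10 apart with a wide exclusion zone: second one masked
  s <- rep(10, 200); s[50] <- 1; s[60] <- 1.5
  prof2 <- structure(list(scores = s, l = 110L, smoothed = TRUE),
                     class = "tsg_profile")
  rep2 <- detect_topk(prof2, k = 2, l = 110)
  expect_equal(nrow(rep2), 2L)
  expect_equal(rep2$start[1], 49L)
  expect_gt(abs(rep2$start[2] - rep2$start[1]), 110)  # survivor outside the zone
  expect_true(attr(detect_topk(prof2, k = 5, l = 110), "truncated"))

  # ties broken by earlier start
  tie <- structure(list(scores = rep(c(3, 8), 50), l = 2L, smoothed = TRUE),
                   class = "tsg_profile")
  expect_equal(detect_topk(tie, k = 1, l = 2)$start, 0L)

  # k = NULL returns the full post-exclusion ranking, scores non-decreasing
  full <- detect_topk(prof2, l = 110)
  expect_false(is.unsorted(full$score))
})

test_that("reported starts always differ by more than the subsequence length", {
  for (seed in 1:8) {
    s <- twin_fixture(seed)
    res <- tsg_detect(s, w_g = 80, l = 110, k = 6)
    st <- sort(res$report$start)
    if (length(st) > 1) expect_gt(min(diff(st)), 110)
  }
})

test_that("top-k accuracy scores hits one-to-one against ground truth", {
  truth <- data.frame(start = c(100, 400, 800), end = c(150, 460, 900))
  hit_all <- data.frame(rank = 1:3, start = c(120, 390, 850), length = 50)
  expect_equal(evaluate_topk(hit_all, truth), 1.0)
  none <- data.frame(rank = 1:3, start = c(0, 200, 600), length = 50)
  expect_equal(evaluate_topk(none, truth), 0.0)
  three_quarters <- data.frame(rank = 1:4, start = c(120, 390, 850, 125),
                               length = 50)
  expect_equal(evaluate_topk(three_quarters, truth), 0.75)  # 4th re-hits claimed
  # pad extends the flagged span to the right
  late <- data.frame(rank = 1, start = 60, length = 30)
  expect_equal(evaluate_topk(late, truth), 0.0)
  expect_equal(evaluate_topk(late, truth, pad = 20), 1.0)
})

test_that("variable-length scans reuse one graph and merge without overlap", {
  s <- twin_fixture(5, cycles = c(10, 30), length = 110)
  built <- build_series_graph(s$values, 80, 100)
  sc <- scan_lengths(built$graph, built$path, 90, 130, step = 20, k = 2,
                     smooth_window = 80)
  expect_equal(names(sc$per_length), c("90", "110", "130"))
  expect_equal(length(sc$per_length), 3L)  # floor((130-90)/20)+1

  # minL == maxL reproduces detect_topk at that length
  one <- scan_lengths(built$graph, built$path, 110, 110, k = 2,
                      smooth_window = 80)
  direct <- detect_topk(smooth_scores(score_profile(built$graph, built$path, 110), 80),
                        k = 2, l = 110)
  expect_equal(one$per_length[["110"]]$start, direct$start)
  expect_equal(one$per_length[["110"]]$score, direct$score)

  # merged entries are pairwise non-overlapping intervals
  m <- sc$merged
  if (nrow(m) > 1) {
    m <- m[order(m$start), ]
    expect_true(all(m$start[-1] >= (m$start + m$length)[-nrow(m)]))
  }
})

test_that("end-to-end detection is deterministic and its minima sit below normal scores", {
  s <- twin_fixture(13, cycles = 25, length = 110)
  r1 <- tsg_detect(s, w_g = 80, l = 110, k = 1)
  r2 <- tsg_detect(s, w_g = 80, l = 110, k = 1)
  expect_identical(r1$report$score, r2$report$score)
  expect_identical(r1$report$start, r2$report$start)
  # monotone separation: minimum inside the anomaly neighborhood is below the
  # median score elsewhere
  truth <- s$truth
  sc <- r1$profile$scores
  idx <- seq_along(sc) - 1L
  near <- idx >= truth$start - 190 & idx <= truth$end
  expect_lt(min(sc[near]), stats::median(sc[!near]))
})
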