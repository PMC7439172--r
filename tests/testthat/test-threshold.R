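two_mass_hist <- function() {
  p <- matrix(0, 4, 4); p[1, 1] <- 0.5; p[4, 4] <- 0.5
  hist_from_p(p, total = 2L)
}

test_that("class statistics follow the quadrant definitions", {
  h <- two_mass_hist()
  cs <- class_stats(h, 0L, 0L)
  expect_equal(cs$w0, 0.5)
  expect_equal(cs$w1, 0.5)
  expect_equal(unname(cs$u0), c(0, 0))
  expect_equal(unname(cs$u1), c(3, 3))
  expect_false(cs$degenerate)

  # constant histogram: everything in class 0 once s >= value
  hc <- hist_from_p({p <- matrix(0, 4, 4); p[2, 2] <- 1; p})
  cs <- class_stats(hc, 1L, 1L)
  expect_equal(cs$w0, 1)
  expect_equal(cs$w1, 0)
  expect_true(cs$degenerate)

  # uniform diagonal: w0 = (s+1)/L along s = t
  hd <- hist_from_p(diag(8) / 8, total = 8L)
  for (s in 0:6)
    expect_equal(class_stats(hd, s, s)$w0, (s + 1) / 8)

  expect_error(class_stats(h, 3L, 0L), "threshold")
  expect_error(class_stats(h, -1L, 0L), "threshold")
})

test_that("trace criterion matches hand evaluation and degenerates to 0", {
  h <- two_mass_hist()
  expect_equal(trace_criterion(h, 0, 0), 4.5)  # 2 * 0.5 * (2.25 + 2.25)

  hc <- hist_from_p({p <- matrix(0, 4, 4); p[2, 2] <- 1; p})
  for (s in 0:2) for (t in 0:2)
    expect_equal(trace_criterion(hc, s, t), 0)

  set.seed(21)
  h <- build_histogram2d(rand_image(8, 8, 8L), "avg_only", levels = 8L)
  for (q in 1:10) {
    st <- sample(0:6, 2, replace = TRUE)
    expect_gte(trace_criterion(h, st[1], st[2]), 0)
  }
})

test_that("fast criterion table equals direct summation everywhere", {
  set.seed(22)
  h <- build_histogram2d(rand_image(12, 12, 8L), "med_medavg", levels = 8L)
  cm <- otsu2d:::criterion_matrix(h)
  for (s in 0:6) for (t in 0:6)
    expect_equal(cm[s + 1, t + 1], trace_criterion(h, s, t),
                 tolerance = 1e-9)
})

test_that("threshold search equals the exhaustive oracle with lexicographic ties", {
  tp <- find_threshold(two_mass_hist())
  expect_identical(c(tp$s, tp$t), c(0L, 0L))  # ties at s,t in {0,1,2}
  expect_equal(tp$criterion, 4.5)

  set.seed(23)
  for (rep in 1:12) {
    h <- build_histogram2d(rand_image(12, 12, 8L),
                           sample(c("avg_only", "med_medavg"), 1),
                           levels = 8L)
    tp <- find_threshold(h)
    or <- naive_find_threshold(h)
    expect_identical(c(tp$s, tp$t), c(or$s, or$t))
    expect_equal(tp$criterion, or$criterion, tolerance = 1e-9)
  }
})

test_that("constant histograms warn and return the constant's level", {
  h <- build_histogram2d(matrix(3L, 5, 5), "avg_only", levels = 8L)
  expect_warning(tp <- find_threshold(h), "degenerate")
  expect_identical(c(tp$s, tp$t), c(3L, 3L))
  expect_equal(tp$criterion, 0)
  expect_true(tp$degenerate)
})

test_that("thresholds shift with a constant gray-level offset", {
  set.seed(24)
  img <- rand_image(16, 16, 5L)  # levels 0..4, room to shift within 0..7
  h1 <- build_histogram2d(img, "avg_only", levels = 8L)
  h2 <- build_histogram2d(img + 3L, "avg_only", levels = 8L)
  tp1 <- find_threshold(h1)
  tp2 <- find_threshold(h2)
  expect_identical(tp2$s, tp1$s + 3L)
  expect_identical(tp2$t, tp1$t + 3L)
  expect_equal(tp2$criterion, tp1$criterion, tolerance = 1e-9)
})

test_that("binarize assigns quadrants I/IV directly and II/III by rule", {
  pair <- list(first = matrix(c(50L, 200L, 200L, 50L), 2, 2),
               smooth = matrix(c(50L, 200L, 10L, 210L), 2, 2))
  tp <- list(s = 100L, t = 100L)
  # (50,50) I -> 0; (200,200) IV -> 1; (200,10) III; (50,210) II
  expect_identical(as.vector(binarize(pair, tp, "smoothed")),
                   c(0L, 1L, 0L, 1L))
  expect_identical(as.vector(binarize(pair, tp, "raw")),
                   c(0L, 1L, 1L, 0L))
  # (200,10) is nearer u0 = (40,40); (50,210) nearer u1 = (205,205)
  st <- list(u0 = c(i = 40, j = 40), u1 = c(i = 205, j = 205))
  expect_identical(as.vector(binarize(pair, tp, "nearest", stats = st)),
                   c(0L, 1L, 0L, 1L))
  expect_error(binarize(pair, tp, "nearest"), "stats")

  const <- list(first = matrix(10L, 3, 3), smooth = matrix(10L, 3, 3))
  expect_identical(binarize(const, list(s = 100L, t = 100L)),
                   matrix(0L, 3, 3))
  expect_identical(binarize(const, list(s = 5L, t = 5L)), matrix(1L, 3, 3))
})
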