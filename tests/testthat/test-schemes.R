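test_that("identical parts give equal per-part, whole-image and joint optima", {
  img <- mirrored_halves(seed = 41)
  regions <- half_split_regions(nrow(img), ncol(img))
  pair <- coordinate_images(img, "med_medavg")

  s1 <- scheme1(img, regions, pair = pair)
  h_whole <- build_histogram2d(img, pair = pair)
  tp_whole <- find_threshold(h_whole)
  expect_identical(c(s1$thresholds[[1]]$s, s1$thresholds[[1]]$t),
                   c(tp_whole$s, tp_whole$t))
  expect_identical(c(s1$thresholds[[2]]$s, s1$thresholds[[2]]$t),
                   c(tp_whole$s, tp_whole$t))

  s2 <- scheme2(img, regions, pair = pair)
  expect_identical(c(s2$thresholds[[1]]$s, s2$thresholds[[1]]$t),
                   c(tp_whole$s, tp_whole$t))
})

test_that("the joint product objective matches exhaustive search at L = 8", {
  set.seed(42)
  for (rep in 1:5) {
    img <- rand_image(12, 12, 8L)
    regions <- half_split_regions(12L, 12L)
    pair <- coordinate_images(img, "avg_only")
    h1 <- build_histogram2d(img, region = regions$part1, pair = pair,
                            levels = 8L)
    h2 <- build_histogram2d(img, region = regions$part2, pair = pair,
                            levels = 8L)
    best <- -1; bs <- bt <- 0L
    for (s in 0:6) for (t in 0:6) {
      v <- trace_criterion(h1, s, t) * trace_criterion(h2, s, t)
      if (v > best) { best <- v; bs <- s; bt <- t }
    }
    s2 <- scheme2(img, regions, pair = pair, levels = 8L)
    expect_identical(c(s2$thresholds[[1]]$s, s2$thresholds[[1]]$t),
                     c(bs, bt))
    expect_equal(s2$thresholds[[1]]$criterion, best, tolerance = 1e-9)
  }
})

test_that("the product objective is invariant to swapping the parts", {
  set.seed(43)
  img <- rand_image(14, 14, 16L)
  regions <- half_split_regions(14L, 14L)
  a <- scheme2(img, regions, levels = 16L)
  b <- scheme2(img, list(part1 = regions$part2, part2 = regions$part1),
               levels = 16L)
  expect_identical(c(a$thresholds[[1]]$s, a$thresholds[[1]]$t),
                   c(b$thresholds[[1]]$s, b$thresholds[[1]]$t))
})

test_that("the stitched scheme-1 mask equals per-part binarization", {
  sc <- synth_preset("coins", seed = 44)
  fit <- otsu2d(sc$image, scheme = "split1", keep_image = TRUE)
  s1 <- fit$fits$split1
  pair <- coordinate_images(sc$image, "med_medavg")
  regions <- partition(dim(sc$image), fit$split)
  for (q in 1:2) {
    pm <- binarize(pair, s1$thresholds[[q]])
    expect_identical(s1$mask[regions[[q]]], pm[regions[[q]]])
  }
})

test_that("constant images degenerate to an all-background mask", {
  img <- matrix(7L, 16, 16)
  regions <- half_split_regions(16L, 16L)
  w1 <- capture_warnings(s1 <- scheme1(img, regions))
  expect_match(w1, "degenerate", all = TRUE)
  expect_length(w1, 2L)  # one per constant part
  expect_identical(s1$mask, matrix(0L, 16, 16))
  expect_true(all(s1$degenerate))

  w2 <- capture_warnings(s2 <- scheme2(img, regions))
  expect_match(w2, "degenerate", all = TRUE)
  expect_equal(s2$thresholds[[1]]$criterion, 0)
})

test_that("partition schemes recover dark-region foreground under uneven light", {
  un <- synth_preset("uneven", seed = 45)
  fit <- otsu2d(un$image, scheme = "both", truth = un$mask,
                keep_image = FALSE)
  glob <- otsu2d(un$image, scheme = "global", truth = un$mask,
                 keep_image = FALSE)
  expect_lt(fit$metrics$split1$me, glob$metrics$global$me)
  expect_identical(fit$selected, "split1")
  # the split line sits at the illumination boundary (middle of 96 rows)
  expect_true(all(abs(fit$split$rows - 48.5) <= 2))
})

test_that("the otsu2d fit object supports the standard methods", {
  sc <- synth_preset("coins", seed = 46)
  fit <- otsu2d(sc$image, scheme = "both", truth = sc$mask)

  expect_s3_class(fit, "otsu2d")
  expect_output(print(fit), "selected")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.otsu2d")
  expect_identical(nrow(sm$table), 3L)  # split1 has two parts, split2 one
  expect_output(print(sm), "scheme")

  cf <- coef(fit)
  expect_identical(colnames(cf), c("s", "t", "criterion"))
  expect_true(all(cf[, "criterion"] >= 0))

  mask <- fitted(fit)
  expect_true(all(mask %in% 0:1) && all(dim(mask) == dim(sc$image)))
  expect_identical(fitted(fit, scheme = "split2"), fit$fits$split2$mask)
  expect_error(fitted(fit, scheme = "nope"), "no fitted scheme")

  res <- residuals(fit)
  expect_true(all(res %in% -1:1))
  expect_equal(mean(res != 0), fit$metrics[[fit$selected]]$me)

  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f, width = 480, height = 200)
  expect_silent(plot(fit))
  grDevices::dev.off()
})

test_that("prediction transfers thresholds to new images", {
  sc <- synth_preset("coins", seed = 47)
  fit <- otsu2d(sc$image, scheme = "global")
  expect_identical(predict(fit, sc$image), fitted(fit))
  expect_identical(predict(fit), fitted(fit))

  sc2 <- synth_preset("coins", seed = 48)
  pred <- predict(fit, sc2$image)
  expect_lt(evaluate_mask(pred, sc2$mask)$me, 0.08)

  fitb <- otsu2d(sc$image, scheme = "both", truth = sc$mask)
  pred2 <- predict(fitb, sc2$image, scheme = "split1")
  expect_lt(evaluate_mask(pred2, sc2$mask)$me, 0.08)
})

test_that("no-truth fits keep both masks without selecting", {
  sc <- synth_preset("coins", seed = 49)
  fit <- otsu2d(sc$image, scheme = "both", keep_image = FALSE)
  expect_true(is.na(fit$selected))
  expect_setequal(names(fit$fits), c("split1", "split2"))
  expect_null(fit$metrics)
})
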