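test_that("colour energy is the squared vertical difference, first row 0", {
  expect_equal(color_energy(matrix(7L, 4, 5)), matrix(0, 4, 5))

  two <- rbind(rep(10L, 3), rep(20L, 3))
  ec <- color_energy(two)
  expect_equal(ec[1, ], rep(0, 3))
  expect_equal(ec[2, ], rep(100, 3))

  set.seed(31)
  img <- rand_image(6, 6)
  expect_equal(color_energy(img)[1, ], rep(0, 6))
  expect_equal(color_energy(matrix(9L, 1, 4)), matrix(0, 1, 4))
})

test_that("geometric energy is the Sobel gradient magnitude", {
  expect_equal(geometric_energy(matrix(3L, 5, 5)), matrix(0, 5, 5))

  img <- cbind(rep(0L, 3), rep(0L, 3), rep(255L, 3))
  eg <- geometric_energy(img)
  expect_equal(eg[2, 2], 1020)  # |Gx| = 4 * 255, Gy = 0 on a vertical edge

  horiz <- rbind(rep(0L, 3), rep(0L, 3), rep(255L, 3))
  expect_equal(geometric_energy(horiz)[2, 2], 1020)  # transposed case
})

test_that("position weight follows the Gaussian centred at m/2", {
  w <- position_weight(4)
  expect_equal(w[1], exp(-4 / 8))  # x = 0, sigma = m/2 = 2
  expect_equal(w[3], 1)            # x = m/2
  expect_equal(w, rev(c(w[-1], exp(-4 / 8))), tolerance = 1e-12)

  wl <- position_weight(4, sigma = "literal_2m")
  expect_equal(wl[1], exp(-4 / 8))  # coincides at m = 4 where m^2/2 = 2m
  m <- 100L
  expect_lt(position_weight(m, "literal_2m")[1],
            position_weight(m, "half_m")[1])  # literal form is far narrower
  expect_true(all(position_weight(m) > 0 & position_weight(m) <= 1))
})

test_that("energy map combines its components elementwise", {
  set.seed(32)
  img <- rand_image(8, 10)
  em <- energy_map(img)
  expect_equal(em$E, em$wpos * (2 * em$color - 1 * em$geom))
  em2 <- energy_map(img, w_color = 3, w_geom = 0.5)
  expect_equal(em2$E, em2$wpos * (3 * em2$color - 0.5 * em2$geom))
  expect_equal(energy_map(matrix(5L, 6, 6))$E, matrix(0, 6, 6))
  expect_equal(energy_map(img, source = "median")$color,
               color_energy(median_filter(img)))
})

test_that("DP split line solves the small instances exactly", {
  E <- matrix(c(1, 0, 0, 3, 5, 0), 2, 3)
  sp <- find_splitline(E)
  expect_identical(sp$rows, c(1L, 2L, 1L))
  expect_equal(sp$total_energy, 9)
  expect_equal(sp$mean_energy, 3)

  sp0 <- find_splitline(matrix(0, 4, 5))
  expect_identical(sp0$rows, rep(1L, 5))  # ties break to the smallest row
  expect_equal(sp0$total_energy, 0)

  expect_identical(find_splitline(matrix(c(2, 7), 1, 2))$rows, c(1L, 1L))
})

test_that("DP equals full path enumeration on random maps", {
  set.seed(33)
  for (rep in 1:40) {
    m <- sample(1:6, 1); n <- sample(1:6, 1)
    E <- matrix(round(rnorm(m * n), 2), m, n)
    expect_equal(find_splitline(E)$total_energy, enumerate_best_path(E),
                 tolerance = 1e-9)
  }
})

test_that("positive scaling of the energy leaves the path unchanged", {
  set.seed(34)
  E <- matrix(rnorm(30), 5, 6)
  expect_identical(find_splitline(E)$rows, find_splitline(10 * E)$rows)
  expect_identical(find_splitline(E)$rows, find_splitline(0.03 * E)$rows)
})

test_that("the line locks onto a one-row illumination step", {
  set.seed(35)
  img <- rbind(matrix(200L, 20, 40), matrix(60L, 20, 40))
  img <- as_gray_image(pmin(pmax(img + rnorm(800, sd = 5), 0), 255))
  sp <- find_splitline(energy_map(img))
  expect_gte(mean(sp$rows == 21L), 0.95)  # within the transition row
})

test_that("partition splits the image into complementary parts", {
  sp <- find_splitline(matrix(0, 6, 8))
  sp$rows <- rep(3L, 8)
  parts <- partition(c(6L, 8L), sp)
  expect_identical(sum(parts$part1), 3L * 8L)
  expect_identical(parts$part1, !parts$part2)

  sp$rows <- rep(1L, 8)
  parts <- partition(c(2L, 8L), sp)
  expect_true(all(parts$part1[1, ]) && all(parts$part2[2, ]))

  sp$rows <- rep(2L, 8)  # line on the bottom row: part 2 empty
  parts <- partition(c(2L, 8L), sp)
  expect_false(any(parts$part2))
})
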