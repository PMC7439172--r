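# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately naive (loops, direct summation, full
# enumeration) so it exercises the definitions, not the implementation.

rand_image <- function(m, n, levels = 256L) {
  matrix(sample.int(levels, m * n, replace = TRUE) - 1L, m, n)
}

# build a histogram2d object straight from a joint probability table,
# bypassing the image pipeline (unit fixtures for histogram-level ops)
hist_from_p <- function(p, total = 1000L) {
  L <- nrow(p)
  counts <- round(p * total)
  total <- sum(counts)
  lv <- 0:(L - 1L)
  pp <- counts / total
  structure(list(counts = counts, p = pp, total = total,
                 mean = c(i = sum(lv * rowSums(pp)),
                          j = sum(lv * colSums(pp))),
                 levels = L, strategy = "manual", k = 3L),
            class = "histogram2d")
}

# naive threshold search: direct summation over the probability table for
# every (s, t), lexicographic tie-break; O(L^4)
naive_find_threshold <- function(h) {
  L <- h$levels
  lv <- 0:(L - 1L)
  uT <- c(sum(lv * rowSums(h$p)), sum(lv * colSums(h$p)))
  best <- -1; bs <- bt <- 0L
  for (s in 0:(L - 2L)) {
    for (t in 0:(L - 2L)) {
      i0 <- 1:(s + 1L); j0 <- 1:(t + 1L)
      i1 <- (s + 2L):L; j1 <- (t + 2L):L
      p0 <- h$p[i0, j0, drop = FALSE]
      p1 <- h$p[i1, j1, drop = FALSE]
      n0 <- sum(h$counts[i0, j0]); n1 <- sum(h$counts[i1, j1])
      crit <- if (n0 == 0L || n1 == 0L) 0 else {
        w0 <- sum(p0); w1 <- sum(p1)
        u0 <- c(sum(lv[i0] * rowSums(p0)), sum(lv[j0] * colSums(p0))) / w0
        u1 <- c(sum(lv[i1] * rowSums(p1)), sum(lv[j1] * colSums(p1))) / w1
        w0 * sum((u0 - uT)^2) + w1 * sum((u1 - uT)^2)
      }
      if (crit > best) { best <- crit; bs <- s; bt <- t }
    }
  }
  list(s = bs, t = bt, criterion = best)
}

# enumerate every 8-connected left-to-right path (one row per column) and
# return the maximum total energy; feasible for m, n <= 6
enumerate_best_path <- function(E) {
  m <- nrow(E); n <- ncol(E)
  best <- -Inf
  walk <- function(row, col, acc) {
    acc <- acc + E[row, col]
    if (col == n) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    for (nxt in max(1L, row - 1L):min(m, row + 1L)) walk(nxt, col + 1L, acc)
  }
  for (r in seq_len(m)) walk(r, 1L, 0)
  best
}

# windowed-loop oracle for the k x k filters with replicate padding
filter_oracle <- function(img, k, stat) {
  m <- nrow(img); n <- ncol(img); r <- (k - 1L) %/% 2L
  out <- matrix(0L, m, n)
  for (x in seq_len(m)) {
    for (y in seq_len(n)) {
      xs <- pmin(pmax((x - r):(x + r), 1L), m)
      ys <- pmin(pmax((y - r):(y + r), 1L), n)
      w <- as.vector(img[xs, ys])
      out[x, y] <- if (stat == "median") as.integer(median(w))
                   else as.integer(floor(mean(w) + 0.5))
    }
  }
  out
}

# confusion counts by explicit pixel loop
count_oracle <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (q in seq_along(pred)) {
    if (pred[q] == 1L && truth[q] == 1L) tp <- tp + 1L
    else if (pred[q] == 1L) fp <- fp + 1L
    else if (truth[q] == 1L) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# image whose two vertical halves are exact copies, with rows near the
# seam constant so the (global) filters see no stitch artefact
mirrored_halves <- function(seed = 1L) {
  set.seed(seed)
  half <- matrix(60L, 32L, 48L)
  X <- matrix(seq_len(32L), 32L, 48L)
  Y <- matrix(seq_len(48L), 32L, 48L, byrow = TRUE)
  for (cy in c(12, 36)) half[(X - 14)^2 + (Y - cy)^2 <= 49] <- 180L
  noise <- matrix(sample(-2:2, 32L * 48L, replace = TRUE), 32L, 48L)
  noise[c(1L, 2L, 31L, 32L), ] <- 0L  # flat seam rows: stacking the copies
  half <- half + noise                # introduces no filter-window artefact
  rbind(half, half)
}

half_split_regions <- function(m, n) {
  path <- structure(list(rows = rep(m %/% 2L, n), total_energy = 0,
                         mean_energy = 0), class = "split_path")
  partition(c(m, n), path)
}
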