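test_that("uniform samples give a flat estimated surface", {
  set.seed(41)
  cv <- cbind(runif(2e5, -1, 1), runif(2e5, -1, 1))
  fes <- estimate_fes(cv, bounds = c(-1, 1), bins = 20, beta = 1 / 0.616)
  expect_equal(min(fes$F, na.rm = TRUE), 0)
  # per-cell z-scores against the multinomial noise scale kT/sqrt(count),
  # Bonferroni-style bound over the 400 cells
  counts <- fes$W * 2e5
  z <- (fes$F - median(fes$F, na.rm = TRUE)) * sqrt(counts) / 0.616
  expect_lt(max(abs(z), na.rm = TRUE), 5)
})

test_that("a standard normal recovers quadratic free energy with beta = 1", {
  set.seed(42)
  cv <- matrix(rnorm(2e5), ncol = 2)
  fes <- estimate_fes(cv, bounds = c(-3, 3), bins = 30, beta = 1)
  idx <- which(is.finite(fes$F) & outer(fes$x^2, fes$y^2, "+") < 4,
               arr.ind = TRUE)
  df <- data.frame(F = fes$F[idx],
                   q = (fes$x[idx[, 1]]^2 + fes$y[idx[, 2]]^2) / 2)
  fit <- lm(F ~ q, data = df)
  expect_equal(unname(coef(fit)["q"]), 1, tolerance = 0.1)
})

test_that("grid normalization and domain contracts hold", {
  set.seed(43)
  cv <- matrix(rnorm(1000, sd = 0.3), ncol = 2)
  fes <- estimate_fes(cv, bounds = c(-2, 2), bins = 25)
  expect_identical(min(fes$F, na.rm = TRUE), 0)
  # far-corner cells are flagged NA, not zero
  expect_true(is.na(fes$F[1, 1]))
  expect_error(estimate_fes(cv + 100, bounds = c(-2, 2)), "outside")
})

test_that("a flat surface has zero barrier", {
  fes <- as_fes_grid(matrix(1, 8, 8))
  p <- minimum_energy_path(fes, c(1, 1), c(8, 8))
  expect_equal(p$barrier, 0)
  expect_equal(nrow(p$path), 8L)  # 8-connected diagonal walk
})

test_that("the minimax search matches exhaustive path enumeration", {
  set.seed(44)
  for (rep_i in 1:15) {
    F <- matrix(runif(20), 4, 5)
    fes <- as_fes_grid(F)
    got <- minimum_energy_path(fes, c(1, 1), c(4, 5))
    expect_equal(got$threshold, dfs_minimax(fes$F, c(1, 1), c(4, 5)))
    expect_equal(got$barrier, got$threshold - fes$F[1, 1])
  }
})

test_that("the minimax search matches threshold-BFS on 12 x 12 grids", {
  set.seed(45)
  for (rep_i in 1:10) {
    F <- matrix(runif(144), 12, 12)
    F[sample(144, 15)] <- NA  # unestimated cells are impassable
    F[1, 1] <- 0; F[12, 12] <- 0
    fes <- as_fes_grid(F)
    got <- tryCatch(minimum_energy_path(fes, c(1, 1), c(12, 12)),
                    error = function(e) NULL)
    ref <- threshold_minimax(fes$F, c(1, 1), c(12, 12))
    if (is.null(got)) {
      expect_true(is.infinite(ref))
    } else {
      expect_equal(got$threshold, ref)
      # returned path is 8-connected and stays at or below the threshold
      steps <- abs(diff(as.matrix(got$path[, c("i", "j")])))
      expect_true(all(steps <= 1))
      expect_true(all(got$path$F <= got$threshold))
    }
  }
})

test_that("a discretized double well recovers its barrier to one bin's resolution", {
  x <- seq(-1.6, 1.6, length.out = 80)
  prof <- 3.0 * (x^2 - 1)^2          # analytic barrier 3.0 at x = 0
  F <- matrix(rep(prof, 3), nrow = 80)
  fes <- as_fes_grid(F, x = x, y = 1:3)
  p <- minimum_energy_path(fes, c(-1, 2), c(1, 2))
  resolution <- max(abs(diff(prof)))
  expect_equal(p$barrier, 3.0, tolerance = resolution / 3.0)
})

test_that("disconnected endpoints raise a connectivity error", {
  F <- matrix(0, 9, 9)
  F[5, ] <- NA
  fes <- as_fes_grid(F)
  expect_error(minimum_energy_path(fes, c(1, 5), c(9, 5)), "connectivity")
  expect_error(minimum_energy_path(fes, c(5, 1), c(9, 5)), "unestimated")
})

test_that("block errors are zero for duplicated data and nonnegative", {
  set.seed(46)
  base <- cbind(c(rnorm(3000, -0.8, 0.4), rnorm(3000, 0.8, 0.4)),
                rnorm(6000, 0, 0.4))
  cv <- base[rep(1:6000, times = 4), ]
  ep <- list(list(name = "well", start = c(-0.8, 0), end = c(0.8, 0)))
  be <- barrier_errors(cv, bounds = c(-2, 2), bins = 20, beta = 1,
                       n_blocks = 4, endpoints = ep)
  expect_equal(be$error, 0, tolerance = 1e-12)
  expect_gte(be$barrier, 0)
})

test_that("block errors scale like one over the square root of the data", {
  set.seed(47)
  draw <- function(n) {
    cv <- cbind(c(rnorm(n / 2, -0.8, 0.4), rnorm(n / 2, 0.8, 0.4)),
                rnorm(n, 0, 0.4))
    cv[sample(nrow(cv)), ]  # iid in time so every block sees both wells
  }
  ep <- list(list(name = "well", start = c(-0.8, 0), end = c(0.8, 0)))
  # fixed per-block size: total data grows with the block count
  err_for <- function(B, reps) {
    mean(vapply(seq_len(reps), function(r) {
      cv <- draw(4000L * B)
      barrier_errors(cv, bounds = c(-2.2, 2.2), bins = 16, beta = 1,
                     n_blocks = B, endpoints = ep)$error
    }, numeric(1)))
  }
  e4 <- err_for(4L, 8L)
  e16 <- err_for(16L, 8L)
  expect_equal(e16 / e4, 0.5, tolerance = 0.2)
})

test_that("pathway masks split the plane along the diagonal with a band", {
  fes <- as_fes_grid(matrix(0, 20, 20), x = seq(-7.5, 7.5, length.out = 20),
                     y = seq(-7.5, 7.5, length.out = 20))
  m1 <- pathway_mask(fes, "INT1")
  m2 <- pathway_mask(fes, "INT2")
  expect_true(all(m1 | m2))            # the band belongs to both
  expect_true(m1[15, 5] && !m1[5, 15]) # INT1 side: cv1 > cv2
  expect_true(m2[5, 15] && !m2[15, 5])
})
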