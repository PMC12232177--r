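test_that("the potential has its four minima at the designed centers", {
  sys <- default_system()
  for (s in rownames(sys$centers)) {
    o <- optim(sys$centers[s, ] + 0.02,
               function(x) surrogate_potential(sys, x)$energy,
               gr = function(x) surrogate_potential(sys, x)$gradient,
               method = "BFGS")
    expect_lt(max(abs(o$par - sys$centers[s, ])), 0.05)
    expect_equal(o$value, unname(sys$basin_energies[s]), tolerance = 1e-6)
    g <- surrogate_potential(sys, sys$centers[s, ])$gradient
    expect_lt(max(abs(g)), 1e-6)
  }
  expect_equal(surrogate_potential(sys, c(0, 0))$energy, 0)
})

test_that("edge saddles scan to their calibrated heights", {
  sys <- default_system()
  t <- seq(0, 1, length.out = 20001)
  scan <- function(X) max(surrogate_potential(sys, X)$energy)
  expect_equal(scan(cbind(t, 0)), 7.5, tolerance = 0.1)
  expect_equal(scan(cbind(1, t)), 15.0, tolerance = 0.1)
  expect_equal(scan(cbind(0, t)), 17.0, tolerance = 0.1)
  # INT2-POST saddle sits int2_post_barrier above the INT2 basin
  expect_equal(scan(cbind(t, 1)) - sys$basin_energies[["INT2"]], 10.0,
               tolerance = 0.1)
})

test_that("a symmetric configuration gives a swap-symmetric potential", {
  sys <- build_surrogate(
    basin_energies = c(PRE = 0, INT1 = 2, INT2 = 2, POST = 1),
    saddle_heights = c(9, 9, 9, 9))
  set.seed(4)
  X <- matrix(runif(60, -0.3, 1.3), ncol = 2)
  v1 <- surrogate_potential(sys, X)$energy
  v2 <- surrogate_potential(sys, X[, 2:1])$energy
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("analytic gradients agree with central differences", {
  sys <- default_system()
  set.seed(7)
  X <- matrix(runif(40, -0.3, 1.3), ncol = 2)
  g <- surrogate_potential(sys, X)$gradient
  h <- 1e-6
  for (d in 1:2) {
    e <- matrix(0, nrow(X), 2); e[, d] <- h
    num <- (surrogate_potential(sys, X + e)$energy -
            surrogate_potential(sys, X - e)$energy) / (2 * h)
    expect_equal(g[, d], num, tolerance = 1e-4)
  }
})

test_that("the diagonal crossing dominates every edge saddle", {
  sys <- default_system()
  vmid <- surrogate_potential(sys, c(0.5, 0.5))$energy
  expect_gte(vmid, max(sys$saddle_heights) + 10 * sys$kT)
  # with one dominant edge saddle the Coons blend alone cannot clear the
  # 10 kT margin; the build must refuse
  expect_error(build_surrogate(saddle_heights = c(4, 4, 20, 4),
                               diagonal_penalty = 0), "diagonal")
})

test_that("invalid configurations are rejected with configuration errors", {
  expect_error(build_surrogate(kT = 0), "configuration error")
  expect_error(build_surrogate(timestep = -1), "configuration error")
  expect_error(build_surrogate(saddle_heights = c(1, 15, 17, 13)),
               "configuration error")  # saddle below the INT1 basin
  expect_error(simulate_surrogate(default_system(), 0), "n_steps")
})

test_that("zero-temperature dynamics pins a basin center", {
  sys <- default_system()
  tr <- simulate_surrogate(sys, 5000, x0 = "INT1", seed = 3, kT = 0)
  expect_lt(max(abs(sweep(tr$latent, 2, sys$centers["INT1", ]))), 1e-6)
})

test_that("zero-temperature relaxation is steepest descent (energy non-increasing)", {
  sys <- default_system()
  set.seed(9)
  tr <- simulate_surrogate(sys, 4000, x0 = c(0.35, 0.12), seed = 9, kT = 0,
                           record_stride = 1L)
  e <- surrogate_potential(sys, tr$latent)$energy
  expect_true(all(diff(e) <= 1e-9))
})

test_that("the sampler satisfies harmonic equipartition within 5%", {
  set.seed(1)
  r <- opescv:::cpp_sim1d(0L, c(1), 0, 2e6, 1e-3, 0.616, 10L, NULL, NULL)
  expect_equal(var(r$x), 0.616, tolerance = 0.05)
})

test_that("identical seeds give bitwise-identical trajectories", {
  sys <- default_system()
  t1 <- simulate_surrogate(sys, 20000, seed = 42)
  t2 <- simulate_surrogate(sys, 20000, seed = 42)
  expect_identical(t1$latent, t2$latent)
  t3 <- simulate_surrogate(sys, 20000, seed = 43)
  expect_false(identical(t1$latent, t3$latent))
})

test_that("divergent integration reports the failing step", {
  set.seed(1)
  expect_error(opescv:::cpp_sim1d(1L, c(1, 0), 1e3, 1000, 10, 0.616, 1L, NULL, NULL),
               "diverged at step")
})

test_that("unbiased double-well occupancy follows the Boltzmann ratio", {
  # V(x) = h (x^2-1)^2 + c x ; occupancy(x<0)/occupancy(x>0) vs quadrature
  kT <- 0.616; h <- 1.0; tilt <- 0.4
  set.seed(5)
  r <- opescv:::cpp_sim1d(1L, c(h, tilt), -1, 4e6, 5e-4, kT, 20L, NULL, NULL)
  frac <- mean(r$x < 0)
  xg <- seq(-3, 3, 1e-3)
  p <- exp(-(h * (xg^2 - 1)^2 + tilt * xg) / kT)
  frac_true <- sum(p[xg < 0]) / sum(p)
  # standard error from contiguous blocks of the (correlated) series
  bl <- tapply(r$x < 0, ceiling(seq_along(r$x) / (length(r$x) / 20)), mean)
  se <- sd(bl) / sqrt(length(bl))
  expect_lt(abs(frac - frac_true), 3 * max(se, 1e-3))
})

test_that("noise-free descriptors are a deterministic function of the latent state", {
  sys <- default_system()
  specs <- descriptor_specs()[1:25, ]
  X <- matrix(runif(40, 0, 1), ncol = 2)
  d1 <- emit_descriptors(sys, X, specs, seed = 1, noise = FALSE)
  d2 <- emit_descriptors(sys, X, specs, seed = 99, noise = FALSE)
  expect_identical(d1$values, d2$values)
  # column 1 responds to axis 1 through the documented logistic switch
  s <- specs[1, ]
  expect_equal(d1$values[, 1],
               s$base + s$amp * plogis((X[, s$axis] - 0.5) / s$tau))
})

test_that("informative columns separate exactly the states their axis encodes", {
  sys <- default_system()
  specs <- descriptor_specs()
  pre <- emit_descriptors(sys, sample_frames_for_test(sys, "PRE"), specs, 11)
  int1 <- emit_descriptors(sys, sample_frames_for_test(sys, "INT1"), specs, 12)
  shift <- abs(colMeans(pre$values) - colMeans(int1$values))
  sdm <- pmax(apply(pre$values, 2, sd), apply(int1$values, 2, sd))
  primer <- specs$class == "informative_primer"
  templ <- specs$class == "informative_template"
  nd <- specs$class == "non_discriminative"
  # PRE -> INT1 moves only the primer axis
  expect_true(all(shift[primer] > 2 * sdm[primer]))
  expect_true(all(shift[templ] < 2 * sdm[templ]))
  expect_true(all(shift[nd] < 2 * sdm[nd]))
})

test_that("non-discriminative columns stay below two SD for all state pairs", {
  sys <- default_system()
  specs <- descriptor_specs(n_informative = 4L, n_redundant = 0L,
                            n_low_presence = 0L, n_non_discriminative = 10L)
  tabs <- lapply(rownames(sys$centers), function(s)
    emit_descriptors(sys, sample_frames_for_test(sys, s), specs,
                     seed = 50 + match(s, rownames(sys$centers))))
  nd <- which(specs$class == "non_discriminative")
  for (a in 1:3) for (b in (a + 1):4) {
    shift <- abs(colMeans(tabs[[a]]$values[, nd, drop = FALSE]) -
                 colMeans(tabs[[b]]$values[, nd, drop = FALSE]))
    sdm <- pmax(apply(tabs[[a]]$values[, nd, drop = FALSE], 2, sd),
                apply(tabs[[b]]$values[, nd, drop = FALSE], 2, sd))
    expect_true(all(shift < 2 * sdm))
  }
})

test_that("the packaged fixture has the designed composition", {
  pool <- fixture_pool()
  specs <- pool$specs
  expect_equal(ncol(pool$PRE$values), 350L)
  expect_equal(as.integer(table(specs$class)[c("informative_primer",
                                               "informative_template")]),
               c(35L, 34L))
  expect_equal(sum(specs$class == "redundant_duplicate"), 81L)
  expect_equal(sum(specs$class == "low_presence"), 100L)
  expect_equal(sum(specs$class == "non_discriminative"), 100L)
  # every duplicate shares its residue-base-pair group with an informative
  inf_groups <- with(specs[grepl("informative", specs$class), ],
                     paste(residue_label, base_pair_label))
  dup_groups <- with(specs[specs$class == "redundant_duplicate", ],
                     paste(residue_label, base_pair_label))
  expect_true(all(dup_groups %in% inf_groups))
  # exactly one informative descriptor per group
  expect_false(any(duplicated(inf_groups)))
  expect_equal(nrow(pool$PRE$values), 5000L)
  expect_identical(unique(pool$PRE$labels), "PRE")
})
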