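one_kernel_bias <- function(cfg, center = 0.4, sigma = 0.1, height = 1) {
  opes_bias(cfg, list(center = matrix(center, 1, cfg$ncv),
                      sigma = matrix(sigma, 1, cfg$ncv),
                      height = height))
}

test_that("an empty kernel list evaluates to zero bias", {
  b <- opes_bias(opes_config(ncv = 1))
  out <- evaluate_bias(b, c(-1, 0, 1))
  expect_equal(out$energy, rep(0, 3))
  expect_equal(as.numeric(out$gradient), rep(0, 3))
})

test_that("a degenerate biasfactor (gamma = 1) gives identically zero bias", {
  for (v in c("standard", "explore")) {
    cfg <- opes_config(ncv = 1, gamma = 1, variant = v)
    b <- one_kernel_bias(cfg)
    expect_equal(evaluate_bias(b, seq(-1, 1, 0.2))$energy, rep(0, 11))
  }
})

test_that("a single Gaussian kernel reproduces the closed-form bias", {
  cfg <- opes_config(ncv = 1, barrier = 20, variant = "standard",
                     epsilon = 0)
  b <- one_kernel_bias(cfg, center = 0.4, sigma = 0.1)
  pref <- (1 - 1 / cfg$gamma) / cfg$beta
  v0 <- evaluate_bias(b, 0.4)$energy
  v1 <- evaluate_bias(b, 0.5)$energy
  # with the max normalization, V(s) = pref * (-d^2/2) in bandwidth units
  expect_equal(v0, 0, tolerance = 1e-8)
  expect_equal(v0 - v1, pref * 0.5, tolerance = 1e-8)
  # gradient consistent with central differences
  g <- evaluate_bias(b, 0.47)$gradient
  h <- 1e-6
  num <- (evaluate_bias(b, 0.47 + h)$energy -
          evaluate_bias(b, 0.47 - h)$energy) / (2 * h)
  expect_equal(as.numeric(g), num, tolerance = 1e-4)
})

test_that("repeated updates fill a basin monotonically and respect the cap", {
  # explore variant: unit deposit weights, so filling tracks visit counts
  cfg <- opes_config(ncv = 1, barrier = 10, variant = "explore",
                     sigma0 = 0.1)
  b <- opes_bias(cfg)
  set.seed(2)
  # fill basin A at 0: an unvisited point then sits a full BARRIER below
  for (k in 1:10) b <- update_bias(b, rnorm(25, 0, 0.1))
  vB0 <- diff(evaluate_bias(b, c(0, 2))$energy)
  expect_lt(vB0, -(cfg$barrier - 1))
  # deposits in basin B at 2 raise its bias monotonically toward A level
  vB <- numeric(15)
  for (k in 1:15) {
    b <- update_bias(b, rnorm(25, 2, 0.1))
    vB[k] <- diff(evaluate_bias(b, c(0, 2))$energy)
  }
  expect_true(all(diff(vB) > -1e-6))
  expect_gt(mean(tail(vB, 3)), vB0 + cfg$barrier / 2)
  # range capped by BARRIER plus the normalization constant pref*log(1+eps)
  grid <- seq(-1, 3, 0.05)
  v <- evaluate_bias(b, grid)$energy
  cap_range <- cfg$barrier +
    (cfg$gamma - 1) / cfg$beta * log1p(cfg$epsilon)
  expect_lte(max(v) - min(v), cap_range + 0.5)
})

test_that("kernels closer than the merge threshold are compressed", {
  cfg <- opes_config(ncv = 1, sigma0 = 0.1, variant = "explore")
  b <- update_bias(opes_bias(cfg), 0)
  expect_equal(length(b$kernels$height), 1L)
  b <- update_bias(b, 0.05)           # within one bandwidth: merged
  expect_equal(length(b$kernels$height), 1L)
  b <- update_bias(b, 1.0)            # far away: new kernel
  expect_equal(length(b$kernels$height), 2L)
})

test_that("an OPES bias round-trips through serialization unchanged", {
  cfg <- opes_config(ncv = 2, barrier = 20, stride = 500, sigma0 = 0.1)
  b <- update_bias(opes_bias(cfg), matrix(c(0, 0, 1, 1, 3, -3), ncol = 2,
                                          byrow = TRUE))
  path <- withr::local_tempfile(fileext = ".json")
  save_opes_bias(b, path)
  b2 <- load_opes_bias(path)
  expect_equal(b2$config$barrier, 20)
  expect_equal(b2$config$stride, 500L)
  expect_equal(b2$config$sigma0, b$config$sigma0)
  expect_equal(b2$kernels$center, b$kernels$center)
  s <- matrix(c(0.3, -0.2, 2, 2), 2, byrow = TRUE)
  expect_equal(evaluate_bias(b2, s)$energy, evaluate_bias(b, s)$energy)
})

test_that("walls are zero inside, follow k (s - limit)^e outside, continuously", {
  w <- wall_spec(-1.5, 1.5, 40000)
  expect_equal(wall_energy(w, 0)$energy, 0)
  expect_equal(wall_energy(w, 1.49)$energy, 0)
  expect_equal(wall_energy(w, 1.6)$energy, 40000 * 0.1^2)
  expect_equal(wall_energy(w, -1.7)$energy, 40000 * 0.2^2)
  # continuity approaching the limit from outside
  expect_lt(wall_energy(w, 1.5 + 1e-9)$energy, 1e-10)
  g <- wall_energy(w, 1.6)$gradient
  h <- 1e-7
  num <- (wall_energy(w, 1.6 + h)$energy - wall_energy(w, 1.6 - h)$energy) /
    (2 * h)
  expect_equal(as.numeric(g), num, tolerance = 1e-4)
  expect_error(wall_spec(2, 1), "lower < upper")
})

test_that("a null bias (gamma = 1) run matches unbiased sampling", {
  sys <- shallow_system()
  ref <- state_reference(sys$centers, 0.3)
  cv <- latent_cv()
  cfg <- opes_config(ncv = 2, gamma = 1, barrier = 20, stride = 500,
                     sigma0 = 0.1, kT = sys$kT, variant = "standard")
  biased <- run_opes(sys, cv, cfg, NULL, n_steps = 6e5, seed = 31)
  plain <- simulate_surrogate(sys, 6e5, seed = 32)
  # thin well past the basin-hopping time so frames are independent
  thin <- function(tr) {
    labs <- assign_states(tr, ref)
    labs[seq(1, length(labs), by = 400)]
  }
  t1 <- table(factor(thin(biased), levels = rownames(sys$centers)))
  t2 <- table(factor(thin(plain), levels = rownames(sys$centers)))
  expect_gt(suppressWarnings(chisq.test(rbind(t1, t2)))$p.value, 0.01)
})

test_that("reweighting is uniform under zero bias, normalized and positive", {
  tr <- simulate_surrogate(shallow_system(), 5000, seed = 3,
                           cv_model = latent_cv())
  tr$cv <- tr$latent
  b <- opes_bias(opes_config(ncv = 2))
  w <- reweight(tr, b)
  expect_equal(w, rep(1 / length(w), length(w)))
  w2 <- opes2d_run()$weights
  expect_true(all(w2 > 0))
  expect_equal(sum(w2), 1)
})

test_that("static-bias reweighting recovers the double-well Boltzmann ratio", {
  kT <- 0.616; h <- 1.2; tilt <- 0.5
  xg <- seq(-2.5, 2.5, 0.01)
  U <- h * (xg^2 - 1)^2 + tilt * xg
  # a static bias filling the deeper (left) well
  Vb <- 1.6 * exp(-(xg + 1)^2 / (2 * 0.35^2))
  set.seed(6)
  r <- opescv:::cpp_sim1d(1L, c(h, tilt), -1, 4e6, 5e-4, kT, 20L, xg, Vb)
  vb_at <- approx(xg, Vb, r$x, rule = 2)$y
  w <- exp((vb_at - max(vb_at)) / kT)
  w <- w / sum(w)
  frac <- sum(w[r$x < 0])
  p <- exp(-U / kT)
  frac_true <- sum(p[xg < 0]) / sum(p)
  blocks <- ceiling(seq_along(r$x) / (length(r$x) / 20))
  bf <- vapply(1:20, function(b) {
    wb <- w[blocks == b]
    sum(wb[r$x[blocks == b] < 0]) / sum(wb)
  }, numeric(1))
  se <- sd(bf) / sqrt(20)
  expect_lt(abs(frac - frac_true), 3 * max(se, 1e-3))
})

test_that("biased runs are reproducible and respect the bias cap", {
  sys <- shallow_system()
  cfg <- opes_config(ncv = 2, barrier = 5, stride = 200, sigma0 = 0.1,
                     kT = sys$kT, variant = "standard")
  r1 <- run_opes(sys, latent_cv(), cfg, NULL, n_steps = 1e5, seed = 8)
  r2 <- run_opes(sys, latent_cv(), cfg, NULL, n_steps = 1e5, seed = 8)
  expect_identical(r1$latent, r2$latent)
  expect_identical(r1$kernels, r2$kernels)
  expect_lte(r1$diagnostics$max_bias - r1$diagnostics$min_bias,
             (1 - 1 / cfg$gamma) * cfg$barrier + 1.0)
})

test_that("dimensionality and finiteness contracts are enforced", {
  sys <- default_system()
  cfg1 <- opes_config(ncv = 1)
  expect_error(run_opes(sys, latent_cv(), cfg1, NULL, 100, seed = 1),
               "dimensionality")
  b <- opes_bias(opes_config(ncv = 1))
  expect_error(update_bias(b, c(0.1, NaN)), "non-finite")
  expect_error(run_opes(sys, multitask_model(),
                        opes_config(ncv = 2),
                        wall_spec(-1.5, 1.5), 100, seed = 1),
               "wall_spec")
})
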