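test_that("fisher_ratio matches its closed-form definition", {
  # identical class distributions: between-scatter vanishes
  expect_equal(fisher_ratio(c(1, 2, 3, 1, 2, 3),
                            rep(c("A", "B"), each = 3)), 0)
  # class means +/-2 with unit population variance -> between 4, within 1
  p <- c(1, 3, -1, -3)
  l <- c("A", "A", "B", "B")
  expect_equal(fisher_ratio(p, l), 4.0)
  # scale invariance
  expect_equal(fisher_ratio(10 * p, l), fisher_ratio(p, l))
  expect_error(fisher_ratio(c(1, 2), c("A", "A")), "two label classes")
  expect_error(fisher_ratio(c(1, 2, 3), c("A", "A", "B", "B")), "input")
})

test_that("a single linear layer recovers the closed-form LDA direction", {
  set.seed(21)
  p <- 5L; n <- 2000L
  mu1 <- c(2, 0, 1, -1, 0.5)
  A <- matrix(rnorm(p * p, sd = 0.3), p) + diag(p)
  Sigma <- crossprod(A)
  X1 <- matrix(rnorm(n * p), n) %*% chol(Sigma)
  X2 <- sweep(matrix(rnorm(n * p), n) %*% chol(Sigma), 2, mu1, "+")
  X <- rbind(X1, X2)
  lab <- rep(c("PRE", "POST"), each = n)
  # near-zero within-scatter ridge so the closed form is the exact target
  m <- train_deep_lda(X, labels = lab, hidden = 5L, epochs = 50,
                      sw_reg = 1e-4, seed = 1)
  # pull the learned discriminant back to input space (linear network)
  w_in <- drop(m$net$W[[1]] %*% m$w) / m$sd
  Z1 <- X[lab == "PRE", ]; Z2 <- X[lab == "POST", ]
  Sw <- (cov(Z1) + cov(Z2)) / 2
  w_ref <- solve(Sw, colMeans(Z1) - colMeans(Z2))
  cosine <- sum(w_in * w_ref) / sqrt(sum(w_in^2) * sum(w_ref^2))
  expect_gt(abs(cosine), 0.99)
})

test_that("shuffled labels destroy the separation", {
  set.seed(8)
  X <- matrix(rnorm(1000 * 10), 1000)
  lab <- sample(rep(c("PRE", "POST"), each = 500))
  m <- train_deep_lda(X, labels = lab, hidden = c(8, 5), epochs = 100,
                      seed = 2)
  expect_lt(m$fisher, 0.1)
})

test_that("training maps the states to +1 and -1 and separates them", {
  m <- lda_model()
  tab <- lda_table()
  cv <- predict(m, tab)
  expect_lt(abs(mean(cv[tab$labels == "PRE"]) - 1), 0.25)
  expect_lt(abs(mean(cv[tab$labels == "POST"]) + 1), 0.25)
  # histogram overlap coefficient below 5%
  br <- seq(min(cv) - 0.01, max(cv) + 0.01, length.out = 80)
  h1 <- hist(cv[tab$labels == "PRE"], breaks = br, plot = FALSE)$density
  h2 <- hist(cv[tab$labels == "POST"], breaks = br, plot = FALSE)$density
  ov <- sum(pmin(h1, h2)) * diff(br[1:2])
  expect_lt(ov, 0.05)
  # loss (negative Fisher ratio) decreases under epoch-window smoothing
  lh <- m$loss_history
  k <- length(lh) %/% 5
  expect_lt(mean(tail(lh, k)), mean(head(lh, k)))
})

test_that("the CV is bounded on arbitrary probes by the saturation scale", {
  m <- lda_model()
  set.seed(77)
  probes <- matrix(rnorm(200 * length(m$mu), sd = 500), 200)
  probes <- sweep(sweep(probes, 2, m$sd, "*"), 2, m$mu, "+")
  cv <- predict(m, probes)
  expect_true(all(abs(cv) <= m$lorentzian * pi / 2))
})

test_that("training is reproducible under a fixed seed", {
  tab <- lda_table()
  small <- function() train_deep_lda(
    descriptor_table(tab$values[c(1:300, 5001:5300), ],
                     tab$meta, tab$labels[c(1:300, 5001:5300)]),
    hidden = c(10, 5), epochs = 30, seed = 9)
  m1 <- small(); m2 <- small()
  expect_identical(m1$net$W, m2$net$W)
  expect_identical(m1$w, m2$w)
})

test_that("evaluation is deterministic, batchable and standardization-aware", {
  m <- lda_model()
  tab <- lda_table()
  X <- tab$values[1:7, ]
  batch <- predict(m, X)
  single <- vapply(1:7, function(i) predict(m, X[i, , drop = FALSE]),
                   numeric(1))
  expect_equal(batch, single)
  expect_identical(predict(m, X[3, , drop = FALSE]),
                   predict(m, X[3, , drop = FALSE]))
  # the training-mean vector standardizes to zero: CV equals the network's
  # response to the zero input
  at_mu <- predict(m, matrix(m$mu, nrow = 1))
  H <- opescv:::nn_forward(m$net, matrix(0, 1, length(m$mu)))$H
  u0 <- drop(H[[length(H)]] %*% m$w)
  uhat <- m$affine[1] * u0 + m$affine[2]
  expect_equal(at_mu, m$lorentzian * atan(uhat / m$lorentzian))
  expect_error(predict(m, X[, 1:10]), "schema error")
})

test_that("degenerate training inputs raise input errors", {
  tab <- lda_table()
  expect_error(
    train_deep_lda(descriptor_table(tab$values[c(1:50, 5001:5050), ],
                                    tab$meta,
                                    tab$labels[c(1:50, 5001:5050)]),
                   epochs = 2),
    "100 frames")
  expect_error(train_deep_lda(tab$values, labels = NULL), "labels")
})
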