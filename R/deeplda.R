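#' Fisher's discriminant ratio of 1-D projections
#'
#' Ratio of the between-class scatter (variance of the two class means about
#' their midpoint) to the within-class scatter (mean of the per-class
#' population variances). Scale invariant; 0 when the class means coincide.
#'
#' @param projections numeric vector of projected values.
#' @param labels two-class factor/character vector aligned with
#'   \code{projections}.
#' @return nonnegative scalar.
#' @export
fisher_ratio <- function(projections, labels) {
  if (length(projections) != length(labels))
    stop("input error: projections and labels differ in length",
         call. = FALSE)
  cls <- unique(labels)
  if (length(cls) != 2L)
    stop("input error: exactly two label classes required", call. = FALSE)
  p1 <- projections[labels == cls[1L]]
  p2 <- projections[labels == cls[2L]]
  if (length(p1) == 0L || length(p2) == 0L)
    stop("input error: a class is empty", call. = FALSE)
  m1 <- mean(p1); m2 <- mean(p2)
  mbar <- (m1 + m2) / 2
  between <- ((m1 - mbar)^2 + (m2 - mbar)^2) / 2
  pop_var <- function(p) mean((p - mean(p))^2)
  within <- (pop_var(p1) + pop_var(p2)) / 2
  if (within == 0) {
    if (between == 0) return(0)
    return(Inf)
  }
  between / within
}

# scatter matrices of the last hidden layer H for the two-class objective:
# Sb = (1/4) dmu dmu', Sw = mean of per-class population covariances
lda_scatters <- function(H, idx1, idx2) {
  mu1 <- colMeans(H[idx1, , drop = FALSE])
  mu2 <- colMeans(H[idx2, , drop = FALSE])
  dmu <- mu1 - mu2
  C1 <- crossprod(sweep(H[idx1, , drop = FALSE], 2, mu1)) / length(idx1)
  C2 <- crossprod(sweep(H[idx2, , drop = FALSE], 2, mu2)) / length(idx2)
  list(Sb = tcrossprod(dmu) / 4, Sw = (C1 + C2) / 2,
       mu1 = mu1, mu2 = mu2, dmu = dmu)
}

# leading generalized eigenpair of (Sw + reg I)^-1 Sb, with w normalized so
# that w' (Sw + reg I) w = 1
lda_direction <- function(Sb, Sw, reg) {
  Swr <- Sw + diag(reg, nrow(Sw))
  e <- eigen(solve(Swr, Sb))
  k <- which.max(Re(e$values))
  w <- Re(e$vectors[, k])
  w <- w / sqrt(drop(t(w) %*% Swr %*% w))
  list(w = w, lambda = Re(e$values[k]))
}

#' Train the Deep-LDA collective variable
#'
#' Optimises a feed-forward network so that the leading linear discriminant
#' of its last hidden layer maximally separates two labeled metastable
#' states (Fisher's ratio objective, with a small ridge on the within
#' scatter). The exported CV is the discriminant projection passed through a
#' bounded Lorentzian-derivative saturation \eqn{u \mapsto L\,\arctan(u/L)}
#' and an affine map that places the two training states at +1 (first state)
#' and -1 (second state).
#'
#' @param table a labeled \code{\link{descriptor_table}} (or numeric matrix
#'   if \code{labels} is given) holding the filtered descriptors.
#' @param labels per-frame state labels (defaults to the table's own).
#' @param states length-2 character: the positive and negative state.
#' @param hidden hidden-layer widths after the input layer.
#' @param epochs,learning_rate,l2 optimiser settings (Adam, full batch by
#'   default).
#' @param sw_reg ridge added to the within-class scatter.
#' @param lorentzian scale of the saturating output transform.
#' @param batch_size optional mini-batch size (default: full batch).
#' @param seed integer seed (initialisation and shuffling).
#' @return an object of class \code{deep_lda_cv}.
#' @export
train_deep_lda <- function(table, labels = NULL, states = c("PRE", "POST"),
                           hidden = c(30, 20, 15, 10, 5),
                           epochs = 500L, learning_rate = 5e-4, l2 = 1e-4,
                           sw_reg = 0.05, lorentzian = 40,
                           batch_size = NULL, seed = 1L) {
  dat <- resolve_table(table, labels)
  X <- dat$X
  labels <- dat$labels
  stopifnot(all(states %in% labels))
  keep <- labels %in% states
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  if (min(table(labels)) < 100L)
    stop("input error: need at least 100 frames per state", call. = FALSE)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  idx1 <- which(labels == states[1L])
  idx2 <- which(labels == states[2L])
  set.seed(seed)
  net <- nn_init(c(ncol(Z), hidden), act = "relu")
  opt <- adam_init(net)
  n <- nrow(Z)
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    batches <- if (is.null(batch_size)) list(seq_len(n)) else {
      split(sample.int(n), ceiling(seq_len(n) / batch_size))
    }
    ep_loss <- 0
    for (bi in batches) {
      b1 <- intersect(bi, idx1)
      b2 <- intersect(bi, idx2)
      if (length(b1) < 2L || length(b2) < 2L) next
      cache <- nn_forward(net, Z[bi, , drop = FALSE])
      H <- cache$H[[length(cache$H)]]
      i1 <- match(b1, bi); i2 <- match(b2, bi)
      sc <- lda_scatters(H, i1, i2)
      dir <- lda_direction(sc$Sb, sc$Sw, sw_reg)
      w <- dir$w
      lam <- dir$lambda
      if (!is.finite(lam))
        stop("training diverged at epoch ", ep, call. = FALSE)
      # d lambda / d h_i for the generalized eigenvalue at fixed w
      proj <- drop(H %*% w)
      wdmu <- sum(w * sc$dmu)
      G <- matrix(0, nrow(H), ncol(H))
      G[i1, ] <- outer(rep(wdmu / (2 * length(i1)), length(i1)), w) -
        lam * outer((proj[i1] - mean(proj[i1])) / length(i1), w)
      G[i2, ] <- outer(rep(-wdmu / (2 * length(i2)), length(i2)), w) -
        lam * outer((proj[i2] - mean(proj[i2])) / length(i2), w)
      grads <- nn_backward(net, cache, -G)  # minimize -lambda
      upd <- adam_step(net, opt, grads, lr = learning_rate, l2 = l2)
      net <- upd$net
      opt <- upd$state
      ep_loss <- ep_loss - lam
    }
    loss_hist[ep] <- ep_loss / length(batches)
    if (!is.finite(loss_hist[ep]))
      stop("training diverged at epoch ", ep, call. = FALSE)
  }
  # final discriminant on the full training set
  cache <- nn_forward(net, Z)
  H <- cache$H[[length(cache$H)]]
  sc <- lda_scatters(H, idx1, idx2)
  dir <- lda_direction(sc$Sb, sc$Sw, sw_reg)
  w <- dir$w
  if (sum(w * sc$mu1) < sum(w * sc$mu2)) w <- -w  # sign: first state positive
  # normalize the projection so the state means sit at +1/-1, then bound it
  # with the Lorentzian-derivative saturation (active only far outside the
  # trained range, |u_hat| >> lorentzian)
  u <- drop(H %*% w)
  u1 <- mean(u[idx1]); u2 <- mean(u[idx2])
  a <- 2 / (u1 - u2)
  b <- 1 - a * u1
  affine <- c(a, b)
  meta <- if (inherits(table, "descriptor_table")) table$meta else NULL
  structure(list(net = net, w = w, lorentzian = lorentzian,
                 affine = affine, mu = mu, sd = sdv,
                 states = states, meta = meta,
                 fisher = dir$lambda, loss_history = loss_hist,
                 config = list(hidden = hidden, epochs = epochs,
                               learning_rate = learning_rate, l2 = l2,
                               sw_reg = sw_reg, lorentzian = lorentzian,
                               seed = seed)),
            class = "deep_lda_cv")
}

resolve_table <- function(table, labels) {
  if (inherits(table, "descriptor_table")) {
    if (is.null(labels)) labels <- table$labels
    X <- table$values
  } else {
    X <- as.matrix(table)
  }
  if (is.null(labels)) stop("input error: frame labels required", call. = FALSE)
  list(X = X, labels = labels)
}

#' Evaluate a trained CV on descriptor data
#'
#' @param object a \code{deep_lda_cv} or \code{multitask_cv}.
#' @param newdata numeric matrix (frames x descriptors) or
#'   \code{descriptor_table} with matching inventory.
#' @param ... unused.
#' @return numeric vector (Deep-LDA) or matrix (multitask latent space).
#' @export
predict.deep_lda_cv <- function(object, newdata, ...) {
  Z <- standardize_for(object, newdata)
  H <- nn_forward(object$net, Z)$H
  u <- drop(H[[length(H)]] %*% object$w)
  uhat <- object$affine[1] * u + object$affine[2]
  object$lorentzian * atan(uhat / object$lorentzian)
}

standardize_for <- function(object, newdata) {
  X <- if (inherits(newdata, "descriptor_table")) newdata$values else
    as.matrix(newdata)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(object$mu))
    stop("schema error: expected ", length(object$mu),
         " descriptors, got ", ncol(X), call. = FALSE)
  sweep(sweep(X, 2, object$mu), 2, object$sd, "/")
}

#' @rdname predict.deep_lda_cv
#' @param model a trained CV model.
#' @param data descriptor data.
#' @export
evaluate_cv <- function(model, data) predict(model, data)

#' @export
print.deep_lda_cv <- function(x, ...) {
  cat("Deep-LDA collective variable\n")
  cat("  architecture: [", paste(x$net$widths, collapse = ", "),
      "], ReLU, discriminant on the last hidden layer\n", sep = "")
  cat("  states:", x$states[1], "-> +1,", x$states[2], "-> -1\n")
  cat("  final Fisher ratio:", format(x$fisher, digits = 4), "\n")
  invisible(x)
}
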