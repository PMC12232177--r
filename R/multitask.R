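#' Default Gaussian targets for the multitask CV
#'
#' Target centers and widths of the per-state Gaussians in the 2-D latent
#' CV space, in the fixed state order PRE, INT2, INT1, POST:
#' centers (-6,-6), (-3,3), (3,-3), (6,6) and width 0.2 per component.
#'
#' @return list with \code{mu} (4 x 2 matrix, rownames the states) and
#'   \code{sigma} (4 x 2 matrix).
#' @export
tda_targets <- function() {
  mu <- matrix(c(-6, -6, -3, 3, 3, -3, 6, 6), 4, 2, byrow = TRUE,
               dimnames = list(c("PRE", "INT2", "INT1", "POST"),
                               c("cv1", "cv2")))
  sigma <- matrix(0.2, 4, 2, dimnames = dimnames(mu))
  list(mu = mu, sigma = sigma)
}

#' Mean squared reconstruction loss
#'
#' @param batch numeric matrix in standardized descriptor space, or a
#'   \code{descriptor_table}/matrix in raw units (standardized internally
#'   when \code{model} is given with \code{raw = TRUE}).
#' @param model a \code{multitask_cv}.
#' @param raw standardize \code{batch} with the model statistics first.
#' @return mean over frames and dimensions of the squared reconstruction
#'   error (nonnegative scalar).
#' @export
reconstruction_loss <- function(batch, model, raw = TRUE) {
  Z <- if (raw) standardize_for(model, batch) else as.matrix(batch)
  if (nrow(Z) == 0L) stop("input error: empty batch", call. = FALSE)
  lat <- nn_forward(model$encoder, Z)$H
  lat <- lat[[length(lat)]]
  rec <- nn_forward(model$decoder, lat)$H
  rec <- rec[[length(rec)]]
  mean((rec - Z)^2)
}

#' Targeted-discriminant (TDA) loss on latent coordinates
#'
#' Sum over states and latent components of weighted squared deviations of
#' the per-state batch mean from the target center and of the per-state
#' batch (population) SD from the target width:
#' \deqn{L = \sum_s \sum_k \alpha (\mu_{sk} - \mu^{tg}_{sk})^2 +
#'   \beta (\sigma_{sk} - \sigma^{tg}_{sk})^2.}
#'
#' @param latent n x d matrix of latent CV values.
#' @param labels per-frame state labels; every state in \code{rownames(mu_tg)}
#'   present in \code{labels} needs >= 2 frames.
#' @param mu_tg,sigma_tg target center/width matrices (states x components).
#' @param alpha,beta mean- and sigma-term weights.
#' @return nonnegative scalar; zero iff all targets are met exactly.
#' @export
tda_loss <- function(latent, labels, mu_tg = tda_targets()$mu,
                     sigma_tg = tda_targets()$sigma, alpha = 1, beta = 1) {
  latent <- as.matrix(latent)
  states <- intersect(rownames(mu_tg), unique(labels))
  loss <- 0
  for (s in states) {
    zs <- latent[labels == s, , drop = FALSE]
    if (nrow(zs) < 2L)
      stop("batch-composition error: state ", s, " has fewer than 2 frames",
           call. = FALSE)
    m <- colMeans(zs)
    sg <- sqrt(colMeans(sweep(zs, 2, m)^2))
    loss <- loss + sum(alpha * (m - mu_tg[s, ])^2 +
                       beta * (sg - sigma_tg[s, ])^2)
  }
  loss
}

#' Train the 2-D multitask collective variable
#'
#' Jointly optimises an autoencoder on unlabeled "reactive" descriptor data
#' (reconstruction task) and the Gaussian-target discriminant loss on
#' labeled four-state data acting on the 2-D latent bottleneck, so that the
#' latent space both resolves the transition pathways and pins each
#' metastable state near its target center. Each optimisation step draws a
#' stratified labeled sub-batch (equal frames per state) for the TDA term
#' and an independent unlabeled sub-batch for the reconstruction term.
#'
#' @param labeled a labeled \code{\link{descriptor_table}} (or matrix with
#'   \code{labels}) covering the four states.
#' @param reactive optional unlabeled \code{descriptor_table}/matrix; when
#'   NULL the reconstruction task trains on the labeled frames.
#' @param labels labels for \code{labeled} if it is a bare matrix.
#' @param encoder_hidden encoder widths after the input layer (the last
#'   entry, 2, is the CV dimensionality); the decoder mirrors them.
#' @param epochs,learning_rate Adam settings.
#' @param steps_per_epoch stratified mini-batch steps per epoch.
#' @param batch_per_state labeled frames per state per step.
#' @param batch_reactive unlabeled frames per step.
#' @param mu_tg,sigma_tg Gaussian targets (see \code{\link{tda_targets}}).
#' @param w_rec,w_tda relative weights of the two losses.
#' @param alpha,beta mean/sigma weights inside the TDA loss.
#' @param seed integer seed.
#' @return an object of class \code{multitask_cv}.
#' @export
train_multitask <- function(labeled, reactive = NULL, labels = NULL,
                            encoder_hidden = c(50, 30, 15, 5, 2),
                            epochs = 500L, learning_rate = 1e-3,
                            steps_per_epoch = 5L, batch_per_state = 250L,
                            batch_reactive = 1000L,
                            mu_tg = tda_targets()$mu,
                            sigma_tg = tda_targets()$sigma,
                            w_rec = 1, w_tda = 1, alpha = 1, beta = 1,
                            seed = 1L) {
  dat <- resolve_table(labeled, labels)
  X <- dat$X
  labels <- dat$labels
  states <- rownames(mu_tg)
  missing <- setdiff(states, unique(labels))
  if (length(missing))
    stop("input error: missing state label(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  R <- if (is.null(reactive)) X else {
    if (inherits(reactive, "descriptor_table")) reactive$values else
      as.matrix(reactive)
  }
  mu <- colMeans(rbind(X, R))
  sdv <- apply(rbind(X, R), 2, sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  ZR <- sweep(sweep(R, 2, mu), 2, sdv, "/")
  set.seed(seed)
  p <- ncol(Z)
  enc <- nn_init(c(p, encoder_hidden), act = "ssp")
  dec <- nn_init(c(rev(encoder_hidden), p), act = "ssp")
  oe <- adam_init(enc)
  od <- adam_init(dec)
  sidx <- lapply(states, function(s) which(labels == s))
  names(sidx) <- states
  d_lat <- encoder_hidden[length(encoder_hidden)]
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ep_loss <- 0
    for (it in seq_len(steps_per_epoch)) {
      bl <- unlist(lapply(sidx, function(ix)
        ix[sample.int(length(ix), min(batch_per_state, length(ix)))]))
      blab <- labels[bl]
      br <- sample.int(nrow(ZR), min(batch_reactive, nrow(ZR)))
      # --- TDA task on the labeled batch (encoder only)
      ce <- nn_forward(enc, Z[bl, , drop = FALSE])
      lat <- ce$H[[length(ce$H)]]
      Gtda <- matrix(0, nrow(lat), d_lat)
      ltda <- 0
      for (s in states) {
        ii <- which(blab == s)
        zs <- lat[ii, , drop = FALSE]
        m <- colMeans(zs)
        dev <- sweep(zs, 2, m)
        sg <- sqrt(colMeans(dev^2))
        ltda <- ltda + sum(alpha * (m - mu_tg[s, ])^2 +
                           beta * (sg - sigma_tg[s, ])^2)
        gm <- 2 * alpha * (m - mu_tg[s, ]) / length(ii)
        gs <- 2 * beta * (sg - sigma_tg[s, ]) / pmax(sg, 1e-12)
        Gtda[ii, ] <- matrix(gm, length(ii), d_lat, byrow = TRUE) +
          sweep(dev, 2, gs / length(ii), "*")
      }
      ge_tda <- nn_backward(enc, ce, w_tda * Gtda)
      # --- reconstruction task on the unlabeled batch (encoder + decoder)
      cr <- nn_forward(enc, ZR[br, , drop = FALSE])
      latr <- cr$H[[length(cr$H)]]
      cd <- nn_forward(dec, latr)
      rec <- cd$H[[length(cd$H)]]
      err <- rec - ZR[br, , drop = FALSE]
      lrec <- mean(err^2)
      Grec <- 2 * err / length(err)
      gd <- nn_backward(dec, cd, w_rec * Grec, input_grad = TRUE)
      ge_rec <- nn_backward(enc, cr, gd$gX)
      ge <- list(gW = Map(`+`, ge_tda$gW, ge_rec$gW),
                 gb = Map(`+`, ge_tda$gb, ge_rec$gb))
      ue <- adam_step(enc, oe, ge, lr = learning_rate)
      enc <- ue$net; oe <- ue$state
      ud <- adam_step(dec, od, gd, lr = learning_rate)
      dec <- ud$net; od <- ud$state
      total <- w_tda * ltda + w_rec * lrec
      if (!is.finite(total))
        stop("training diverged at epoch ", ep, call. = FALSE)
      ep_loss <- ep_loss + total
    }
    loss_hist[ep] <- ep_loss / steps_per_epoch
  }
  model <- structure(list(
    encoder = enc, decoder = dec, mu = mu, sd = sdv,
    mu_tg = mu_tg, sigma_tg = sigma_tg, states = states,
    meta = if (inherits(labeled, "descriptor_table")) labeled$meta else NULL,
    loss_history = loss_hist,
    config = list(encoder_hidden = encoder_hidden, epochs = epochs,
                  learning_rate = learning_rate,
                  steps_per_epoch = steps_per_epoch,
                  batch_per_state = batch_per_state,
                  batch_reactive = batch_reactive,
                  w_rec = w_rec, w_tda = w_tda, alpha = alpha, beta = beta,
                  seed = seed)),
    class = "multitask_cv")
  lat <- predict(model, X)
  model$state_centers <- t(vapply(states, function(s)
    colMeans(lat[labels == s, , drop = FALSE]), numeric(d_lat)))
  colnames(model$state_centers) <- colnames(mu_tg)
  model
}

#' @rdname predict.deep_lda_cv
#' @param what for \code{multitask_cv}: return the latent CV coordinates or
#'   the decoder reconstruction (standardized descriptor space).
#' @export
predict.multitask_cv <- function(object, newdata,
                                 what = c("latent", "reconstruction"), ...) {
  what <- match.arg(what)
  Z <- standardize_for(object, newdata)
  lat <- nn_forward(object$encoder, Z)$H
  lat <- lat[[length(lat)]]
  colnames(lat) <- colnames(object$mu_tg)
  if (what == "latent") return(lat)
  rec <- nn_forward(object$decoder, lat)$H
  rec[[length(rec)]]
}

#' @export
print.multitask_cv <- function(x, ...) {
  cat("Multitask 2-D collective variable (autoencoder + Gaussian targets)\n")
  cat("  encoder: [", paste(x$encoder$widths, collapse = ", "),
      "], shifted softplus\n", sep = "")
  if (!is.null(x$state_centers)) {
    cat("  learned state centroids:\n")
    print(round(x$state_centers, 2))
  }
  invisible(x)
}
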