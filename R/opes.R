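#' OPES configuration
#'
#' Parameters of the on-the-fly probability enhanced sampling bias
#' \deqn{V(s) = \frac{1}{\beta}\log\frac{p(s)}{p_{tg}(s)}}
#' with the well-tempered target \eqn{P_{tg} \propto P^{1/\gamma}}. The
#' kernel density p(s) is built from deposited Gaussian kernels whose
#' bandwidth shrinks with the effective sample size; near-duplicate kernels
#' are merged. Two variants are supported: \code{"explore"} (kernels weight
#' the sampled distribution directly; suited to exploration) and
#' \code{"standard"} (kernels carry unbiasing weights \eqn{e^{\beta V}}).
#'
#' @param ncv CV dimensionality (1 or 2).
#' @param barrier BARRIER parameter (kcal/mol): the largest barrier the bias
#'   is expected to overcome; caps the deposited bias.
#' @param stride deposit a kernel every this many integration steps.
#' @param sigma0 initial kernel width per CV dimension (SIGMA).
#' @param kT thermal energy (kcal/mol).
#' @param gamma biasfactor; default \eqn{\beta \cdot} \code{barrier}.
#' @param variant "explore" or "standard".
#' @param epsilon regularisation floor of the probability estimate; default
#'   \eqn{e^{-\beta B/(1-1/\gamma)}} (standard) or
#'   \eqn{e^{-\beta B/(\gamma-1)}} (explore).
#' @param merge_threshold kernel-merge distance in bandwidth units.
#' @param cutoff_sd kernels further than this many bandwidths contribute 0.
#' @param sigma_min_frac floor on the adaptive bandwidth shrinkage, as a
#'   fraction of \code{sigma0} (keeps the kernel estimate smooth on long
#'   runs).
#' @return list of class \code{opes_config}.
#' @export
opes_config <- function(ncv = 1L, barrier = 20, stride = 500L, sigma0 = 0.1,
                        kT = 0.616, gamma = NULL,
                        variant = c("explore", "standard"),
                        epsilon = NULL, merge_threshold = 1,
                        cutoff_sd = 6, sigma_min_frac = 0.2) {
  variant <- match.arg(variant)
  beta <- 1 / kT
  if (is.null(gamma)) gamma <- beta * barrier
  if (gamma < 1) stop("biasfactor gamma must be >= 1", call. = FALSE)
  if (is.null(epsilon)) {
    epsilon <- if (gamma == 1) 1 else if (variant == "explore")
      exp(-beta * barrier / (gamma - 1)) else
      exp(-beta * barrier / (1 - 1 / gamma))
  }
  sigma0 <- rep_len(sigma0, ncv)
  structure(list(ncv = as.integer(ncv), barrier = barrier,
                 stride = as.integer(stride), sigma0 = sigma0, kT = kT,
                 beta = beta, gamma = gamma, variant = variant,
                 epsilon = epsilon, merge_threshold = merge_threshold,
                 cutoff_sd = cutoff_sd, sigma_min_frac = sigma_min_frac),
            class = "opes_config")
}

#' Create an (initially empty) OPES bias
#'
#' @param config an \code{\link{opes_config}}.
#' @param kernels optional kernel list (\code{center}, \code{sigma} matrices
#'   and \code{height} vector) to start from.
#' @return object of class \code{opes_bias}; with no kernels it evaluates
#'   to zero everywhere.
#' @export
opes_bias <- function(config, kernels = NULL) {
  stopifnot(inherits(config, "opes_config"))
  structure(list(config = config, kernels = kernels), class = "opes_bias")
}

opes_cpp_pars <- function(bias) {
  cfg <- bias$config
  list(ncv = cfg$ncv, variant = if (cfg$variant == "explore") 1L else 0L,
       beta = cfg$beta, gamma = cfg$gamma, barrier = cfg$barrier,
       epsilon = cfg$epsilon, merge_threshold = cfg$merge_threshold,
       cutoff_sd = cfg$cutoff_sd, sigma_min_frac = cfg$sigma_min_frac,
       sigma0 = cfg$sigma0, kernels = bias$kernels)
}

#' Evaluate an OPES bias
#'
#' @param bias an \code{opes_bias}.
#' @param s numeric vector (one point) or matrix of CV values.
#' @return list with \code{energy} (kcal/mol) and \code{gradient}.
#' @export
evaluate_bias <- function(bias, s) {
  stopifnot(inherits(bias, "opes_bias"))
  s <- as_cv_matrix(s, bias$config$ncv)
  out <- cpp_eval_bias(opes_cpp_pars(bias), s)
  if (nrow(s) == 1L) {
    out$energy <- out$energy[[1L]]
    out$gradient <- drop(out$gradient)
  }
  out
}

as_cv_matrix <- function(s, ncv) {
  if (is.null(dim(s))) {
    if (length(s) %% ncv != 0L)
      stop("CV dimensionality mismatch", call. = FALSE)
    s <- matrix(s, ncol = ncv, byrow = length(s) > ncv)
  }
  if (ncol(s) != ncv) stop("CV dimensionality mismatch", call. = FALSE)
  if (any(!is.finite(s))) stop("sampling error: non-finite CV", call. = FALSE)
  s
}

#' Deposit CV samples into an OPES bias
#'
#' Adds one kernel per supplied sample (the caller enforces the deposition
#' stride), merging kernels closer than the merge threshold.
#'
#' @param bias an \code{opes_bias}.
#' @param samples CV samples collected since the last update (vector for
#'   1-D, or matrix).
#' @return the updated \code{opes_bias}.
#' @export
update_bias <- function(bias, samples) {
  stopifnot(inherits(bias, "opes_bias"))
  s <- as_cv_matrix(samples, bias$config$ncv)
  res <- cpp_update_bias(opes_cpp_pars(bias), s)
  bias$kernels <- res$kernels
  bias
}

#' @export
print.opes_bias <- function(x, ...) {
  nk <- if (is.null(x$kernels)) 0L else length(x$kernels$height)
  cat("OPES bias (", x$config$variant, " variant): ", nk, " kernels, ",
      "BARRIER = ", x$config$barrier, " kcal/mol, gamma = ",
      format(x$config$gamma, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Save / load an OPES bias (configuration + kernels)
#'
#' Portable JSON serialisation; the BARRIER/STRIDE/SIGMA settings and the
#' full kernel list round-trip unchanged.
#'
#' @param bias an \code{opes_bias}.
#' @param path file path.
#' @export
save_opes_bias <- function(bias, path) {
  stopifnot(inherits(bias, "opes_bias"))
  payload <- pack_obj(list(config = unclass(bias$config),
                           kernels = bias$kernels))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_opes_bias
#' @export
load_opes_bias <- function(path) {
  obj <- unpack_obj(jsonlite::read_json(path, simplifyVector = FALSE))
  cfg <- obj$config
  for (f in c("sigma0")) cfg[[f]] <- unlist(cfg[[f]])
  cfg$ncv <- as.integer(cfg$ncv)
  cfg$stride <- as.integer(cfg$stride)
  class(cfg) <- "opes_config"
  kern <- obj$kernels
  if (!is.null(kern)) kern$height <- unlist(kern$height)
  opes_bias(cfg, kern)
}

#' Repulsive wall specification
#'
#' One-sided power restraints confining each CV dimension:
#' zero strictly inside \code{[lower, upper]} and
#' \eqn{k (s - \mathrm{limit})^{e}} outside.
#'
#' @param lower,upper per-dimension limits (NA disables a side).
#' @param k_lower,k_upper force constants (kcal/mol per CV unit^exponent).
#' @param exponent restraint power (default 2).
#' @return matrix of class \code{wall_spec} (one row per CV dimension).
#' @export
wall_spec <- function(lower, upper, k_lower = 40000, k_upper = k_lower,
                      exponent = 2) {
  n <- max(length(lower), length(upper))
  if (any(!is.na(lower) & !is.na(upper) & lower >= upper))
    stop("wall limits require lower < upper", call. = FALSE)
  if (any(c(k_lower, k_upper) < 0))
    stop("wall force constants must be >= 0", call. = FALSE)
  m <- cbind(lower = rep_len(lower, n), upper = rep_len(upper, n),
             k_lower = rep_len(k_lower, n), k_upper = rep_len(k_upper, n),
             exponent = rep_len(exponent, n))
  class(m) <- c("wall_spec", class(m))
  m
}

#' Wall energy and gradient
#'
#' @param spec a \code{\link{wall_spec}}.
#' @param s CV values (vector or matrix).
#' @return list with \code{energy} and \code{gradient}.
#' @export
wall_energy <- function(spec, s) {
  s <- as_cv_matrix(s, nrow(spec))
  out <- cpp_wall_energy(unclass(spec), s)
  if (nrow(s) == 1L) {
    out$energy <- out$energy[[1L]]
    out$gradient <- drop(out$gradient)
  }
  out
}

# build the C++ CV spec for a trained model (or test helper) driving the
# surrogate; requires the analytic descriptor metadata the model was
# trained with
cv_model_spec <- function(model) {
  if (inherits(model, "latent_cv")) {
    return(list(type = 0L, ncv = ncol(model$P), P = model$P))
  }
  meta <- model$meta
  if (is.null(meta) || !all(c("axis", "base", "amp", "tau") %in% names(meta)))
    stop("the CV model carries no analytic descriptor map; only models ",
         "trained on surrogate descriptor tables can drive the surrogate",
         call. = FALSE)
  desc <- cbind(meta$axis, meta$base, meta$amp, meta$tau)
  if (inherits(model, "deep_lda_cv")) {
    list(type = 1L, ncv = 1L, desc = desc, mu = model$mu, sd = model$sd,
         W = model$net$W, b = model$net$b,
         act = if (model$net$act == "relu") 1L else 2L,
         head = 1L, head_w = model$w, lorentz = model$lorentzian,
         affine_a = model$affine[1], affine_b = model$affine[2])
  } else if (inherits(model, "multitask_cv")) {
    list(type = 1L, ncv = 2L, desc = desc, mu = model$mu, sd = model$sd,
         W = model$encoder$W, b = model$encoder$b, act = 2L, head = 0L)
  } else stop("unsupported CV model class", call. = FALSE)
}

#' Identity/linear latent CV (testing and auditing helper)
#'
#' A CV that is a fixed linear map of the latent surrogate coordinates,
#' bypassing descriptors and networks.
#'
#' @param P 2 x ncv projection matrix (default identity: s = x).
#' @export
latent_cv <- function(P = diag(2)) {
  structure(list(P = P), class = "latent_cv")
}

#' @export
predict.latent_cv <- function(object, newdata, ...) {
  as.matrix(newdata) %*% object$P
}

#' Run an OPES-biased surrogate simulation
#'
#' Integrates the surrogate Langevin dynamics under an adaptively updated
#' OPES bias acting on the CV model (bias forces reach the latent
#' coordinates by the chain rule through the analytic descriptor map and the
#' network). Records per-frame CVs and instantaneous bias, and attaches
#' normalized importance weights from the final bias for reweighting.
#'
#' @param system a \code{surrogate_system}.
#' @param cv_model a trained \code{deep_lda_cv}, \code{multitask_cv} or a
#'   \code{\link{latent_cv}}.
#' @param config an \code{\link{opes_config}} with matching dimensionality.
#' @param walls optional \code{\link{wall_spec}}.
#' @param n_steps integration steps.
#' @param seed integer seed.
#' @param x0 start point (state name or numeric(2)).
#' @param record_stride store every this-many steps.
#' @param sigma0 optional override of the initial kernel width; when the
#'   config carries \code{NA}, it is estimated as the CV standard deviation
#'   over a short unbiased pre-run.
#' @return a \code{trajectory} with CVs, bias, kernels, the final
#'   \code{opes_bias} and reweighting \code{weights}.
#' @export
run_opes <- function(system, cv_model, config, walls = NULL, n_steps,
                     seed = 1L, x0 = "PRE", record_stride = 10L,
                     sigma0 = NULL) {
  stopifnot(inherits(system, "surrogate_system"),
            inherits(config, "opes_config"))
  spec <- cv_model_spec(cv_model)
  if (spec$ncv != config$ncv)
    stop("opes_config dimensionality (", config$ncv,
         ") does not match the CV model (", spec$ncv, ")", call. = FALSE)
  if (!is.null(walls) && nrow(walls) != config$ncv)
    stop("wall_spec dimensionality mismatch", call. = FALSE)
  if (is.character(x0)) x0 <- system$centers[x0, ]
  if (!is.null(sigma0)) config$sigma0 <- rep_len(sigma0, config$ncv)
  if (anyNA(config$sigma0)) {
    pre <- simulate_surrogate(system, 2000L, x0 = x0, cv_model = cv_model,
                              seed = seed, record_stride = 5L)
    config$sigma0 <- pmax(apply(as_cv_matrix(pre$cv, config$ncv), 2, sd),
                          1e-4)
  }
  bias <- opes_bias(config)
  set.seed(seed)
  res <- cpp_run(surrogate_pars(system), as.numeric(x0), as.integer(n_steps),
                 system$timestep, system$kT, system$friction,
                 as.integer(record_stride), cv_model_spec(cv_model),
                 opes_cpp_pars(bias),
                 if (is.null(walls)) NULL else unclass(walls),
                 bias_stride = config$stride, freeze_bias = FALSE,
                 max_step = default_max_step(system))
  traj <- new_trajectory(res, system, seed, record_stride)
  traj$final_bias <- opes_bias(config, res$kernels)
  traj$weights <- reweight(traj, traj$final_bias)
  traj
}

#' Reweight a biased trajectory to the unbiased ensemble
#'
#' Umbrella-like estimator using the final bias re-evaluated on every
#' recorded frame: weights proportional to \eqn{e^{\beta V_{final}(s_t)}},
#' normalized to sum to one (log-sum-exp guarded).
#'
#' @param trajectory a \code{trajectory} carrying CV values.
#' @param final_bias an \code{opes_bias} (defaults to the bias stored on the
#'   trajectory).
#' @return numeric vector of positive weights summing to 1.
#' @export
reweight <- function(trajectory, final_bias = trajectory$final_bias) {
  if (is.null(trajectory$cv))
    stop("trajectory carries no CV values", call. = FALSE)
  stopifnot(inherits(final_bias, "opes_bias"))
  v <- cpp_eval_bias(opes_cpp_pars(final_bias),
                     as_cv_matrix(trajectory$cv, final_bias$config$ncv))$energy
  lw <- final_bias$config$beta * v
  w <- exp(lw - max(lw))
  w / sum(w)
}
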