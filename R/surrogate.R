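#' Build the surrogate translocation landscape
#'
#' Constructs a smooth two-dimensional model potential with four metastable
#' basins laid out on the unit square: PRE at (0,0), INT1 at (1,0), INT2 at
#' (0,1) and POST at (1,1). The first latent coordinate is primer-strand
#' progress, the second template-strand progress, so INT1 is the
#' "primer translocated first" intermediate and INT2 its template-first
#' mirror. The four edge saddles are calibrated numerically (1-D line scans
#' plus root finding on the bump amplitude of each edge profile) to user-set
#' heights, and a central product bump penalises the direct diagonal
#' PRE-POST crossing so the two stepwise paths are the only viable routes.
#'
#' Default saddle heights above the PRE minimum are 7.5 (PRE-INT1),
#' 15.0 (INT1-POST) and 17.0 (PRE-INT2) kcal/mol, with the INT2-POST saddle
#' placed \code{int2_post_barrier} above the INT2 basin energy.
#'
#' @param basin_energies named numeric of basin energies (kcal/mol) for
#'   PRE, INT1, INT2, POST; PRE must be 0 (the normalization).
#' @param saddle_heights optional numeric(4): edge saddle energies above PRE
#'   for PRE-INT1, INT1-POST, PRE-INT2, INT2-POST. When \code{NULL} the
#'   defaults above are used.
#' @param int2_post_barrier barrier of the INT2 to POST step measured from
#'   the INT2 basin (kcal/mol); used only when \code{saddle_heights} is NULL.
#' @param diagonal_penalty amplitude (kcal/mol) of the central bump blocking
#'   the concerted diagonal crossing.
#' @param kT thermal energy in kcal/mol (0.616 corresponds to 310 K).
#' @param friction,timestep overdamped-Langevin parameters (reduced units).
#' @param seed integer seed stored with the system.
#' @return An object of class \code{surrogate_system}.
#' @export
build_surrogate <- function(basin_energies = c(PRE = 0, INT1 = 2.5,
                                               INT2 = 3.0, POST = 0),
                            saddle_heights = NULL,
                            int2_post_barrier = 10.0,
                            diagonal_penalty = 25.0,
                            kT = 0.616, friction = 1, timestep = 2.5e-4,
                            seed = 1L) {
  states <- c("PRE", "INT1", "INT2", "POST")
  if (!is.numeric(kT) || kT <= 0)
    stop("configuration error: kT must be positive", call. = FALSE)
  if (!is.numeric(timestep) || timestep <= 0)
    stop("configuration error: timestep must be positive", call. = FALSE)
  if (length(basin_energies) != 4)
    stop("configuration error: need four basin energies", call. = FALSE)
  E <- unname(basin_energies)
  if (abs(E[1]) > 1e-12)
    stop("configuration error: PRE basin energy must be 0", call. = FALSE)
  if (is.null(saddle_heights))
    saddle_heights <- c(7.5, 15.0, 17.0, E[3] + int2_post_barrier)
  S <- unname(saddle_heights)
  if (any(S <= 0))
    stop("configuration error: saddle heights must be positive", call. = FALSE)
  # edges: A = PRE-INT1 (vary x1 at x2=0), B = INT2-POST (x1 at x2=1),
  #        C = PRE-INT2 (x2 at x1=0),      D = INT1-POST (x2 at x1=1)
  edges <- list(A = c(E[1], E[2], S[1]), B = c(E[3], E[4], S[4]),
                C = c(E[1], E[3], S[3]), D = c(E[2], E[4], S[2]))
  bumps <- vapply(edges, function(e) calibrate_edge_bump(e[1], e[2], e[3]),
                  numeric(1))
  centers <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE,
                    dimnames = list(states, c("x1", "x2")))
  sys <- structure(list(
    basin_energies = setNames(E, states),
    saddle_heights = setNames(S, c("PRE-INT1", "INT1-POST",
                                   "PRE-INT2", "INT2-POST")),
    bumps = unname(bumps),
    diagonal_penalty = diagonal_penalty,
    kT = kT, friction = friction, timestep = timestep,
    seed = as.integer(seed), centers = centers
  ), class = "surrogate_system")
  # the diagonal must dominate every edge saddle by a wide thermal margin
  vmid <- surrogate_potential(sys, c(0.5, 0.5))$energy
  if (vmid < max(S) + 10 * kT)
    stop("configuration error: diagonal penalty too small; the direct ",
         "PRE-POST crossing must exceed every edge saddle by >= 10 kT",
         call. = FALSE)
  sys
}

# Find the bump amplitude b such that the 1-D edge profile
# e0 + (e1-e0)*s(t) + b*phi(t) has maximum `target` on (0,1).
calibrate_edge_bump <- function(e0, e1, target) {
  if (target <= max(e0, e1))
    stop("configuration error: saddle height ", target,
         " does not exceed the basin energies it connects", call. = FALSE)
  profile_max <- function(b) {
    f <- function(t) edge_profile_r(t, e0, e1, b)
    optimize(f, c(1e-3, 1 - 1e-3), maximum = TRUE)$objective
  }
  upper <- target - (e0 + e1) / 2
  uniroot(function(b) profile_max(b) - target, c(0, upper + 1e-9),
          tol = 1e-10)$root
}

# R-side mirrors of the compiled smootherstep/bump edge profile (used only
# for calibration at build time; dynamics and energies go through C++)
smootherstep_r <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^3 * (10 + t * (-15 + 6 * t))
}
edge_profile_r <- function(t, e0, e1, b) {
  e0 + (e1 - e0) * smootherstep_r(t) + b * 16 * t^2 * (1 - t)^2
}

surrogate_pars <- function(system) {
  list(basin_energies = unname(system$basin_energies),
       bumps = system$bumps,
       diagonal_penalty = system$diagonal_penalty)
}

#' Evaluate the surrogate potential
#'
#' @param system a \code{surrogate_system}.
#' @param x numeric(2) or an n x 2 matrix of latent coordinates.
#' @return list with \code{energy} (kcal/mol) and \code{gradient} (n x 2).
#' @export
surrogate_potential <- function(system, x) {
  stopifnot(inherits(system, "surrogate_system"))
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  out <- cpp_potential(surrogate_pars(system), x)
  if (nrow(x) == 1L) out$gradient <- drop(out$gradient)
  if (length(out$energy) == 1L) out$energy <- out$energy[[1L]]
  out
}

#' Simulate overdamped Langevin dynamics on the surrogate
#'
#' Euler-Maruyama integration of the latent coordinates at temperature
#' \code{kT}, optionally under a frozen external bias acting through a CV
#' model. Randomness goes through R's RNG, so runs are reproducible given
#' \code{seed}.
#'
#' @param system a \code{surrogate_system}.
#' @param n_steps number of integration steps (>= 1).
#' @param x0 starting point: numeric(2) or a state name.
#' @param bias optional \code{opes_bias} to apply (frozen, no updates);
#'   requires \code{cv_model}.
#' @param cv_model CV model through which \code{bias} acts.
#' @param seed integer seed.
#' @param record_stride store every this-many steps.
#' @param kT optional temperature override (kcal/mol).
#' @return A \code{trajectory} object: times, latent coordinates, optional
#'   CV values and bias energies, and the seed used.
#' @export
simulate_surrogate <- function(system, n_steps, x0 = "PRE", bias = NULL,
                               cv_model = NULL, seed = 1L,
                               record_stride = 10L, kT = system$kT) {
  stopifnot(inherits(system, "surrogate_system"))
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  if (is.character(x0)) x0 <- system$centers[x0, ]
  if (!is.null(bias) && is.null(cv_model))
    stop("a bias needs a cv_model to act through", call. = FALSE)
  set.seed(seed)
  spec <- if (is.null(cv_model)) NULL else cv_model_spec(cv_model)
  opes <- if (is.null(bias)) NULL else opes_cpp_pars(bias)
  res <- cpp_run(surrogate_pars(system), as.numeric(x0), as.integer(n_steps),
                 system$timestep, kT, system$friction,
                 as.integer(record_stride), spec, opes, NULL,
                 bias_stride = .Machine$integer.max, freeze_bias = TRUE,
                 max_step = default_max_step(system, kT))
  new_trajectory(res, system, seed, record_stride)
}

#' @rdname simulate_surrogate
#' @param object a \code{surrogate_system} (S3 method for
#'   \code{\link[stats]{simulate}}).
#' @param nsim number of integration steps.
#' @param ... passed on to \code{simulate_surrogate}.
#' @export
simulate.surrogate_system <- function(object, nsim = 1000L, seed = 1L, ...) {
  simulate_surrogate(object, n_steps = nsim, seed = seed, ...)
}

# displacement guard: generous (10 thermal step widths) so it only engages
# on pathological force spikes, e.g. a deep wall overshoot
default_max_step <- function(system, kT = system$kT) {
  10 * sqrt(2 * kT * system$timestep / system$friction)
}

new_trajectory <- function(res, system, seed, record_stride) {
  ncv <- if (length(res$cv)) ncol(res$cv) else 0L
  structure(list(
    time = res$time,
    latent = res$X,
    cv = if (ncv) res$cv else NULL,
    bias = if (ncv) res$bias else NULL,
    weights = NULL,
    kernels = res$kernels,
    diagnostics = list(n_clamped = res$n_clamped,
                       max_bias = res$max_bias, min_bias = res$min_bias,
                       n_merged = res$n_merged, n_deposited = res$n_deposited),
    timestep = system$timestep, record_stride = record_stride,
    seed = seed
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Surrogate trajectory:", nrow(x$latent), "recorded frames\n")
  if (!is.null(x$cv))
    cat("  CV dimensionality:", ncol(x$cv),
        "| max bias:", format(max(x$bias), digits = 4), "kcal/mol\n")
  if (!is.null(x$weights)) cat("  reweighted: yes\n")
  invisible(x)
}

#' @export
print.surrogate_system <- function(x, ...) {
  cat("Surrogate translocation landscape (4 basins, 2 paths)\n")
  cat("  basin energies (kcal/mol):",
      paste(names(x$basin_energies),
            format(x$basin_energies, digits = 3), collapse = ", "), "\n")
  cat("  edge saddles above PRE (kcal/mol):",
      paste(names(x$saddle_heights),
            format(x$saddle_heights, digits = 3), collapse = ", "), "\n")
  cat("  kT =", x$kT, "kcal/mol, dt =", x$timestep, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Descriptor emulation
# ---------------------------------------------------------------------------

#' Candidate contact-descriptor specifications for the surrogate
#'
#' Builds the designed candidate pool emulating the ~350 protein-DNA
#' contact distances screened in the real system. Classes:
#' \describe{
#'   \item{informative_primer / informative_template}{logistic switch between
#'     a bound (~4 A) and an unbound (~9 A) plateau as the primer (x1) or
#'     template (x2) progress coordinate crosses 0.5; exactly one per
#'     synthetic residue-base-pair group.}
#'   \item{redundant_duplicate}{a second, noisier descriptor in an existing
#'     residue-base-pair group.}
#'   \item{low_presence}{plateaus above the contact cutoff in both states.}
#'   \item{non_discriminative}{state-independent distribution.}
#' }
#'
#' @param n_informative,n_redundant,n_low_presence,n_non_discriminative
#'   class sizes; the defaults give the designed 350-column pool whose
#'   three-rule filter retains exactly the 69 informative groups.
#' @return data.frame of per-descriptor metadata (one row per column).
#' @export
descriptor_specs <- function(n_informative = 69L, n_redundant = 81L,
                             n_low_presence = 100L,
                             n_non_discriminative = 100L) {
  n_primer <- ceiling(n_informative / 2)
  rows <- list()
  aa <- function(i) if (i %% 2L == 1L) "LYS" else "ARG"
  for (i in seq_len(n_informative)) {
    axis <- if (i <= n_primer) 1L else 2L
    strand <- if (axis == 1L) "P" else "T"
    up <- i %% 2L == 0L  # alternate contact-forming vs contact-breaking
    rows[[length(rows) + 1L]] <- data.frame(
      descriptor_id = sprintf("c%03d", i),
      class = if (axis == 1L) "informative_primer" else "informative_template",
      residue_label = paste0(aa(i), 100L + i),
      base_pair_label = paste0(strand, 1L + (i %% 9L)),
      axis = axis, base = if (up) 4 else 9, amp = if (up) 5 else -5,
      tau = 0.2, noise_sd = 0.4, stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_redundant)) {
    i <- 1L + (j - 1L) %% n_informative  # spread duplicates over the groups
    tmpl <- rows[[i]]
    tmpl$descriptor_id <- sprintf("c%03d_dup%d", i, 1L + (j - 1L) %/% n_informative)
    tmpl$class <- "redundant_duplicate"
    tmpl$tau <- 0.25
    tmpl$noise_sd <- 0.6
    rows[[length(rows) + 1L]] <- tmpl
  }
  for (j in seq_len(n_low_presence)) {
    rows[[length(rows) + 1L]] <- data.frame(
      descriptor_id = sprintf("lp%03d", j), class = "low_presence",
      residue_label = paste0(aa(j), 300L + j),
      base_pair_label = paste0(if (j %% 2L) "P" else "T", 1L + (j %% 9L)),
      axis = 1L + j %% 2L, base = 7.5, amp = 3, tau = 0.1, noise_sd = 0.4,
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_non_discriminative)) {
    rows[[length(rows) + 1L]] <- data.frame(
      descriptor_id = sprintf("nd%03d", j), class = "non_discriminative",
      residue_label = paste0(aa(j), 500L + j),
      base_pair_label = paste0(if (j %% 2L) "P" else "T", 1L + (j %% 9L)),
      axis = 1L, base = 5.0, amp = 0, tau = 0.1, noise_sd = 0.5,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Emit synthetic contact-distance descriptors for latent frames
#'
#' Each descriptor column is a logistic switch of one latent axis between
#' two plateau distances plus additive Gaussian noise (its spec row).
#'
#' @param system a \code{surrogate_system} (unused numerically but anchors
#'   units and documents provenance).
#' @param latent n x 2 matrix of latent coordinates.
#' @param specs data.frame from \code{\link{descriptor_specs}}.
#' @param seed integer seed for the noise.
#' @param noise if FALSE, return the deterministic mean map.
#' @param labels optional per-frame state labels stored with the table.
#' @return A \code{descriptor_table}: list with \code{values} (n x p matrix),
#'   \code{meta} (the specs) and optional \code{labels}.
#' @export
emit_descriptors <- function(system, latent, specs, seed = 1L, noise = TRUE,
                             labels = NULL) {
  if (nrow(specs) == 0L) stop("specs must be nonempty", call. = FALSE)
  if (is.null(dim(latent))) latent <- matrix(latent, ncol = 2)
  set.seed(seed)
  n <- nrow(latent)
  vals <- matrix(0, n, nrow(specs),
                 dimnames = list(NULL, specs$descriptor_id))
  for (j in seq_len(nrow(specs))) {
    s <- specs[j, ]
    m <- s$base + s$amp * plogis((latent[, s$axis] - 0.5) / s$tau)
    vals[, j] <- if (noise) m + rnorm(n, sd = s$noise_sd) else m
  }
  descriptor_table(vals, specs, labels)
}

#' Construct a descriptor table
#'
#' @param values numeric matrix, frames x descriptors (named columns).
#' @param meta per-descriptor metadata data.frame with a
#'   \code{descriptor_id} column matching the column names.
#' @param labels optional character vector of per-frame state labels.
#' @export
descriptor_table <- function(values, meta, labels = NULL) {
  stopifnot(is.matrix(values), nrow(meta) == ncol(values))
  if (!is.null(labels)) stopifnot(length(labels) == nrow(values))
  structure(list(values = values, meta = meta, labels = labels),
            class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("Descriptor table:", nrow(x$values), "frames x",
      ncol(x$values), "descriptors\n")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$meta$class)) {
    tab <- table(x$meta$class)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# basin-restricted Boltzmann sampling: short unbiased runs started at the
# basin center; barriers of >= 12 kT make escapes astronomically unlikely
# on these run lengths
sample_state_frames <- function(system, state, n_frames, seed,
                                thin = 10L, burn_in = 2000L) {
  n_steps <- burn_in + n_frames * thin
  traj <- simulate_surrogate(system, n_steps, x0 = state, seed = seed,
                             record_stride = thin)
  X <- traj$latent
  X[(nrow(X) - n_frames + 1L):nrow(X), , drop = FALSE]
}

#' Two-state descriptor fixture (candidate pool for filtering and Deep-LDA)
#'
#' Generates the packaged synthetic candidate pool: descriptor tables for
#' the PRE and POST states over the designed 350-column inventory
#' (69 informative groups, 81 redundant duplicates, 100 low-presence,
#' 100 non-discriminative columns), sampled from basin-restricted dynamics.
#'
#' @param seed integer master seed.
#' @param n_frames frames per state (the reference setting is 20000).
#' @param system optional \code{surrogate_system}; defaults to
#'   \code{build_surrogate()}.
#' @param specs optional descriptor specs; defaults to the designed pool.
#' @return list with \code{descriptor_table}s \code{PRE} and \code{POST}
#'   (each carrying labels) and the \code{specs}.
#' @export
make_fixture <- function(seed = 1L, n_frames = 20000L, system = NULL,
                         specs = NULL) {
  if (is.null(system)) system <- build_surrogate()
  if (is.null(specs)) specs <- descriptor_specs()
  out <- list()
  for (k in seq_along(c("PRE", "POST"))) {
    st <- c("PRE", "POST")[k]
    X <- sample_state_frames(system, st, n_frames, seed = seed + k)
    out[[st]] <- emit_descriptors(system, X, specs, seed = seed + 10L + k,
                                  labels = rep(st, n_frames))
  }
  out$specs <- specs
  out
}

#' Four-state + reactive fixture for the multitask CV
#'
#' Labeled basin samples for PRE, INT1, INT2 and POST plus an unlabeled
#' "reactive" set drawn along the two translocation paths (uniform along
#' each edge of the state square with transverse Gaussian jitter),
#' emulating configurations harvested from CV-biased reactive trajectories.
#'
#' @param seed integer master seed.
#' @param n_labeled frames per labeled state.
#' @param n_reactive unlabeled reactive frames.
#' @param descriptors character: which descriptor columns to emit;
#'   \code{"retained"} (default) runs the three-rule filter on a matched
#'   two-state pool and keeps the surviving 69 columns, as in the reference
#'   protocol; \code{"all"} keeps the full pool.
#' @param jitter transverse SD of the reactive tube (latent units).
#' @inheritParams make_fixture
#' @return list with \code{labeled} (a labeled \code{descriptor_table} over
#'   the four states), \code{reactive} (unlabeled \code{descriptor_table})
#'   and \code{specs} for the emitted columns.
#' @export
make_multitask_fixture <- function(seed = 1L, n_labeled = 5000L,
                                   n_reactive = 10000L, system = NULL,
                                   specs = NULL,
                                   descriptors = c("retained", "all"),
                                   jitter = 0.05) {
  descriptors <- match.arg(descriptors)
  if (is.null(system)) system <- build_surrogate()
  if (is.null(specs)) specs <- descriptor_specs()
  if (descriptors == "retained") {
    pool <- make_fixture(seed = seed, n_frames = 5000L, system = system,
                         specs = specs)
    keep <- filter_descriptors(pool$PRE, pool$POST)$retained
    specs <- specs[match(keep, specs$descriptor_id), ]
  }
  states <- c("PRE", "INT1", "INT2", "POST")
  Xl <- vector("list", 4L)
  for (k in seq_along(states)) {
    Xl[[k]] <- sample_state_frames(system, states[k], n_labeled,
                                   seed = seed + 20L + k)
  }
  labeled <- emit_descriptors(system, do.call(rbind, Xl), specs,
                              seed = seed + 30L,
                              labels = rep(states, each = n_labeled))
  # reactive tube: edges PRE-INT1, INT1-POST, PRE-INT2, INT2-POST
  set.seed(seed + 40L)
  edge <- sample.int(4L, n_reactive, replace = TRUE)
  t <- runif(n_reactive)
  u <- rnorm(n_reactive, sd = jitter)
  Xr <- matrix(0, n_reactive, 2L)
  Xr[edge == 1L, ] <- cbind(t[edge == 1L], u[edge == 1L])
  Xr[edge == 2L, ] <- cbind(1 + u[edge == 2L], t[edge == 2L])
  Xr[edge == 3L, ] <- cbind(u[edge == 3L], t[edge == 3L])
  Xr[edge == 4L, ] <- cbind(t[edge == 4L], 1 + u[edge == 4L])
  reactive <- emit_descriptors(system, Xr, specs, seed = seed + 41L)
  list(labeled = labeled, reactive = reactive, specs = specs)
}
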