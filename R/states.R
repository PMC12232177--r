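#' Reference geometry for state assignment
#'
#' Frames are assigned to a metastable state when they fall inside a fixed
#' radius of its reference point, and to TRANSIT otherwise. For surrogate
#' data the metric space is the latent plane (primer progress, template
#' progress); for real data the two axes are the primer- and
#' template-strand phosphate displacement metrics.
#'
#' @param centers matrix of reference points (rows named by state).
#' @param radius assignment radius, scalar or per state.
#' @return object of class \code{state_reference}.
#' @export
state_reference <- function(centers = build_surrogate()$centers,
                            radius = 0.25) {
  radius <- rep_len(radius, nrow(centers))
  if (any(radius <= 0)) stop("radii must be positive", call. = FALSE)
  d <- as.matrix(dist(centers))
  diag(d) <- Inf
  if (min(d) <= 2 * max(radius))
    stop("reference-configuration error: state spheres overlap ",
         "(centers closer than twice the radius)", call. = FALSE)
  structure(list(centers = as.matrix(centers), radius = radius),
            class = "state_reference")
}

#' Assign frames to metastable states
#'
#' @param x a \code{trajectory} (its latent coordinates are used) or a
#'   coordinate matrix matching the reference dimensionality.
#' @param reference a \code{\link{state_reference}}.
#' @return character vector of labels (state names or "TRANSIT").
#' @export
assign_states <- function(x, reference = state_reference()) {
  stopifnot(inherits(reference, "state_reference"))
  X <- if (inherits(x, "trajectory")) x$latent else as.matrix(x)
  if (ncol(X) != ncol(reference$centers))
    stop("coordinate dimensionality does not match the reference",
         call. = FALSE)
  lab <- rep("TRANSIT", nrow(X))
  d2min <- rep(Inf, nrow(X))
  for (k in seq_len(nrow(reference$centers))) {
    d2 <- rowSums(sweep(X, 2, reference$centers[k, ])^2)
    inside <- d2 <= reference$radius[k]^2 & d2 < d2min
    lab[inside] <- rownames(reference$centers)[k]
    d2min <- pmin(d2min, d2)
  }
  lab
}

#' Count end-state transitions and classify their pathway
#'
#' Scans a label sequence for excursions between the two end states
#' (PRE and POST). A state is "entered" when at least \code{settle}
#' consecutive frames carry its label (suppressing recrossing noise);
#' a record is emitted whenever the settled end state changes. The
#' intermediate attributed to a record is the last INT1/INT2 label seen
#' strictly between the endpoints; pathway 1 is via INT1, pathway 2 via
#' INT2.
#'
#' @param labels character label sequence from \code{\link{assign_states}}.
#' @param settle minimum consecutive frames to count a state as entered.
#' @param end_states the two terminal states.
#' @return data.frame of class \code{transition_records} with columns
#'   \code{from}, \code{to}, \code{start_frame}, \code{end_frame},
#'   \code{intermediate}, \code{pathway}.
#' @export
count_transitions <- function(labels, settle = 10L,
                              end_states = c("PRE", "POST")) {
  if (length(labels) == 0L) stop("empty label sequence", call. = FALSE)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  settled <- r$lengths >= settle & r$values != "TRANSIT"
  vis_state <- r$values[settled]
  vis_start <- starts[settled]
  vis_end <- ends[settled]
  is_end <- vis_state %in% end_states
  ei <- which(is_end)
  recs <- list()
  for (k in seq_along(ei)[-1]) {
    a <- ei[k - 1L]
    b <- ei[k]
    if (vis_state[a] == vis_state[b]) next
    f0 <- vis_end[a]
    f1 <- vis_start[b]
    between <- labels[seq.int(f0 + 1L, max(f0 + 1L, f1 - 1L))]
    ints <- between[between %in% c("INT1", "INT2")]
    intermediate <- if (length(ints)) ints[length(ints)] else "none"
    recs[[length(recs) + 1L]] <- data.frame(
      from = vis_state[a], to = vis_state[b],
      start_frame = f0, end_frame = f1,
      intermediate = intermediate,
      pathway = switch(intermediate, INT1 = 1L, INT2 = 2L, NA_integer_),
      stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(from = character(), to = character(),
               start_frame = integer(), end_frame = integer(),
               intermediate = character(), pathway = integer(),
               stringsAsFactors = FALSE)
  class(out) <- c("transition_records", class(out))
  out
}

#' Per-state distance distributions of descriptors
#'
#' Normalised histograms and mean +/- SD summaries of each descriptor
#' within each state, the per-state reporting style used for key
#' residue-DNA distances.
#'
#' @param table a \code{descriptor_table} (or matrix).
#' @param labels per-frame state labels aligned with the table.
#' @param states states to summarise (default: all non-TRANSIT present).
#' @param breaks histogram breaks (passed to \code{\link[graphics]{hist}}).
#' @return list with \code{summary} (descriptor, state, mean, sd, n) and
#'   \code{histograms} (nested list of density histograms).
#' @export
state_distance_distributions <- function(table, labels, states = NULL,
                                         breaks = 50) {
  X <- if (inherits(table, "descriptor_table")) table$values else
    as.matrix(table)
  stopifnot(length(labels) == nrow(X))
  present <- setdiff(unique(labels), "TRANSIT")
  if (is.null(states)) states <- present
  absent <- setdiff(states, present)
  if (length(absent))
    stop("input error: state(s) absent from labels: ",
         paste(absent, collapse = ", "), call. = FALSE)
  sm <- list()
  hists <- list()
  for (s in states) {
    xs <- X[labels == s, , drop = FALSE]
    hists[[s]] <- list()
    for (j in seq_len(ncol(X))) {
      id <- colnames(X)[j]
      v <- xs[, j]
      sm[[length(sm) + 1L]] <- data.frame(
        descriptor_id = id, state = s, mean = mean(v), sd = sd(v),
        n = length(v), stringsAsFactors = FALSE)
      hists[[s]][[id]] <- if (length(unique(v)) == 1L) {
        list(mids = v[1L], density = Inf, degenerate = TRUE)
      } else {
        h <- graphics::hist(v, breaks = breaks, plot = FALSE)
        list(mids = h$mids, density = h$density,
             breaks = h$breaks, degenerate = FALSE)
      }
    }
  }
  list(summary = do.call(rbind, sm), histograms = hists)
}

#' Pathway preference of PRE-origin transitions
#'
#' Fraction of transitions starting from PRE that proceed via INT1
#' (pathway 1), with an exact binomial confidence interval.
#'
#' @param records a \code{\link{count_transitions}} result.
#' @param conf.level confidence level for the interval.
#' @return list with \code{fraction}, \code{n}, \code{n_via_int1} and
#'   \code{conf.int}.
#' @export
pathway_preference <- function(records, conf.level = 0.95) {
  pre <- records[records$from == "PRE", , drop = FALSE]
  if (nrow(pre) == 0L)
    stop("undefined result: no PRE-origin transitions", call. = FALSE)
  k <- sum(pre$intermediate == "INT1")
  bt <- binom.test(k, nrow(pre), conf.level = conf.level)
  list(fraction = k / nrow(pre), n = nrow(pre), n_via_int1 = k,
       conf.int = as.numeric(bt$conf.int))
}
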