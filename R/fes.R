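#' Estimate a free-energy surface from (weighted) CV samples
#'
#' Bins samples on a regular 2-D grid and sets
#' \eqn{F = -\frac{1}{\beta}\log(\text{weighted occupancy})}, shifted so the
#' minimum estimated cell is 0. Cells with no samples are flagged
#' unestimated (NA), never 0.
#'
#' @param cv n x 2 matrix of CV samples.
#' @param weights optional normalized frame weights (default uniform).
#' @param bounds list or vector: \code{c(lo, hi)} applied to both axes, or
#'   list of two such vectors.
#' @param bins number of bins per axis (scalar or length 2).
#' @param beta inverse thermal energy (mol/kcal).
#' @param n_blocks optional: also compute a per-cell standard error from
#'   this many contiguous sample blocks.
#' @return object of class \code{fes_grid}: axis centers \code{x}, \code{y},
#'   free-energy matrix \code{F} (kcal/mol), occupancy \code{W}, optional
#'   \code{error}, plus \code{beta}, \code{bounds}, \code{bins}.
#' @export
estimate_fes <- function(cv, weights = NULL, bounds = c(-7.5, 7.5),
                         bins = 60L, beta = 1 / 0.616, n_blocks = NULL) {
  cv <- as.matrix(cv)
  stopifnot(ncol(cv) == 2L)
  if (!is.list(bounds)) bounds <- list(bounds, bounds)
  bins <- rep_len(as.integer(bins), 2L)
  n <- nrow(cv)
  if (is.null(weights)) weights <- rep(1 / n, n)
  stopifnot(length(weights) == n)
  bx <- seq(bounds[[1]][1], bounds[[1]][2], length.out = bins[1] + 1L)
  by <- seq(bounds[[2]][1], bounds[[2]][2], length.out = bins[2] + 1L)
  ix <- findInterval(cv[, 1], bx, rightmost.closed = TRUE)
  iy <- findInterval(cv[, 2], by, rightmost.closed = TRUE)
  ok <- ix >= 1L & ix <= bins[1] & iy >= 1L & iy <= bins[2]
  if (!any(ok)) stop("input error: all samples fall outside the grid",
                     call. = FALSE)
  W <- matrix(0, bins[1], bins[2])
  acc <- tapply(weights[ok], list((ix[ok] - 1L) * bins[2] + iy[ok]), sum)
  cells <- as.integer(names(acc))
  W[cbind((cells - 1L) %/% bins[2] + 1L, (cells - 1L) %% bins[2] + 1L)] <- acc
  F <- matrix(NA_real_, bins[1], bins[2])
  est <- W > 0
  F[est] <- -log(W[est]) / beta
  F <- F - min(F, na.rm = TRUE)
  err <- NULL
  if (!is.null(n_blocks) && n_blocks >= 2L) {
    Fb <- array(NA_real_, c(bins[1], bins[2], n_blocks))
    blk <- ceiling(seq_len(n) / (n / n_blocks))
    for (b in seq_len(n_blocks)) {
      sel <- blk == b
      fb <- tryCatch(
        estimate_fes(cv[sel, , drop = FALSE],
                     weights[sel] / sum(weights[sel]),
                     bounds, bins, beta),
        error = function(e) NULL)
      if (!is.null(fb)) Fb[, , b] <- fb$F
    }
    err <- apply(Fb, c(1, 2), function(v) {
      v <- v[is.finite(v)]
      if (length(v) < 2L) NA_real_ else sd(v) / sqrt(length(v))
    })
  }
  structure(list(x = (bx[-1] + bx[-length(bx)]) / 2,
                 y = (by[-1] + by[-length(by)]) / 2,
                 F = F, W = W, error = err, beta = beta,
                 bounds = bounds, bins = bins),
            class = "fes_grid")
}

#' Construct a free-energy grid from a precomputed matrix
#'
#' @param F free-energy matrix (kcal/mol; NA = unestimated).
#' @param x,y axis cell centers.
#' @param beta inverse thermal energy.
#' @export
as_fes_grid <- function(F, x = seq_len(nrow(F)), y = seq_len(ncol(F)),
                        beta = 1 / 0.616) {
  structure(list(x = x, y = y, F = F - min(F, na.rm = TRUE),
                 W = NULL, error = NULL, beta = beta,
                 bounds = list(range(x), range(y)),
                 bins = dim(F)),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat("Free-energy surface:", nrow(x$F), "x", ncol(x$F), "cells,",
      sum(is.finite(x$F)), "estimated\n")
  cat("  range of estimated F:", paste(format(range(x$F, na.rm = TRUE),
                                              digits = 4), collapse = " - "),
      "kcal/mol\n")
  invisible(x)
}

#' @export
plot.fes_grid <- function(x, levels = pretty(range(x$F, na.rm = TRUE), 12),
                          ...) {
  graphics::filled.contour(x$x, x$y, x$F, levels = levels,
                           color.palette = grDevices::hcl.colors,
                           xlab = "CV1", ylab = "CV2", ...)
  invisible(x)
}

# integer vectors are cell indices; doubles are CV-space coordinates
# snapped to the nearest cell
fes_cell_of <- function(fes, point) {
  stopifnot(length(point) == 2L)
  if (is.integer(point)) return(point)
  c(which.min(abs(fes$x - point[1])), which.min(abs(fes$y - point[2])))
}

#' Minimum-energy (minimax) path between two basins on a FES grid
#'
#' Returns the path over 8-connected estimated grid cells that minimises
#' the maximum free energy crossed; the barrier is that maximum relative to
#' the free energy of the start cell. Unestimated cells are impassable;
#' a logical \code{mask} can further restrict the search region (e.g. to a
#' single pathway's half plane).
#'
#' @param fes an \code{fes_grid}.
#' @param start,end CV-space points (numeric(2), snapped to the nearest
#'   cell) or integer cell indices \code{c(i, j)}.
#' @param mask optional logical matrix (same shape as \code{fes$F}); FALSE
#'   cells are impassable.
#' @return object of class \code{fes_path}: data.frame \code{path} with the
#'   ordered cells, \code{barrier} (kcal/mol), \code{threshold} (absolute
#'   minimax level) and \code{start_F}.
#' @export
minimum_energy_path <- function(fes, start, end, mask = NULL) {
  stopifnot(inherits(fes, "fes_grid"))
  Fm <- fes$F
  nb <- dim(Fm)
  sc <- fes_cell_of(fes, start)
  ec <- fes_cell_of(fes, end)
  allowed <- is.finite(Fm)
  if (!is.null(mask)) allowed <- allowed & mask
  for (cell in list(sc, ec)) {
    if (!allowed[cell[1], cell[2]])
      stop("endpoint cell is unestimated or masked", call. = FALSE)
  }
  idx <- which(allowed)
  ord <- idx[order(Fm[idx])]
  # union-find over cells added in increasing free energy
  parent <- seq_len(prod(nb))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  added <- matrix(FALSE, nb[1], nb[2])
  sflat <- (sc[2] - 1L) * nb[1] + sc[1]
  eflat <- (ec[2] - 1L) * nb[1] + ec[1]
  threshold <- NA_real_
  for (f in ord) {
    i <- (f - 1L) %% nb[1] + 1L
    j <- (f - 1L) %/% nb[1] + 1L
    added[i, j] <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      ii <- i + di; jj <- j + dj
      if (ii < 1L || ii > nb[1] || jj < 1L || jj > nb[2]) next
      if (!added[ii, jj]) next
      ra <- find(f); rb <- find((jj - 1L) * nb[1] + ii)
      if (ra != rb) parent[ra] <- rb
    }
    if (added[sc[1], sc[2]] && added[ec[1], ec[2]] &&
        find(sflat) == find(eflat)) {
      threshold <- Fm[f]
      break
    }
  }
  if (is.na(threshold))
    stop("connectivity error: endpoints are not connected through ",
         "estimated cells", call. = FALSE)
  # shortest path through cells at or below the threshold (BFS)
  open <- allowed & Fm <= threshold
  prev <- matrix(NA_integer_, nb[1], nb[2])
  seen <- matrix(FALSE, nb[1], nb[2])
  queue <- c(sflat)
  seen[sc[1], sc[2]] <- TRUE
  qi <- 1L
  while (qi <= length(queue)) {
    f <- queue[qi]; qi <- qi + 1L
    i <- (f - 1L) %% nb[1] + 1L
    j <- (f - 1L) %/% nb[1] + 1L
    if (f == eflat) break
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      ii <- i + di; jj <- j + dj
      if (ii < 1L || ii > nb[1] || jj < 1L || jj > nb[2]) next
      if (!open[ii, jj] || seen[ii, jj]) next
      seen[ii, jj] <- TRUE
      prev[ii, jj] <- f
      queue <- c(queue, (jj - 1L) * nb[1] + ii)
    }
  }
  cells <- list()
  f <- eflat
  while (!is.na(f)) {
    i <- (f - 1L) %% nb[1] + 1L
    j <- (f - 1L) %/% nb[1] + 1L
    cells[[length(cells) + 1L]] <- c(i, j)
    if (f == sflat) break
    f <- prev[i, j]
  }
  cells <- rev(cells)
  path <- data.frame(
    i = vapply(cells, `[`, integer(1), 1L),
    j = vapply(cells, `[`, integer(1), 2L))
  path$cv1 <- fes$x[path$i]
  path$cv2 <- fes$y[path$j]
  path$F <- Fm[cbind(path$i, path$j)]
  start_F <- Fm[sc[1], sc[2]]
  structure(list(path = path, barrier = max(path$F) - start_F,
                 threshold = threshold, start_F = start_F),
            class = "fes_path")
}

#' @export
print.fes_path <- function(x, ...) {
  cat("Minimax path:", nrow(x$path), "cells, barrier",
      format(x$barrier, digits = 4), "kcal/mol\n")
  invisible(x)
}

#' Half-plane pathway masks for the two translocation routes
#'
#' The two pathways live on opposite sides of the diagonal connecting PRE
#' and POST (INT1 on the cv1 > cv2 side, INT2 on the cv1 < cv2 side, for
#' center layouts like the target geometry). Cells on the diagonal belong
#' to both masks.
#'
#' @param fes an \code{fes_grid}.
#' @param via "INT1" or "INT2".
#' @param band tolerance band around the diagonal (CV units); defaults to
#'   one grid cell so the on-diagonal end states belong to both masks.
#' @return logical matrix usable as \code{mask} in
#'   \code{\link{minimum_energy_path}}.
#' @export
pathway_mask <- function(fes, via = c("INT1", "INT2"), band = NULL) {
  via <- match.arg(via)
  if (is.null(band))
    band <- max(diff(fes$x[1:2]), diff(fes$y[1:2]))
  d <- outer(fes$x, fes$y, "-")
  if (via == "INT1") d >= -band else d <= band
}

#' The four designed edge barriers from a FES
#'
#' Extracts, via masked minimax paths, the barriers the landscape was
#' designed around: PRE to INT1 and the overall PRE to POST barrier on
#' pathway 1 (both measured from PRE), PRE to INT2 (from PRE) and INT2 to
#' POST (measured from INT2) on pathway 2.
#'
#' @param fes an \code{fes_grid} over a CV space.
#' @param centers 4 x 2 matrix of state locations in that CV space with
#'   rownames PRE, INT1, INT2, POST.
#' @return data.frame with columns \code{name}, \code{from}, \code{to},
#'   \code{via}, \code{barrier}.
#' @export
edge_barriers <- function(fes, centers) {
  m1 <- pathway_mask(fes, "INT1")
  m2 <- pathway_mask(fes, "INT2")
  spec <- list(
    list("PRE-INT1", "PRE", "INT1", "INT1", m1),
    list("PRE-POST(via INT1)", "PRE", "POST", "INT1", m1),
    list("PRE-INT2", "PRE", "INT2", "INT2", m2),
    list("INT2-POST", "INT2", "POST", "INT2", m2))
  rows <- lapply(spec, function(s) {
    p <- minimum_energy_path(fes, centers[s[[2]], ], centers[s[[3]], ],
                             mask = s[[5]])
    data.frame(name = s[[1]], from = s[[2]], to = s[[3]], via = s[[4]],
               barrier = p$barrier, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Block-average errors for FES barriers
#'
#' Splits the trajectory into contiguous blocks, recomputes the FES and the
#' requested barriers per block, and reports the standard error over blocks.
#' Blocks in which an endpoint basin is unsampled (or disconnected) are
#' skipped and counted.
#'
#' @inheritParams estimate_fes
#' @param n_blocks number of contiguous blocks (>= 2).
#' @param endpoints list of \code{list(start =, end =, mask_via =)} entries,
#'   or a \code{centers} matrix to use the designed-edge set of
#'   \code{\link{edge_barriers}}.
#' @return data.frame with \code{name}, \code{barrier} (full-data value),
#'   \code{error}, \code{n_blocks_used}, \code{n_blocks_skipped}.
#' @export
barrier_errors <- function(cv, weights = NULL, bounds = c(-7.5, 7.5),
                           bins = 60L, beta = 1 / 0.616, n_blocks = 4L,
                           endpoints) {
  if (n_blocks < 2L) stop("n_blocks must be >= 2", call. = FALSE)
  cv <- as.matrix(cv)
  n <- nrow(cv)
  if (is.null(weights)) weights <- rep(1 / n, n)
  full <- estimate_fes(cv, weights, bounds, bins, beta)
  if (is.matrix(endpoints)) {
    centers <- endpoints
    eb <- edge_barriers(full, centers)
    endpoints <- list(
      list(name = "PRE-INT1", start = centers["PRE", ],
           end = centers["INT1", ], mask_via = "INT1"),
      list(name = "PRE-POST(via INT1)", start = centers["PRE", ],
           end = centers["POST", ], mask_via = "INT1"),
      list(name = "PRE-INT2", start = centers["PRE", ],
           end = centers["INT2", ], mask_via = "INT2"),
      list(name = "INT2-POST", start = centers["INT2", ],
           end = centers["POST", ], mask_via = "INT2"))
    full_barriers <- eb$barrier
  } else {
    full_barriers <- vapply(endpoints, function(e) {
      mask <- if (is.null(e$mask_via)) NULL else pathway_mask(full, e$mask_via)
      minimum_energy_path(full, e$start, e$end, mask)$barrier
    }, numeric(1))
  }
  blk <- ceiling(seq_len(n) / (n / n_blocks))
  vals <- matrix(NA_real_, n_blocks, length(endpoints))
  skipped <- integer(length(endpoints))
  for (b in seq_len(n_blocks)) {
    sel <- blk == b
    fb <- tryCatch(estimate_fes(cv[sel, , drop = FALSE],
                                weights[sel] / sum(weights[sel]),
                                bounds, bins, beta),
                   error = function(e) NULL)
    for (k in seq_along(endpoints)) {
      e <- endpoints[[k]]
      vals[b, k] <- if (is.null(fb)) NA_real_ else tryCatch({
        mask <- if (is.null(e$mask_via)) NULL else pathway_mask(fb, e$mask_via)
        minimum_energy_path(fb, e$start, e$end, mask)$barrier
      }, error = function(err) NA_real_)
    }
  }
  errs <- numeric(length(endpoints))
  used <- integer(length(endpoints))
  for (k in seq_along(endpoints)) {
    v <- vals[, k][is.finite(vals[, k])]
    used[k] <- length(v)
    skipped[k] <- n_blocks - length(v)
    errs[k] <- if (length(v) >= 2L) sd(v) / sqrt(length(v)) else NA_real_
  }
  if (any(skipped > 0L))
    warning(sum(skipped), " block barrier(s) skipped (unsampled endpoint)",
            call. = FALSE)
  data.frame(
    name = vapply(endpoints, function(e)
      if (is.null(e$name)) "barrier" else e$name, character(1)),
    barrier = full_barriers, error = errs,
    n_blocks_used = used, n_blocks_skipped = skipped,
    stringsAsFactors = FALSE)
}
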