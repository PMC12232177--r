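# independent minimax oracles: exhaustive DFS over all simple paths (small
# grids) and threshold search with BFS connectivity (medium grids)
dfs_minimax <- function(F, start, end) {
  nb <- dim(F)
  best <- Inf
  visited <- matrix(FALSE, nb[1], nb[2])
  rec <- function(i, j, cur) {
    cur <- max(cur, F[i, j])
    if (cur >= best) return()
    if (i == end[1] && j == end[2]) { best <<- cur; return() }
    visited[i, j] <<- TRUE
    # visit low-energy neighbors first: tightens the bound early while
    # still enumerating every simple path not pruned by it
    nbrs <- NULL
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if ((di | dj) && ii >= 1 && ii <= nb[1] && jj >= 1 && jj <= nb[2] &&
          !visited[ii, jj] && is.finite(F[ii, jj]))
        nbrs <- rbind(nbrs, c(ii, jj, F[ii, jj]))
    }
    if (!is.null(nbrs))
      for (r in order(nbrs[, 3])) rec(nbrs[r, 1], nbrs[r, 2], cur)
    visited[i, j] <<- FALSE
  }
  rec(start[1], start[2], -Inf)
  best
}

threshold_minimax <- function(F, start, end) {
  for (thr in sort(unique(as.numeric(F[is.finite(F)])))) {
    open <- is.finite(F) & F <= thr
    if (!open[start[1], start[2]] || !open[end[1], end[2]]) next
    # BFS connectivity
    seen <- matrix(FALSE, nrow(F), ncol(F))
    q <- list(start)
    seen[start[1], start[2]] <- TRUE
    while (length(q)) {
      c0 <- q[[1]]; q <- q[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- c0[1] + di; jj <- c0[2] + dj
        if ((di | dj) && ii >= 1 && ii <= nrow(F) && jj >= 1 &&
            jj <= ncol(F) && open[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          q <- c(q, list(c(ii, jj)))
        }
      }
    }
    if (seen[end[1], end[2]]) return(thr)
  }
  Inf
}
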