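## Jonker-Volgenant shortest-augmenting-path solver for the square linear
## assignment problem (exact Kuhn-Munkres optimum, O(n^3)). Rows are
## processed in increasing index order, which fixes tie-breaking
## deterministically. `a` must be a finite square matrix.
lap_square <- function(a) {
  n <- nrow(a)
  m <- ncol(a)
  stopifnot(n == m, all(is.finite(a)))
  u <- numeric(n)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)       # p[j] = row assigned to column j (0 = none)
  way <- integer(m + 1L)
  J0 <- m + 1L               # virtual column
  for (i in seq_len(n)) {
    p[J0] <- i
    j0 <- J0
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      cur <- a[i0, ] - u[i0] - v[seq_len(m)]
      upd <- !used[seq_len(m)] & cur < minv
      minv[upd] <- cur[upd]
      way[upd] <- j0
      free <- which(!used[seq_len(m)])
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      su <- which(used)
      u[p[su]] <- u[p[su]] + delta
      v[su] <- v[su] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == J0) break
    }
  }
  p[seq_len(m)]              # row matched to each column
}

#' Solve a (possibly rectangular) minimum-cost assignment
#'
#' Exact Kuhn-Munkres / Jonker-Volgenant solution of the rectangular linear
#' assignment problem. Entries of `+Inf` mark forbidden pairings: internally
#' they are replaced by a sentinel exceeding the sum of all finite entries,
#' the square-padded problem is solved exactly, and any matched pair that hit
#' the sentinel is stripped, so the result is the minimum-cost pairing among
#' all maximum-cardinality feasible pairings. Rows and columns may therefore
#' end up unassigned.
#'
#' @param cost Numeric matrix, entries `>= 0` or `+Inf`.
#' @return Tibble with columns `row`, `col` (1-based indices of matched
#'   pairs) and `cost`; attribute `total` holds the summed cost.
#' @export
solve_assignment <- function(cost) {
  if (length(cost) == 0 || nrow(cost) == 0 || ncol(cost) == 0) {
    out <- tibble(row = integer(), col = integer(), cost = double())
    attr(out, "total") <- 0
    return(out)
  }
  if (any(cost < 0, na.rm = TRUE)) abort("costs must be non-negative")
  n <- nrow(cost); m <- ncol(cost)
  finite <- cost[is.finite(cost)]
  M <- 1 + sum(finite)
  a <- cost
  a[!is.finite(a)] <- M
  k <- max(n, m)
  sq <- matrix(0, k, k)      # zero-cost dummy rows/columns absorb the slack
  sq[seq_len(n), seq_len(m)] <- a
  p <- lap_square(sq)
  rows <- p[seq_len(m)]
  keep <- which(rows <= n & rows > 0L)
  rr <- rows[keep]; cc <- keep
  real <- is.finite(cost[cbind(rr, cc)])
  out <- tibble(row = as.integer(rr[real]), col = as.integer(cc[real]),
                cost = cost[cbind(rr[real], cc[real])])
  out <- dplyr::arrange(out, .data$row)
  attr(out, "total") <- sum(out$cost)
  out
}
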