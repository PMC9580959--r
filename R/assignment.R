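#' Minimum-cost one-to-one assignment
#'
#' Solves the rectangular linear assignment problem by shortest augmenting
#' paths with dual potentials (Jonker-Volgenant). Every row is assigned to a
#' distinct column; `Inf` entries forbid a link (internally replaced by a
#' finite sentinel, and links ending on a sentinel are reported as
#' unassigned).
#'
#' @param cost numeric matrix, `nrow(cost) <= ncol(cost)`. May contain `Inf`
#'   for forbidden pairings.
#' @return integer vector of length `nrow(cost)`; entry `i` is the column
#'   assigned to row `i`, or `NA` if row `i` could only be placed on a
#'   forbidden column.
#' @keywords internal
solve_assignment <- function(cost) {
  if (!is.matrix(cost)) cost <- as.matrix(cost)
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0L) return(integer(0))
  stopifnot(n <= m)
  finite <- cost[is.finite(cost)]
  big <- if (length(finite)) max(abs(finite)) * (m + n) + 1 else 1
  a <- cost
  a[!is.finite(a)] <- big

  u <- numeric(n)       # row potentials
  v <- numeric(m + 1)   # column potentials; index m+1 is the virtual column
  p <- integer(m + 1)   # p[j] = row currently matched to column j (0 = free)

  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- m + 1L        # current column in the alternating tree
    minv <- rep(Inf, m)
    way <- integer(m)
    used <- logical(m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free_j <- which(!used[seq_len(m)])
      red <- a[i0, free_j] - u[i0] - v[free_j]
      upd <- red < minv[free_j]
      if (any(upd)) {
        minv[free_j[upd]] <- red[upd]
        way[free_j[upd]] <- j0
      }
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      used_j <- which(used)
      u[p[used_j]] <- u[p[used_j]] + delta
      v[used_j] <- v[used_j] - delta
      minv[free_j] <- minv[free_j] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    # augment along the stored alternating path
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }

  res <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j] > 0L) res[p[j]] <- j
  # rows stuck on a forbidden link are unassigned
  bad <- which(!is.na(res) & cost[cbind(seq_len(n), res)] >= big)
  if (length(bad)) res[bad] <- NA_integer_
  # also rows whose chosen entry was Inf originally
  chosen <- which(!is.na(res))
  if (length(chosen)) {
    inf_pick <- chosen[!is.finite(cost[cbind(chosen, res[chosen])])]
    if (length(inf_pick)) res[inf_pick] <- NA_integer_
  }
  res
}

#' One-to-one matching with a per-link cost cap
#'
#' Rows may remain unmatched: each row is given a private dummy column whose
#' cost is `max_cost`, so any real link costing more than `max_cost` is
#' rejected in favour of "no match". The result minimizes total cost among
#' all one-to-one matchings under the cap.
#'
#' @param cost numeric `n x m` matrix (any shape); `Inf` forbids a link.
#' @param max_cost scalar; links with cost `> max_cost` are never made.
#' @return integer vector of length `n`: matched column index or `NA`.
#' @keywords internal
match_one_to_one <- function(cost, max_cost = Inf) {
  if (!is.matrix(cost)) cost <- as.matrix(cost)
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0L) return(integer(0))
  if (m == 0L) return(rep(NA_integer_, n))
  aug <- cost
  aug[aug > max_cost] <- Inf
  if (is.finite(max_cost)) {
    dummy <- matrix(Inf, n, n)
    diag(dummy) <- max_cost
    aug <- cbind(aug, dummy)
  } else if (m < n) {
    aug <- cbind(aug, matrix(max(cost[is.finite(cost)], 0) + 1, n, n))
  }
  res <- solve_assignment(aug)
  res[!is.na(res) & res > m] <- NA_integer_
  res
}

#' Brute-force assignment by permutation enumeration
#'
#' Independent oracle used in tests; exponential, only for tiny problems.
#' @keywords internal
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m, m <= 8)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v)) {
      for (p in perms(v[-k])) out[[length(out) + 1L]] <- c(v[k], p)
    }
    out
  }
  best <- NULL
  best_cost <- Inf
  for (p in perms(seq_len(m))) {
    sel <- p[seq_len(n)]
    cc <- sum(cost[cbind(seq_len(n), sel)])
    if (cc < best_cost) {
      best_cost <- cc
      best <- sel
    }
  }
  list(assignment = best, cost = best_cost)
}
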