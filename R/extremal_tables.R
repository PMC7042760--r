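# Reference integer allocations and contingency tables that anchor the
# normalization of d' and H2'. All heuristics are deterministic (largest
# remainder; index-order tie-breaks) and are polished by an exhaustive
# unit-transfer local search on small problems, where they provably reach
# the integer optimum (the objectives are separable and, for 2 x n tables,
# every marginal-preserving cycle is a 2 x 2 swap).

# Largest-remainder allocation of `total` integer events across cells
# proportionally to weights w (sums to `total` exactly).
largest_remainder <- function(total, w) {
  expected <- total * w / sum(w)
  alloc <- floor(expected)
  left <- total - sum(alloc)
  if (left > 0) {
    ord <- order(expected - alloc, seq_along(w), decreasing = c(TRUE, FALSE),
      method = "radix"
    )
    alloc[ord[seq_len(left)]] <- alloc[ord[seq_len(left)]] + 1
  }
  alloc
}

# KL divergence of an integer allocation `a` (partner-use counts) against
# availabilities q; the d statistic for a hypothetical species.
kl_alloc <- function(a, q) {
  A <- sum(a)
  nz <- a > 0
  sum((a[nz] / A) * log((a[nz] / A) / q[nz]))
}

# Most generalized achievable integer allocation of A events across partners
# with availabilities q: largest-remainder start, then unit-exchange descent.
# KL is separable convex in the allocation, so the descent terminates at the
# global integer minimum.
min_kl_allocation <- function(A, q) {
  a <- largest_remainder(A, q)
  k <- length(q)
  if (k == 1) {
    return(a)
  }
  repeat {
    best <- kl_alloc(a, q)
    best_move <- NULL
    for (from in seq_len(k)) {
      if (a[from] == 0) next
      for (to in seq_len(k)) {
        if (to == from) next
        cand <- a
        cand[from] <- cand[from] - 1
        cand[to] <- cand[to] + 1
        val <- kl_alloc(cand, q)
        if (val < best - 1e-12) {
          best <- val
          best_move <- cand
        }
      }
    }
    if (is.null(best_move)) {
      return(a)
    }
    a <- best_move
  }
}

# Greedy most-heterogeneous table with the given marginals: repeatedly place
# min(remaining row, remaining col) into the cell pairing the largest
# remaining row and column totals (ties by index order).
greedy_min_entropy_table <- function(r, c) {
  a <- matrix(0, length(r), length(c))
  rr <- r
  cc <- c
  while (sum(rr) > 0) {
    i <- which.max(rr)
    j <- which.max(cc)
    x <- min(rr[i], cc[j])
    a[i, j] <- a[i, j] + x
    rr[i] <- rr[i] - x
    cc[j] <- cc[j] - x
  }
  a
}

# Most-even table heuristic: floor of expected values r_i c_j / m, then the
# leftover units go one by one to the feasible cell with the largest
# remainder (ties by index order).
even_entropy_table <- function(r, c) {
  m <- sum(r)
  expected <- outer(r, c) / m
  a <- floor(expected)
  rr <- r - rowSums(a)
  cc <- c - colSums(a)
  while (sum(rr) > 0) {
    feas <- outer(rr > 0, cc > 0)
    rem <- expected - a
    rem[!feas] <- -Inf
    idx <- which(rem == max(rem), arr.ind = TRUE)[1, ]
    a[idx[1], idx[2]] <- a[idx[1], idx[2]] + 1
    rr[idx[1]] <- rr[idx[1]] - 1
    cc[idx[2]] <- cc[idx[2]] - 1
  }
  a
}

# Unit-transfer local search over 2x2 cycles (a[i,j]-1, a[i,j']+1,
# a[i',j']-1, a[i',j]+1), improving `direction * entropy`. Applied only to
# small tables; the construction heuristics stand alone on larger ones.
refine_entropy_table <- function(a, direction, max_cells = 36,
                                 max_iter = 200) {
  nr <- nrow(a)
  nc <- ncol(a)
  if (nr * nc > max_cells || nr < 2 || nc < 2) {
    return(a)
  }
  for (iter in seq_len(max_iter)) {
    best <- direction * shannon_entropy(a)
    best_move <- NULL
    for (i in seq_len(nr - 1)) {
      for (ip in (i + 1):nr) {
        for (j in seq_len(nc)) {
          for (jp in seq_len(nc)) {
            if (j == jp) next
            if (a[i, j] == 0 || a[ip, jp] == 0) next
            cand <- a
            cand[i, j] <- cand[i, j] - 1
            cand[i, jp] <- cand[i, jp] + 1
            cand[ip, jp] <- cand[ip, jp] - 1
            cand[ip, j] <- cand[ip, j] + 1
            val <- direction * shannon_entropy(cand)
            if (val > best + 1e-12) {
              best <- val
              best_move <- cand
            }
          }
        }
      }
    }
    if (is.null(best_move)) {
      return(a)
    }
    a <- best_move
  }
  a
}

max_entropy_table <- function(r, c) {
  refine_entropy_table(even_entropy_table(r, c), direction = 1)
}

# Entropy is concave, so its minimum over the transportation polytope sits
# at a vertex; every vertex arises from the saturating greedy rule (place
# min(remaining row, remaining col), drop the exhausted line) under some
# cell order. On small matrices we therefore search all vertices exactly by
# memoized recursion over the remaining-marginal states; larger matrices
# use the single largest-pairing greedy vertex polished by unit transfers.
min_entropy_table <- function(r, c, exact_max_cells = 9) {
  if (length(r) * length(c) <= exact_max_cells) {
    return(min_entropy_vertex_search(r, c))
  }
  refine_entropy_table(greedy_min_entropy_table(r, c), direction = -1)
}

min_entropy_vertex_search <- function(r, c) {
  m <- sum(r)
  memo <- new.env(parent = emptyenv())
  cell_value <- function(x) if (x == 0) 0 else -(x / m) * log(x / m)
  solve <- function(rr, cc) {
    key <- paste(c(rr, "|", cc), collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    active_r <- which(rr > 0)
    active_c <- which(cc > 0)
    if (length(active_r) == 0) {
      res <- list(value = 0, cell = NULL, amount = NULL)
      memo[[key]] <- res
      return(res)
    }
    best <- NULL
    for (i in active_r) {
      for (j in active_c) {
        x <- min(rr[i], cc[j])
        rr2 <- rr
        cc2 <- cc
        rr2[i] <- rr2[i] - x
        cc2[j] <- cc2[j] - x
        sub <- solve(rr2, cc2)
        val <- cell_value(x) + sub$value
        if (is.null(best) || val < best$value - 1e-12) {
          best <- list(value = val, cell = c(i, j), amount = x)
        }
      }
    }
    memo[[key]] <- best
    best
  }
  a <- matrix(0, length(r), length(c))
  rr <- r
  cc <- c
  repeat {
    step <- solve(rr, cc)
    if (is.null(step$cell)) break
    i <- step$cell[1]
    j <- step$cell[2]
    a[i, j] <- a[i, j] + step$amount
    rr[i] <- rr[i] - step$amount
    cc[j] <- cc[j] - step$amount
  }
  a
}
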