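# Independent brute-force oracles used to validate the heuristic reference
# tables and pairwise metrics. These deliberately share no code with the
# package implementations.

# All nonnegative integer matrices with the given row and column sums.
enumerate_tables <- function(r, c) {
  out <- list()
  recurse <- function(row_idx, remaining_cols, acc) {
    if (row_idx > length(r)) {
      if (all(remaining_cols == 0)) out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    fill_row <- function(col_idx, left, row_acc) {
      if (col_idx > length(c)) {
        if (left == 0) {
          recurse(
            row_idx + 1,
            remaining_cols - row_acc,
            rbind(acc, row_acc)
          )
        }
        return(invisible())
      }
      for (v in 0:min(left, remaining_cols[col_idx])) {
        fill_row(col_idx + 1, left - v, c(row_acc, v))
      }
    }
    fill_row(1, r[row_idx], numeric(0))
  }
  recurse(1, c, NULL)
  lapply(out, function(m) {
    m <- matrix(m, length(r), length(c), byrow = FALSE)
    dimnames(m) <- NULL
    m
  })
}

# All allocations of `total` units across k cells.
enumerate_allocations <- function(total, k) {
  if (k == 1) {
    return(list(total))
  }
  out <- list()
  for (v in 0:total) {
    for (rest in enumerate_allocations(total - v, k - 1)) {
      out[[length(out) + 1]] <- c(v, rest)
    }
  }
  out
}

entropy_oracle <- function(m) {
  p <- m[m > 0] / sum(m)
  -sum(p * log(p))
}

kl_oracle <- function(alloc, q) {
  A <- sum(alloc)
  i <- alloc > 0
  sum((alloc[i] / A) * log((alloc[i] / A) / q[i]))
}

# Definitional WNODF evaluator, written against the pairwise rule from
# first principles with utils::combn.
wnodf_oracle <- function(mat) {
  mat <- mat[order(rowSums(mat), decreasing = TRUE), , drop = FALSE]
  mat <- mat[, order(colSums(mat), decreasing = TRUE), drop = FALSE]
  score_pairs <- function(vectors) {
    totals <- vapply(vectors, sum, numeric(1))
    pairs <- utils::combn(length(vectors), 2)
    apply(pairs, 2, function(idx) {
      u <- vectors[[idx[1]]]
      v <- vectors[[idx[2]]]
      if (sum(v) >= sum(u)) {
        return(0)
      }
      filled <- which(v > 0)
      100 * mean(v[filled] < u[filled])
    })
  }
  rows <- lapply(seq_len(nrow(mat)), function(i) mat[i, ])
  cols <- lapply(seq_len(ncol(mat)), function(j) mat[, j])
  mean(c(score_pairs(rows), score_pairs(cols)))
}

# Random integer matrix without all-zero rows or columns.
random_count_matrix <- function(nr, nc, max_count = 6) {
  repeat {
    m <- matrix(sample(0:max_count, nr * nc, replace = TRUE), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      return(m)
    }
  }
}

# Simple record tibble for assembly tests.
toy_records <- function() {
  tibble::tibble(
    site_id = c("s1", "s1", "s1", "s1", "s2"),
    walk_id = c("w1", "w1", "w1", "w2", "w3"),
    plant_taxon = c("P1", "P2", "P1", "P1", "P9"),
    pollinator_taxon = c("B1", "B1", "F1", "B1", "B2"),
    pollinator_group = c("bee", "bee", "other", "bee", "wasp"),
    count = c(2, 1, 4, 1, 6)
  )
}

small_study <- function(seed = 1, a1 = 0.14) {
  generate_study(study_config(
    n_sites = 8, plant_pool = 50, pollinator_pool = 60,
    a1 = a1, seed = seed
  ))
}
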