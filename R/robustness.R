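#' Secondary-extinction curve of a network
#'
#' Removes species of one trophic level one at a time in the given order
#' (setting all their interactions to zero) and records, after each removal,
#' the fraction of species at the other level that still have at least one
#' interaction left. The curve is on normalized axes and always runs from
#' (0, 1) to (1, 0).
#'
#' @param net A [quant_network()].
#' @param level_removed `"pollinator"` or `"plant"`: the level subjected to
#'   primary extinctions.
#' @param order Permutation (indices or species names) of the species at
#'   `level_removed`.
#' @return Tibble with columns `fraction_removed`, `fraction_surviving`.
#' @export
#' @examples
#' extinction_curve(quant_network(diag(3) + 0), "plant", 1:3)
extinction_curve <- function(net, level_removed = c("pollinator", "plant"),
                             order) {
  level_removed <- match.arg(level_removed)
  a <- unclass(net)
  if (level_removed == "plant") a <- t(a) # removed level on columns
  if (is.character(order)) order <- match(order, colnames(a))
  n <- ncol(a)
  if (!setequal(order, seq_len(n))) {
    abort("order must be a permutation of the species at level_removed.")
  }
  surv <- survivor_counts(a, order)
  tibble::tibble(
    fraction_removed = (0:n) / n,
    fraction_surviving = surv / nrow(a)
  )
}

# Number of surviving row species after 0..n column removals in `order`.
# A row survives step k iff at least one of its nonzero columns is removed
# later than k; that threshold is the max removal position over the row's
# partners.
survivor_counts <- function(a, order) {
  n <- ncol(a)
  pos <- integer(n)
  pos[order] <- seq_len(n)
  last_partner <- apply(a, 1, function(row) max(pos[row > 0]))
  vapply(0:n, function(k) sum(last_partner > k), numeric(1))
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Robustness to random species loss
#'
#' Robustness `R` is the area under the secondary-extinction survivor curve
#' (trapezoidal rule on normalized axes, endpoints (0,1) and (1,0)
#' included), averaged over `n_orders` uniformly random removal orders.
#' `R = 1` would mean no secondary loss until the very end; the identity
#' matrix gives exactly 0.5 and a fully connected network with `p` removable
#' species gives `1 - 1/(2p)`.
#'
#' @inheritParams extinction_curve
#' @param n_orders Number of random removal orders averaged (default 100).
#' @param seed Study-level seed; the per-network stream is derived from it.
#' @return An `extinction_result`: list with `R`, `se` (Monte-Carlo standard
#'   error), `curve` (mean survivor curve), `level_removed`, `n_orders`,
#'   `walk_id`, `seed`.
#' @export
robustness <- function(net, level_removed = c("pollinator", "plant"),
                       n_orders = 100, seed = 1) {
  level_removed <- match.arg(level_removed)
  a <- unclass(net)
  if (level_removed == "plant") a <- t(a)
  n <- ncol(a)
  stream <- derive_seed(seed, c("robustness", level_removed, attr(net, "walk_id")))
  sims <- with_seed(stream, {
    purrr::map(seq_len(n_orders), function(i) {
      ord <- if (n == 1) 1L else sample.int(n)
      survivor_counts(a, ord) / nrow(a)
    })
  })
  x <- (0:n) / n
  areas <- purrr::map_dbl(sims, function(y) trapezoid_area(x, y))
  mean_curve <- Reduce(`+`, sims) / n_orders
  structure(
    list(
      R = mean(areas),
      se = if (n_orders > 1) sd(areas) / sqrt(n_orders) else NA_real_,
      curve = tibble::tibble(
        fraction_removed = x, fraction_surviving = mean_curve
      ),
      level_removed = level_removed, n_orders = n_orders,
      walk_id = attr(net, "walk_id"), seed = seed
    ),
    class = "extinction_result"
  )
}

#' @export
print.extinction_result <- function(x, ...) {
  cat("<extinction_result> walk ", x$walk_id, ", removing ",
    x$level_removed, "s: R = ", signif(x$R, 4), " (MC se ",
    signif(x$se, 3), ", ", x$n_orders, " orders)\n",
    sep = ""
  )
  invisible(x)
}

#' Null-standardized robustness
#'
#' z-score of robustness `R` against Patefield null networks with the same
#' marginals, each null's `R` computed with the same number of random
#' removal orders — the "standardized robustness" consumed by the gradient
#' stage.
#'
#' @inheritParams robustness
#' @param n_null Number of null networks.
#' @return A `null_ensemble`.
#' @export
standardized_robustness <- function(net, level_removed = c("pollinator", "plant"),
                                    n_orders = 100, n_null = 1000, seed = 1) {
  level_removed <- match.arg(level_removed)
  standardize_metric(
    net,
    function(x) robustness(x, level_removed, n_orders, seed)$R,
    n_null = n_null, seed = seed,
    metric_name = paste0("robustness_", level_removed)
  )
}
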