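#' Quantitative bipartite interaction network
#'
#' A `quant_network` is an integer plant x pollinator interaction matrix with
#' labelled rows (plants, the lower trophic level) and columns (pollinators,
#' the higher trophic level). Cell `a[i, j]` counts interaction events between
#' plant `i` and pollinator `j`. Row totals, column totals and the grand total
#' `m` are available through [row_totals()], [col_totals()] and
#' [grand_total()]. Matrices never contain an all-zero row or column: a
#' species with no interactions is not part of the network.
#'
#' @param a Nonnegative integer matrix with unique row and column names.
#' @param walk_id,site_id Optional identifiers carried as attributes.
#'
#' @return An object of class `quant_network` (an integer matrix).
#' @export
#' @examples
#' quant_network(matrix(c(2, 1, 0, 3), 2, 2,
#'   dimnames = list(c("P1", "P2"), c("B1", "B2"))
#' ))
quant_network <- function(a, walk_id = NA_character_, site_id = NA_character_) {
  a <- as.matrix(a)
  if (any(a < 0) || any(a != round(a))) {
    abort("Interaction matrix must contain nonnegative integers.")
  }
  if (is.null(rownames(a))) rownames(a) <- paste0("P", seq_len(nrow(a)))
  if (is.null(colnames(a))) colnames(a) <- paste0("A", seq_len(ncol(a)))
  if (any(rowSums(a) == 0) || any(colSums(a) == 0)) {
    abort("Interaction matrix must not contain all-zero rows or columns.")
  }
  storage.mode(a) <- "double"
  structure(a,
    walk_id = walk_id, site_id = site_id,
    class = c("quant_network", class(a))
  )
}

#' @export
print.quant_network <- function(x, ...) {
  cat(
    "<quant_network> walk ", attr(x, "walk_id"), ": ",
    nrow(x), " plants x ", ncol(x), " pollinators, m = ",
    grand_total(x), "\n",
    sep = ""
  )
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Marginal totals of a quantitative network
#'
#' @param net A [quant_network()].
#' @return `row_totals()` and `col_totals()` return named numeric vectors of
#'   per-species interaction totals (`A_i`, `A_j`); `grand_total()` returns
#'   the total number of interaction events `m`.
#' @export
row_totals <- function(net) rowSums(unclass(net))

#' @rdname row_totals
#' @export
col_totals <- function(net) colSums(unclass(net))

#' @rdname row_totals
#' @export
grand_total <- function(net) sum(unclass(net))

#' Matrix size of a network
#'
#' The product of the number of plant and pollinator species; the gradient
#' stage analyses its natural logarithm.
#'
#' @param net A [quant_network()].
#' @return A positive integer.
#' @export
matrix_size <- function(net) nrow(net) * ncol(net)

species_at_level <- function(net, level = c("pollinator", "plant")) {
  level <- match.arg(level)
  if (level == "plant") rownames(net) else colnames(net)
}
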