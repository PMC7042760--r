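# Piecewise path analysis: a DAG of component mixed models, a d-separation
# basis set, Fisher's C goodness of fit, and AICc search over path
# combinations. Component models use a random site intercept (ordinary
# least squares as fallback when no grouping is available).

#' Declare a piecewise path (SEM) model
#'
#' @param edges Tibble/data frame with columns `from`, `to` and optionally
#'   `optional` (logical; optional edges are toggled by
#'   [exhaustive_path_search()]).
#' @param nodes Character vector of variables; defaults to those appearing
#'   in `edges`. Extra (isolated) nodes add independence claims.
#' @return A `sem_model`: list with `nodes`, `edges` and the deterministic
#'   topological `order` (declared node order used for tie-breaks).
#' @export
#' @examples
#' sem_model(tibble::tibble(from = c("A", "B"), to = c("B", "C")))
sem_model <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (!"optional" %in% names(edges)) edges$optional <- FALSE
  nodes <- nodes %||% unique(c(edges$from, edges$to))
  if (!all(c(edges$from, edges$to) %in% nodes)) {
    abort("All edge endpoints must be listed in nodes.")
  }
  order <- topological_order(nodes, edges)
  structure(
    list(nodes = nodes, edges = edges, order = order),
    class = "sem_model"
  )
}

topological_order <- function(nodes, edges) {
  remaining <- nodes
  ord <- character(0)
  e <- edges
  while (length(remaining) > 0) {
    indeg0 <- remaining[!remaining %in% e$to[e$from %in% remaining]]
    if (length(indeg0) == 0) {
      abort("Path model graph contains a cycle.")
    }
    nxt <- indeg0[1] # declared order breaks ties deterministically
    ord <- c(ord, nxt)
    remaining <- setdiff(remaining, nxt)
    e <- e[e$from != nxt, , drop = FALSE]
  }
  ord
}

parents_of <- function(model, node) {
  model$edges$from[model$edges$to == node]
}

#' d-separation basis set of a path model
#'
#' One independence claim per non-adjacent pair of variables: the variable
#' later in the (deterministic) topological order is regressed on the
#' earlier one plus the later variable's parents; under the causal graph
#' the earlier variable's partial coefficient is zero (local Markov
#' property). Claims are returned in a fixed order.
#'
#' @param model A [sem_model()].
#' @return Tibble with columns `response`, `predictor`, `conditioning`
#'   (list-column).
#' @export
basis_set <- function(model) {
  ord <- model$order
  adj <- paste(model$edges$from, model$edges$to)
  claims <- list()
  for (i in seq_along(ord)) {
    for (j in seq_along(ord)) {
      if (j <= i) next
      u <- ord[i]
      v <- ord[j]
      if (paste(u, v) %in% adj || paste(v, u) %in% adj) next
      claims[[length(claims) + 1]] <- tibble::tibble(
        response = v, predictor = u,
        conditioning = list(setdiff(parents_of(model, v), u))
      )
    }
  }
  dplyr::bind_rows(c(list(tibble::tibble(
    response = character(), predictor = character(), conditioning = list()
  )), claims))
}

#' Fisher's C statistic
#'
#' Combines the p-values of the k independence claims of a basis set:
#' `C = -2 sum(ln p_i)`, chi-square distributed with `2k` degrees of
#' freedom when the causal structure is correct; `p_C > .05` indicates the
#' structure is compatible with the data. An empty basis set gives `C = 0`,
#' `p_C = 1`.
#'
#' @param p Vector of claim p-values in `(0, 1]`.
#' @return Tibble: `C`, `df`, `p_C`.
#' @export
#' @examples
#' fishers_c(c(0.5, 0.5)) # C = 2.7726, df = 4
fishers_c <- function(p) {
  if (length(p) == 0) {
    return(tibble::tibble(C = 0, df = 0L, p_C = 1))
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("Claim p-values must lie in (0, 1].")
  }
  C <- -2 * sum(log(p))
  df <- 2L * length(p)
  tibble::tibble(C = C, df = df, p_C = pchisq(C, df, lower.tail = FALSE))
}

# One component regression: response ~ predictors (+ random site
# intercept). Falls back to OLS when no usable grouping exists.
component_fit <- function(data, response, predictors, group) {
  rhs <- if (length(predictors) == 0) "1" else paste(predictors, collapse = " + ")
  use_lme <- !is.null(group) && group %in% names(data) &&
    dplyr::n_distinct(data[[group]]) >= 2
  if (use_lme) {
    fit <- tryCatch(
      nlme::lme(
        fixed = as.formula(paste(response, "~", rhs)),
        random = as.formula(paste0("~ 1 | ", group)),
        data = as.data.frame(data), method = "REML",
        control = nlme::lmeControl(opt = "optim", returnObject = TRUE)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      tt <- summary(fit)$tTable
      vc <- suppressWarnings(as.numeric(nlme::VarCorr(fit)["(Intercept)", "StdDev"]))
      var_b <- vc^2
      var_e <- fit$sigma^2
      X <- stats::model.matrix(stats::formula(fit), data = fit$data)
      var_f <- var(as.numeric(X %*% nlme::fixef(fit)))
      tot <- var_f + var_b + var_e
      return(list(
        coefs = tibble::tibble(
          response = response, term = rownames(tt),
          estimate = unname(tt[, "Value"]),
          std_error = unname(tt[, "Std.Error"]),
          statistic = unname(tt[, "t-value"]),
          p_value = unname(tt[, "p-value"])
        ),
        k = nrow(tt) + 2, ll_ml = NA_real_,
        r2_marginal = var_f / tot, r2_conditional = (var_f + var_b) / tot,
        engine = "lme"
      ))
    }
  }
  fit <- lm(as.formula(paste(response, "~", rhs)), data = data)
  cf <- summary(fit)$coefficients
  var_f <- var(stats::fitted(fit))
  tot <- var_f + summary(fit)$sigma^2
  list(
    coefs = tibble::tibble(
      response = response, term = rownames(cf),
      estimate = unname(cf[, 1]), std_error = unname(cf[, 2]),
      statistic = unname(cf[, 3]), p_value = unname(cf[, 4])
    ),
    k = nrow(cf) + 1, ll_ml = NA_real_,
    r2_marginal = var_f / tot, r2_conditional = var_f / tot,
    engine = "lm"
  )
}

#' Fit a piecewise path model
#'
#' All model variables are z-transformed, each endogenous node is fit on
#' its parents with a random site intercept, every basis-set claim is
#' tested, and the model is scored by Fisher's C and the small-sample
#' information criterion `AICc = C + 2 K n / (n - K - 1)`, where `K` counts
#' all estimated parameters (fixed coefficients including intercepts plus
#' random-effect and residual variances) across component models and `n` is
#' the number of complete observations.
#'
#' @param model A [sem_model()].
#' @param data Tibble holding every model variable (and the grouping
#'   column).
#' @param group Grouping column for the random intercept (default
#'   `"site_id"`; set `NULL` for plain OLS components).
#' @return A `sem_result`: path coefficients, claims with p-values, `C`,
#'   `df`, `p_C`, `K`, `n`, `AICc`, per-node R2.
#' @export
sem_fit <- function(model, data, group = "site_id") {
  vars <- model$nodes
  keep_cols <- c(vars, if (!is.null(group) && group %in% names(data)) group)
  data <- data[stats::complete.cases(data[, keep_cols]), keep_cols, drop = FALSE]
  n <- nrow(data)
  for (v in vars) data[[v]] <- zscore(data[[v]])
  endogenous <- unique(model$edges$to)
  comps <- purrr::map(endogenous, function(v) {
    component_fit(data, v, parents_of(model, v), group)
  })
  coefs <- dplyr::bind_rows(purrr::map(comps, "coefs"))
  K <- sum(purrr::map_dbl(comps, "k"))
  if (n <= K + 1) {
    abort(paste0(
      "AICc undefined: n = ", n, " observations for K = ", K, " parameters."
    ))
  }
  claims <- basis_set(model)
  claim_p <- purrr::map_dbl(seq_len(nrow(claims)), function(i) {
    preds <- c(claims$predictor[i], claims$conditioning[[i]])
    cf <- component_fit(data, claims$response[i], preds, group)$coefs
    p <- cf$p_value[cf$term == claims$predictor[i]]
    max(p, .Machine$double.xmin) # guard against exact zeros
  })
  claims$p_value <- claim_p
  fc <- fishers_c(claim_p)
  aicc <- fc$C + 2 * K * n / (n - K - 1)
  r2 <- tibble::tibble(
    node = endogenous,
    r2_marginal = purrr::map_dbl(comps, "r2_marginal"),
    r2_conditional = purrr::map_dbl(comps, "r2_conditional")
  )
  structure(
    list(
      model = model, coefficients = coefs, claims = claims,
      C = fc$C, df = fc$df, p_C = fc$p_C, K = K, n = n, AICc = aicc,
      r2 = r2
    ),
    class = "sem_result"
  )
}

#' @export
print.sem_result <- function(x, ...) {
  cat("<sem_result> ", nrow(x$model$edges), " paths, ", nrow(x$claims),
    " independence claims; Fisher's C = ", signif(x$C, 4), " (df = ",
    x$df, ", p = ", signif(x$p_C, 3), "), K = ", x$K, ", n = ", x$n,
    ", AICc = ", signif(x$AICc, 5), "\n",
    sep = ""
  )
  path_coefs <- x$coefficients[x$coefficients$term != "(Intercept)", ]
  print(as.data.frame(path_coefs), digits = 3)
  invisible(x)
}

#' @method tidy sem_result
#' @export
tidy.sem_result <- function(x, ...) {
  x$coefficients[x$coefficients$term != "(Intercept)", ]
}

#' @method glance sem_result
#' @export
glance.sem_result <- function(x, ...) {
  tibble::tibble(
    C = x$C, df = x$df, p_C = x$p_C, K = x$K, n = x$n, AICc = x$AICc
  )
}

#' Exhaustive AICc search over optional path combinations
#'
#' Evaluates every subset of the model's optional edges (mandatory edges
#' always included), ranks the resulting path models by AICc and reports
#' the difference to the best model. Ties within `delta < 0.01` share the
#' top rank. At most 12 optional edges (4096 models) are allowed.
#'
#' @param model A [sem_model()] with at least one edge flagged
#'   `optional = TRUE`.
#' @inheritParams sem_fit
#' @return Tibble ranked by AICc: `rank`, `edges_included`, `AICc`,
#'   `delta_aicc`, `C`, `p_C`, `K`, and the fitted `sem_result`s as a list
#'   column `fit`.
#' @export
exhaustive_path_search <- function(model, data, group = "site_id") {
  opt <- which(model$edges$optional)
  if (length(opt) > 12) {
    abort("More than 12 optional edges; preselect variables first.")
  }
  subsets <- if (length(opt) == 0) {
    list(integer(0))
  } else {
    purrr::map(
      0:(2^length(opt) - 1),
      function(mask) opt[bitwAnd(mask, 2^(seq_along(opt) - 1)) > 0]
    )
  }
  rows <- purrr::map(subsets, function(inc) {
    keep <- sort(c(which(!model$edges$optional), inc))
    sub <- sem_model(model$edges[keep, , drop = FALSE], nodes = model$nodes)
    fit <- sem_fit(sub, data, group)
    tibble::tibble(
      edges_included = paste(
        paste0(sub$edges$from, "->", sub$edges$to),
        collapse = "; "
      ),
      n_edges = nrow(sub$edges), AICc = fit$AICc, C = fit$C, p_C = fit$p_C,
      K = fit$K, fit = list(fit)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$AICc, .data$n_edges)
  out$delta_aicc <- out$AICc - out$AICc[1]
  out$rank <- cumsum(c(1, diff(out$AICc) >= 0.01))
  dplyr::relocate(out, "rank", "edges_included", "AICc", "delta_aicc")
}

#' AICc-based variable preselection within and across hypothesis blocks
#'
#' Within each hypothesis block (e.g. resources = flower abundance and
#' richness; pollinators = richness and visitation rate; temperature = MAT
#' and ACT; area), every subset of the block's variables is scored by the
#' ML AICc of a mixed model of the response on the subset (random site
#' intercept); the best subset advances. A second exhaustive pass over the
#' union of the advanced variables gives the final selection.
#'
#' @param data Tibble with the response, candidate variables and grouping
#'   column; variables are z-transformed internally.
#' @param response Name of the response column.
#' @param blocks Named list of character vectors (hypothesis blocks).
#' @param group Grouping column.
#' @return List with `selected` (character vector), `within` (per-block
#'   winner table) and `across` (final pass table).
#' @export
preselect_variables <- function(data, response, blocks, group = "site_id") {
  vars <- unique(unlist(blocks))
  keep <- stats::complete.cases(data[, c(response, vars, group)])
  data <- data[keep, , drop = FALSE]
  for (v in c(response, vars)) data[[v]] <- zscore(data[[v]])
  score_subset <- function(subset) {
    fit <- fit_lme_containment(data, response, subset, group, method = "ML")
    aicc_from_ll(logLik(fit), length(nlme::fixef(fit)) + 2, nrow(data))
  }
  best_subset <- function(cands) {
    subsets <- purrr::map(
      0:(2^length(cands) - 1),
      function(mask) cands[bitwAnd(mask, 2^(seq_along(cands) - 1)) > 0]
    )
    scores <- purrr::map_dbl(subsets, score_subset)
    tibble::tibble(
      subset = purrr::map_chr(subsets, ~ paste(.x, collapse = "+")),
      vars = subsets, aicc = scores
    ) |> dplyr::arrange(.data$aicc)
  }
  within <- purrr::imap(blocks, function(vars_b, name) {
    if (length(vars_b) == 0) {
      return(NULL)
    }
    tab <- best_subset(vars_b)
    tab$block <- name
    tab
  })
  advanced <- unique(unlist(purrr::map(within, ~ .x$vars[[1]])))
  across <- best_subset(advanced)
  list(
    selected = across$vars[[1]],
    within = dplyr::bind_rows(within),
    across = across
  )
}
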