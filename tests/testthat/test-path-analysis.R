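chain_model <- function() {
  sem_model(tibble::tibble(from = c("A", "B"), to = c("B", "C")))
}

test_that("basis sets enumerate exactly the non-adjacent pairs", {
  bs <- basis_set(chain_model())
  expect_equal(nrow(bs), 1)
  expect_equal(bs$response, "C")
  expect_equal(bs$predictor, "A")
  expect_equal(bs$conditioning[[1]], "B")

  saturated <- sem_model(tibble::tibble(
    from = c("A", "A", "B"), to = c("B", "C", "C")
  ))
  expect_equal(nrow(basis_set(saturated)), 0)

  # 4-node DAG: A -> B -> D, A -> C; hand-enumerated claims
  dag <- sem_model(tibble::tibble(
    from = c("A", "B", "A"), to = c("B", "D", "C")
  ))
  bs4 <- basis_set(dag)
  claims <- paste(bs4$response, "indep", bs4$predictor, "given",
    vapply(bs4$conditioning, paste, "", collapse = ","),
    sep = " "
  )
  expect_setequal(claims, c(
    "D indep A given B",
    "C indep B given A",
    "C indep D given A" # D before C? order follows declaration: B, D before C
  ))
  expect_error(
    sem_model(tibble::tibble(from = c("A", "B"), to = c("B", "A"))),
    "cycle"
  )
})

test_that("Fisher's C combines claim p-values as -2 sum log p", {
  expect_equal(fishers_c(numeric(0)), tibble::tibble(C = 0, df = 0L, p_C = 1))
  expect_equal(fishers_c(c(1, 1))$C, 0)
  expect_equal(fishers_c(c(1, 1))$p_C, 1)
  fc <- fishers_c(c(0.5, 0.5))
  expect_equal(fc$C, 2.7726, tolerance = 1e-4)
  expect_equal(fc$df, 4L)
  expect_error(fishers_c(c(0.5, 0)), "0, 1")
  # additivity over a split basis set
  p <- c(0.2, 0.7, 0.4, 0.9)
  expect_equal(
    fishers_c(p)$C,
    fishers_c(p[1:2])$C + fishers_c(p[3:4])$C
  )
})

simulate_dag_data <- function(n = 60, b_direct = 0.6, b_fr = 0.4,
                              b_fa = 0.5, seed = 1, sites = 12) {
  withr::with_seed(seed, {
    site <- sprintf("s%02d", sample(sites, n, replace = TRUE))
    mat <- rnorm(n)
    log_fa <- rnorm(n)
    fr <- b_fr * mat + b_fa * log_fa + rnorm(n, 0, 0.7)
    dp <- b_direct * mat + 0.3 * fr + rnorm(n, 0, 0.6)
    tibble::tibble(
      site_id = site, MAT = mat, log_flower_abundance = log_fa,
      flower_richness = fr, mean_dprime_pollinators = dp
    )
  })
}

fig_model <- function(optional = c(FALSE, FALSE, TRUE, TRUE)) {
  sem_model(tibble::tibble(
    from = c("MAT", "log_flower_abundance", "MAT", "flower_richness"),
    to = c(
      "flower_richness", "flower_richness",
      "mean_dprime_pollinators", "mean_dprime_pollinators"
    ),
    optional = optional
  ))
}

test_that("piecewise fits recover simulated path structure and score AICc", {
  d <- simulate_dag_data(seed = 3)
  fit <- sem_fit(fig_model(rep(FALSE, 4)), d)
  paths <- tidy(fit)
  direct <- paths[paths$response == "mean_dprime_pollinators" &
    paths$term == "MAT", ]
  expect_gt(direct$estimate, 0)
  expect_lt(direct$p_value, 0.05)
  fr_path <- paths[paths$response == "flower_richness" & paths$term == "MAT", ]
  expect_gt(fr_path$estimate, 0)
  # AICc identity and glance contract
  g <- glance(fit)
  expect_equal(g$AICc, g$C + 2 * g$K * g$n / (g$n - g$K - 1))
  expect_true(all(fit$r2$r2_marginal >= 0 & fit$r2$r2_conditional <= 1))
  # AICc small-sample arithmetic: C = 2.77, K = 3, n = 62 -> 9.18
  expect_equal(2.77 + 2 * 3 * 62 / (62 - 3 - 1), 9.1838, tolerance = 1e-3)
  # too few observations for the parameter count
  expect_error(sem_fit(fig_model(rep(FALSE, 4)), d[1:8, ]), "AICc undefined")
})

test_that("the exhaustive search ranks all optional-path combinations", {
  d <- simulate_dag_data(seed = 5)
  search <- exhaustive_path_search(fig_model(), d)
  expect_equal(nrow(search), 4) # two optional edges
  expect_equal(search$delta_aicc[1], 0)
  expect_true(grepl("MAT->mean_dprime_pollinators", search$edges_included[1]))
  # removing the true direct path costs support
  without <- search[!grepl("MAT->mean_dprime_pollinators", search$edges_included), ]
  expect_gt(min(without$delta_aicc), 2)
  # enumeration order of edges must not change the ranking
  shuffled_model <- sem_model(fig_model()$edges[c(3, 1, 4, 2), ])
  search2 <- exhaustive_path_search(shuffled_model, d)
  expect_equal(search2$AICc, search$AICc, tolerance = 1e-9)
  too_many <- sem_model(tibble::tibble(
    from = letters[1:13], to = rep("z", 13), optional = TRUE
  ))
  expect_error(exhaustive_path_search(too_many, d), "12 optional")
})

test_that("a zero-effect generator favours the empty path structure", {
  best_counts <- vapply(1:40, function(s) {
    d <- simulate_dag_data(n = 50, b_direct = 0, b_fr = 0, b_fa = 0, seed = 700 + s)
    d$mean_dprime_pollinators <- withr::with_seed(s, rnorm(50))
    search <- exhaustive_path_search(fig_model(c(FALSE, FALSE, TRUE, TRUE)), d)
    search$n_edges[1] == 2 # only the mandatory edges survive
  }, logical(1))
  expect_gt(mean(best_counts), 0.5)
})

test_that("variable preselection finds the causal block members", {
  withr::with_seed(9, {
    n <- 80
    site <- sprintf("s%02d", sample(15, n, replace = TRUE))
    x1 <- rnorm(n)
    x2 <- x1 * 0.995 + rnorm(n, 0, sqrt(1 - 0.995^2)) # r ~ .99 decoy
    noise <- rnorm(n)
    y <- 0.8 * x1 + rnorm(n, 0, 0.4)
    d <- tibble::tibble(
      site_id = site, causal = x1, decoy = x2, noise = noise, y = y
    )
  })
  sel <- preselect_variables(
    d, "y",
    blocks = list(main = c("causal", "decoy"), spare = "noise")
  )
  expect_true("causal" %in% sel$selected)
  expect_false("decoy" %in% sel$selected)
  # a lone informative variable passes through
  sel2 <- preselect_variables(d, "y", blocks = list(only = "causal"))
  expect_equal(sel2$selected, "causal")
})
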