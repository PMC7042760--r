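test_that("the gradient fit reports slope, t-identity and containment df", {
  d <- simulate_lmm_data(seed = 3)
  fit <- fit_metric_vs_elevation(d, "y")
  tt <- tidy(fit)
  expect_equal(tt$statistic, tt$estimate / tt$std_error)
  # site-level predictor: G - 2 df; intercept: N - G
  expect_equal(tt$df[tt$term == "elevation"], 18 - 2)
  expect_equal(tt$df[tt$term == "(Intercept)"], 72 - 18)
  expect_true(fit$R2_fixed >= 0 && fit$R2_fixed <= 1)
  expect_lt(tt$p_value[tt$term == "elevation"], 0.001)

  const <- dplyr::mutate(d, y = 5)
  cfit <- fit_metric_vs_elevation(const, "y")
  expect_equal(tidy(cfit)$estimate[2], 0)
  expect_equal(cfit$R2_fixed, 0)
  expect_error(fit_metric_vs_elevation(d[1:2, ], "y"), ">= 2 sites")
})

test_that("REML matches closed-form ANOVA variance components when balanced", {
  d <- simulate_lmm_data(
    n_sites = 12, walks_per_site = 5, beta = 0,
    site_sd = 0.5, resid_sd = 0.4, seed = 11
  )
  fit <- fit_metric_vs_elevation(d, "y")
  g <- length(unique(d$site_id))
  nper <- 5
  site_means <- tapply(d$y, d$site_id, mean)
  msw <- sum((d$y - rep(site_means[unique(d$site_id)], each = nper))^2) /
    (g * (nper - 1))
  # one-way components after removing the site-level regression: compare on
  # a no-predictor fit where the classical identities are exact
  fit0 <- pollinet:::summarise_lme(
    pollinet:::fit_lme_containment(d, "y", character(0), "site_id"),
    d, "y", character(0), "site_id"
  )
  msb <- nper * sum((site_means - mean(d$y))^2) / (g - 1)
  expect_equal(fit0$resid_sd^2, msw, tolerance = 1e-6)
  expect_equal(fit0$random_sd^2, (msb - msw) / nper, tolerance = 1e-6)
})

test_that("AICc comparison follows its closed form and sign convention", {
  # corrections cancel at equal k and n: delta is the plain AIC difference
  aicc <- pollinet:::aicc_from_ll
  # AIC = -2 ll + 2k: AIC values 14 and 10 at equal k = 3, n = 62
  expect_equal(aicc(-4, 3, 62) - aicc(-2, 3, 62), 4)
  d <- simulate_lmm_data(seed = 5)
  same <- dplyr::mutate(d, lui = elevation)
  cmp_same <- compare_elevation_vs_lui(same, "y")
  expect_equal(cmp_same$delta_aicc, 0, tolerance = 1e-8)

  # an elevation-driven response should usually favour elevation (delta > 0)
  wins <- vapply(1:20, function(s) {
    di <- simulate_lmm_data(seed = 100 + s, beta = -3e-4, site_sd = 0.1)
    compare_elevation_vs_lui(di, "y")$delta_aicc > 0
  }, logical(1))
  expect_gte(sum(wins), 16)
})

test_that("slope test keeps its nominal type-I error under the null", {
  rejected <- vapply(1:400, function(s) {
    d <- simulate_lmm_data(
      n_sites = 15, walks_per_site = 3, beta = 0, seed = 5000 + s
    )
    tt <- tidy(fit_metric_vs_elevation(d, "y"))
    tt$p_value[tt$term == "elevation"] < 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.02)
  expect_lte(mean(rejected), 0.09)
})

test_that("intraspecific temperature model recovers within-species trends", {
  make_scores <- function(slope, seed) {
    withr::with_seed(seed, {
      mats <- seq(5, 24, length.out = 12)
      grid <- tidyr::expand_grid(
        species = sprintf("sp%02d", 1:25),
        site = 1:12
      )
      grid <- grid[runif(nrow(grid)) < 0.6, ]
      tibble::tibble(
        species = grid$species,
        site_id = sprintf("s%02d", grid$site),
        MAT = mats[grid$site],
        is_named = grid$species %in% sprintf("sp%02d", 1:12),
        d_prime = pmin(1, pmax(0, 0.2 + slope * mats[grid$site] +
          rnorm(nrow(grid), 0, 0.08) +
          rep(0, nrow(grid))))
      )
    })
  }
  sc <- make_scores(slope = 0.02, seed = 2)
  fit <- intraspecific_dprime_model(sc)
  tt <- tidy(fit)
  expect_gt(tt$estimate[tt$term == "MAT"], 0)
  expect_lt(tt$p_value[tt$term == "MAT"], 0.05)
  # row order must not matter
  fit2 <- intraspecific_dprime_model(sc[sample(nrow(sc)), ])
  expect_equal(tidy(fit2)$estimate, tt$estimate, tolerance = 1e-8)
  # named-species subset runs
  expect_s3_class(
    intraspecific_dprime_model(sc, named_only = TRUE), "lmm_fit"
  )
  expect_error(
    intraspecific_dprime_model(dplyr::mutate(sc, MAT = 10)), "constant"
  )
  few <- dplyr::filter(sc, species %in% c("sp01"))
  expect_error(intraspecific_dprime_model(few), "2 species")
})

test_that("taxon and trait models recover a built-in group contrast", {
  make_species <- function(delta, seed) {
    withr::with_seed(seed, {
      n <- 90
      group <- sample(c("bee", "wasp", "syrphid"), n,
        replace = TRUE,
        prob = c(.6, .15, .25)
      )
      genus <- paste0(substr(group, 1, 1), sample(1:25, n, replace = TRUE))
      tibble::tibble(
        species = sprintf("sp%03d", 1:n), group = group,
        order_name = ifelse(group == "syrphid", "Diptera", "Hymenoptera"),
        family = paste0(substr(group, 1, 1), "f", sample(1:6, n, TRUE)),
        genus = genus,
        proboscis_length = rlnorm(n, log(3), 0.3),
        head_width = rlnorm(n, log(2), 0.3),
        elevational_range = runif(n, 0, 2500),
        mean_dprime = pmin(1, pmax(
          0,
          0.3 + delta * (group != "syrphid") + rnorm(n, 0, 0.1)
        ))
      )
    })
  }
  sp <- make_species(delta = 0.25, seed = 4)
  fits <- trait_and_taxon_models(sp)
  tx <- tidy(fits$taxon)
  est <- tx$estimate[grepl("higher_taxon", tx$term)]
  expect_lt(abs(abs(est) - 0.25), 0.12)
  expect_lt(tx$p_value[grepl("higher_taxon", tx$term)], 0.05)
  # uncorrelated traits stay mostly nonsignificant across seeds
  pvals <- vapply(1:20, function(s) {
    f <- trait_and_taxon_models(make_species(delta = 0, seed = 100 + s))
    tt <- tidy(f$proboscis)
    tt$p_value[tt$term == "proboscis_length"]
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.25)
  bad <- sp
  bad$genus[3] <- NA
  expect_error(trait_and_taxon_models(bad), "sp003")
})

test_that("backward elimination keeps the true robustness predictor", {
  make_rob <- function(h2_effect, seed) {
    d <- simulate_lmm_data(seed = seed, beta = 0, site_sd = 0.1)
    withr::with_seed(seed + 1, {
      d$H2_prime <- runif(nrow(d))
      d$nestedness_z <- rnorm(nrow(d))
      d$MAT <- 25 - d$elevation / 200
      d$rob <- 0.5 + h2_effect * d$H2_prime + rnorm(nrow(d), 0, 0.05)
    })
    d
  }
  res <- robustness_predictor_model(
    make_rob(-0.4, seed = 21), "rob",
    predictors = c("H2_prime", "nestedness_z", "MAT", "lui")
  )
  kept <- tidy(res$final)$term
  expect_true("H2_prime" %in% kept)
  expect_lte(nrow(res$trace), 4)
  # pure noise: everything is usually eliminated
  empty <- vapply(1:20, function(s) {
    r <- robustness_predictor_model(
      make_rob(0, seed = 300 + s), "rob",
      predictors = c("H2_prime", "nestedness_z", "MAT", "lui")
    )
    !is.null(r$final$note)
  }, logical(1))
  expect_gte(sum(empty), 12)
})

test_that("sensitivity analyses agree with the main gradient fits", {
  study <- small_study(seed = 17)
  networks <- suppressMessages(filter_networks(build_networks(study$interactions)))
  metrics <- network_metrics(networks) |>
    dplyr::left_join(study$sites, by = "site_id")
  cols <- c("mean_dprime_pollinators", "H2_prime")
  out <- suppressWarnings(
    sensitivity_suite(metrics, networks, metric_cols = cols)
  )
  # site-mean OLS slope signs match the walk-level mixed-model signs
  for (mc in cols) {
    lmm <- tidy(fit_metric_vs_elevation(metrics, mc))
    lmm_slope <- lmm$estimate[lmm$term == "elevation"]
    ols_slope <- out$estimate[out$analysis == "site_mean_ols" & out$metric == mc]
    expect_equal(sign(ols_slope), sign(lmm_slope))
  }
  # a cutoff above the highest site reproduces the full-data fit
  full <- suppressWarnings(sensitivity_suite(
    metrics, networks,
    metric_cols = cols, elevation_cutoff = 10000
  ))
  main <- tidy(fit_metric_vs_elevation(
    metrics[is.finite(metrics$H2_prime), ], "H2_prime"
  ))
  expect_equal(
    full$estimate[full$analysis == "below_cutoff_lmm" & full$metric == "H2_prime"],
    main$estimate[main$term == "elevation"],
    tolerance = 1e-8
  )
  # pooled analysis uses exactly the sites with enough walks
  eligible <- names(which(table(networks$site_id) >= 5))
  expect_equal(
    out$n[out$analysis == "pooled_ols"],
    length(eligible)
  )
})
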