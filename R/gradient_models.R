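# Mixed-model gradient stage. Single random-intercept models are fitted
# with nlme::lme (REML for estimates, ML refits for AICc comparisons);
# crossed and nested random-effect models with lme4/lmerTest. Denominator
# df are containment-style: terms varying within sites get N - G - 1,
# site-level terms G - 2, the intercept N - G (the df pattern of classical
# nested designs). Satterthwaite df are available for lmer-based fits.

new_lmm_fit <- function(response, terms, random_sd, resid_sd, n_obs,
                        n_groups, R2_fixed, AICc, singular = FALSE,
                        engine = "nlme", fit = NULL, note = NULL) {
  structure(
    list(
      response = response, terms = terms, random_sd = random_sd,
      resid_sd = resid_sd, n_obs = n_obs, n_groups = n_groups,
      R2_fixed = R2_fixed, AICc = AICc, singular = singular,
      engine = engine, fit = fit, note = note
    ),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> ", x$response, " (", x$engine, "), n = ", x$n_obs,
    ", groups = ", x$n_groups, if (isTRUE(x$singular)) ", singular" else "",
    "\n",
    sep = ""
  )
  print(as.data.frame(x$terms), digits = 4)
  cat(
    "random sd = ", signif(x$random_sd, 3), ", residual sd = ",
    signif(x$resid_sd, 3), ", R2(fixed) = ", signif(x$R2_fixed, 3),
    ", AICc(ML) = ", signif(x$AICc, 6), "\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy lmm_fit
#' @export
tidy.lmm_fit <- function(x, ...) x$terms

#' @method glance lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response, n_obs = x$n_obs, n_groups = x$n_groups,
    random_sd = x$random_sd, resid_sd = x$resid_sd, R2_fixed = x$R2_fixed,
    AICc = x$AICc, singular = x$singular
  )
}

aicc_from_ll <- function(ll, k, n) {
  if (n - k - 1 <= 0) {
    return(NA_real_)
  }
  -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Containment-style denominator df for one fixed term.
containment_df <- function(term_varies_within, n_obs, n_groups,
                           n_fixed_terms) {
  if (term_varies_within) n_obs - n_groups - 1 else n_groups - 2
}

term_varies_within_group <- function(data, term, group) {
  x <- data[[term]]
  if (!is.numeric(x)) x <- as.numeric(as.factor(x))
  any(tapply(x, data[[group]], function(v) max(v) - min(v)) > 1e-10)
}

fit_lme_containment <- function(data, response, predictors, group,
                                method = "REML") {
  fml <- as.formula(paste(
    response, "~",
    if (length(predictors) == 0) "1" else paste(predictors, collapse = " + ")
  ))
  data <- as.data.frame(data)
  fit <- nlme::lme(
    fixed = fml, random = as.formula(paste0("~ 1 | ", group)),
    data = data, method = method,
    control = nlme::lmeControl(opt = "optim", returnObject = TRUE)
  )
  fit
}

summarise_lme <- function(fit, data, response, predictors, group) {
  tt <- summary(fit)$tTable
  n_obs <- nrow(fit$data)
  n_groups <- length(unique(fit$data[[group]]))
  terms <- tibble::tibble(
    term = rownames(tt),
    estimate = unname(tt[, "Value"]),
    std_error = unname(tt[, "Std.Error"])
  )
  terms$df <- unname(vapply(terms$term, function(tm) {
    if (tm == "(Intercept)") {
      return(n_obs - n_groups)
    }
    base <- sub(":.*", "", tm)
    varies <- term_varies_within_group(
      fit$data, intersect(c(tm, base, predictors), names(fit$data))[1], group
    )
    containment_df(varies, n_obs, n_groups, length(predictors))
  }, numeric(1)))
  terms$statistic <- terms$estimate / terms$std_error
  terms$p_value <- 2 * pt(-abs(terms$statistic), terms$df)
  vc <- nlme::VarCorr(fit)
  random_sd <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
  resid_sd <- fit$sigma
  # Nakagawa & Schielzeth variance decomposition; semipartial R2 of the
  # fixed part = var of the fixed-effect predictor alone over total.
  X <- stats::model.matrix(stats::formula(fit), data = fit$data)
  beta <- nlme::fixef(fit)
  var_f <- var(as.numeric(X %*% beta))
  var_tot <- var_f + random_sd^2 + resid_sd^2
  r2 <- if (var_tot > 0) var_f / var_tot else 0
  ml <- tryCatch(
    {
      mlfit <- fit_lme_containment(
        fit$data, response, predictors, group,
        method = "ML"
      )
      k <- length(beta) + 2 # fixed coefficients + random + residual variance
      aicc_from_ll(logLik(mlfit), k, n_obs)
    },
    error = function(e) NA_real_
  )
  new_lmm_fit(
    response = response, terms = terms, random_sd = random_sd,
    resid_sd = resid_sd, n_obs = n_obs, n_groups = n_groups,
    R2_fixed = r2, AICc = ml,
    singular = is.finite(random_sd) && random_sd < 1e-8 * max(resid_sd, 1e-12),
    engine = "nlme", fit = fit
  )
}

#' Fit a network metric against elevation with a random site intercept
#'
#' The gradient stage: a linear mixed-effects model of a per-walk metric on
#' one predictor (elevation by default), with study site as a random
#' intercept to absorb repeated walks on the same site. Reports slope, SE,
#' containment-style df, t, p, the Nakagawa-style semipartial R2 for the
#' fixed effect and the ML AICc. A constant response yields a flagged
#' zero-slope fit rather than an error.
#'
#' @param data Tibble with the metric, predictor and grouping columns
#'   (typically [network_metrics()] joined to site metadata).
#' @param metric Name of the response column.
#' @param predictor Name of the fixed-effect column (default `"elevation"`).
#' @param group Name of the grouping column (default `"site_id"`).
#' @return An `lmm_fit` object.
#' @export
fit_metric_vs_elevation <- function(data, metric, predictor = "elevation",
                                    group = "site_id") {
  keep <- stats::complete.cases(data[, c(metric, predictor, group)])
  data <- data[keep, , drop = FALSE]
  if (length(unique(data[[group]])) < 2 || nrow(data) < 3) {
    abort("Need >= 2 sites and >= 3 observations.")
  }
  if (sd(data[[metric]]) == 0) {
    terms <- tibble::tibble(
      term = c("(Intercept)", predictor),
      estimate = c(mean(data[[metric]]), 0),
      std_error = c(NA_real_, NA_real_), df = c(NA_real_, NA_real_),
      statistic = c(NA_real_, NA_real_), p_value = c(NA_real_, NA_real_)
    )
    return(new_lmm_fit(
      response = metric, terms = terms, random_sd = 0, resid_sd = 0,
      n_obs = nrow(data), n_groups = length(unique(data[[group]])),
      R2_fixed = 0, AICc = NA_real_, singular = TRUE,
      note = "constant response"
    ))
  }
  fit <- fit_lme_containment(data, metric, predictor, group)
  summarise_lme(fit, data, metric, predictor, group)
}

#' AICc comparison of elevation versus land-use intensity
#'
#' Both single-predictor mixed models are refit by maximum likelihood (REML
#' likelihoods are not comparable across fixed structures) and compared by
#' the small-sample AICc (`AIC + 2k(k+1)/(n-k-1)`). The returned difference
#' is `AICc(LUI) - AICc(elevation)`: negative values mean the land-use model
#' is better supported; `|delta| <= 2` counts as similar support.
#'
#' @inheritParams fit_metric_vs_elevation
#' @param elevation,lui Names of the two predictor columns.
#' @return A one-row tibble: `metric`, `aicc_elevation`, `aicc_lui`,
#'   `delta_aicc`, `similarly_supported`, `n`.
#' @export
compare_elevation_vs_lui <- function(data, metric, elevation = "elevation",
                                     lui = "lui", group = "site_id") {
  keep <- stats::complete.cases(data[, c(metric, elevation, lui, group)])
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  fits <- purrr::map(c(elevation, lui), function(p) {
    fit <- fit_lme_containment(data, metric, p, group, method = "ML")
    if (nrow(fit$data) != n) abort("Models compare different observations.")
    aicc_from_ll(logLik(fit), length(nlme::fixef(fit)) + 2, n)
  })
  delta <- fits[[2]] - fits[[1]]
  tibble::tibble(
    metric = metric, aicc_elevation = fits[[1]], aicc_lui = fits[[2]],
    delta_aicc = delta, similarly_supported = abs(delta) <= 2, n = n
  )
}

#' Intraspecific specialization along the temperature gradient
#'
#' Gaussian mixed model of walk-level species d' on mean annual temperature
#' with crossed random intercepts for species and site, restricted to
#' species recorded on at least `min_sites` distinct sites. Satterthwaite
#' df/p via lmerTest.
#'
#' @param scores Species-score table (one row per species x network) with
#'   columns `species`, `site_id`, `d_prime` and the `mat` column.
#' @param mat Name of the temperature column (default `"MAT"`).
#' @param min_sites Minimum number of distinct sites per species.
#' @param named_only If `TRUE`, restrict to rows with `is_named == TRUE`
#'   (species with proper names, excluding morphospecies).
#' @return An `lmm_fit` (engine `"lmer"`).
#' @export
intraspecific_dprime_model <- function(scores, mat = "MAT", min_sites = 3,
                                       named_only = FALSE) {
  if (named_only) {
    if (!"is_named" %in% names(scores)) {
      abort("named_only = TRUE needs an is_named column.")
    }
    scores <- dplyr::filter(scores, .data$is_named)
  }
  eligible <- scores |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_sites = dplyr::n_distinct(.data$site_id)) |>
    dplyr::filter(.data$n_sites >= min_sites)
  scores <- dplyr::semi_join(scores, eligible, by = "species")
  if (dplyr::n_distinct(scores$species) < 2) {
    abort("Fewer than 2 species remain after the min_sites filter.")
  }
  if (sd(scores[[mat]]) == 0) {
    abort("Temperature is constant; the slope is not identifiable.")
  }
  fml <- as.formula(paste0("d_prime ~ ", mat, " + (1 | species) + (1 | site_id)"))
  fit <- lmerTest::lmer(fml, data = scores)
  summarise_lmer(fit, response = "d_prime")
}

summarise_lmer <- function(fit, response) {
  sm <- summary(fit)
  tt <- sm$coefficients
  terms <- tibble::tibble(
    term = rownames(tt), estimate = unname(tt[, "Estimate"]),
    std_error = unname(tt[, "Std. Error"]),
    df = if ("df" %in% colnames(tt)) unname(tt[, "df"]) else NA_real_,
    statistic = unname(tt[, "t value"]),
    p_value = if ("Pr(>|t|)" %in% colnames(tt)) {
      unname(tt[, "Pr(>|t|)"])
    } else {
      NA_real_
    }
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  resid_sd <- vc$sdcor[vc$grp == "Residual"]
  random_sd <- sqrt(sum(vc$sdcor[vc$grp != "Residual"]^2))
  X <- lme4::getME(fit, "X")
  var_f <- var(as.numeric(X %*% lme4::fixef(fit)))
  var_tot <- var_f + sum(vc$sdcor[vc$grp != "Residual"]^2) + resid_sd^2
  n <- stats::nobs(fit)
  k <- length(lme4::fixef(fit)) + nrow(vc)
  ml <- tryCatch(
    aicc_from_ll(logLik(stats::update(fit, REML = FALSE)), k, n),
    error = function(e) NA_real_
  )
  new_lmm_fit(
    response = response, terms = terms, random_sd = random_sd,
    resid_sd = resid_sd, n_obs = n,
    n_groups = length(unique(lme4::getME(fit, "flist")[[1]])),
    R2_fixed = if (var_tot > 0) var_f / var_tot else 0, AICc = ml,
    singular = lme4::isSingular(fit), engine = "lmer", fit = fit
  )
}

#' Taxonomic and trait models of species mean specialization
#'
#' Fits the species-level models: (A) mean d' by higher taxon (Hymenoptera:
#' bees and wasps, versus Diptera: syrphid flies) with a random genus
#' intercept; (B, C) mean d' on proboscis length and head width, and (D) on
#' elevational range, each with nested order/family/genus random intercepts.
#'
#' @param species_tbl Tibble with one row per species: `species`,
#'   `mean_dprime`, `group` (bee/wasp/syrphid), `order_name`, `family`,
#'   `genus`, `proboscis_length`, `head_width`, `elevational_range`.
#' @return Named list of `lmm_fit`s: `taxon`, `proboscis`, `head_width`,
#'   `range`.
#' @export
trait_and_taxon_models <- function(species_tbl) {
  tax_cols <- c("order_name", "family", "genus")
  bad <- species_tbl$species[!stats::complete.cases(species_tbl[, tax_cols])]
  if (length(bad) > 0) {
    abort(paste0(
      "Unresolved taxonomy for species: ",
      paste(head(bad, 10), collapse = ", ")
    ))
  }
  species_tbl$higher_taxon <- ifelse(
    species_tbl$group %in% c("bee", "wasp"), "Hymenoptera", "Diptera"
  )
  fit_one <- function(fml) {
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(as.formula(fml), data = species_tbl)
    ))
    summarise_lmer(fit, response = "mean_dprime")
  }
  list(
    taxon = fit_one("mean_dprime ~ higher_taxon + (1 | genus)"),
    proboscis = fit_one(
      "mean_dprime ~ proboscis_length + (1 | order_name / family / genus)"
    ),
    head_width = fit_one(
      "mean_dprime ~ head_width + (1 | order_name / family / genus)"
    ),
    range = fit_one(
      "mean_dprime ~ elevational_range + (1 | order_name / family / genus)"
    )
  )
}

#' Predictors of network robustness with backward elimination
#'
#' Mixed model of standardized robustness on network specialization (H2'),
#' standardized nestedness, MAT and LUI (random site intercept), simplified
#' by successively removing the least significant term while any p > alpha.
#'
#' @param data Complete-case tibble holding the response and predictors.
#' @param response Name of the robustness column.
#' @param predictors Character vector of candidate predictor columns.
#' @param group Grouping column.
#' @param alpha Removal threshold (default 0.05).
#' @return List with `final` (an `lmm_fit`; intercept-only is flagged via
#'   `note`) and `trace` (tibble of removed terms with their p-values).
#' @export
robustness_predictor_model <- function(data, response,
                                       predictors = c(
                                         "H2_prime", "nestedness_z", "MAT",
                                         "lui"
                                       ),
                                       group = "site_id", alpha = 0.05) {
  keep <- stats::complete.cases(data[, c(response, predictors, group)])
  data <- data[keep, , drop = FALSE]
  current <- predictors
  trace <- tibble::tibble(step = integer(), removed = character(), p = numeric())
  step <- 0
  repeat {
    if (length(current) == 0) {
      fit <- fit_lme_containment(data, response, character(0), group)
      final <- summarise_lme(fit, data, response, character(0), group)
      final$note <- "all terms eliminated; intercept-only model"
      return(list(final = final, trace = trace))
    }
    fit <- fit_lme_containment(data, response, current, group)
    res <- summarise_lme(fit, data, response, current, group)
    tt <- res$terms[res$terms$term != "(Intercept)", ]
    worst <- which.max(tt$p_value)
    if (tt$p_value[worst] <= alpha) {
      return(list(final = res, trace = trace))
    }
    step <- step + 1
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step, removed = tt$term[worst], p = tt$p_value[worst]
    ))
    current <- setdiff(current, tt$term[worst])
  }
}

#' Sensitivity analyses of the elevational gradient
#'
#' Re-runs the gradient stage under the five robustness checks:
#' (a) ordinary least squares on site means of each metric; (b) AICc
#' comparison of elevation against land-use intensity per metric; (c) mixed
#' models restricted to sites below an elevation cutoff; (d) OLS of H2' on
#' elevation for pooled site networks (sites with >= `min_walks` walks);
#' (e) mixed models restricted to open habitats (canopy cover at or below
#' the median). Empty subsets are skipped with a warning.
#'
#' @param metrics Per-walk metric table joined to site metadata (must hold
#'   `site_id`, `elevation`, `lui`, `canopy_cover` and the metric columns).
#' @param networks Network tibble (for the pooled-network analysis).
#' @param metric_cols Metric columns to analyse.
#' @param elevation_cutoff Cutoff for analysis (c), in m (default 2000).
#' @param min_walks Pooling threshold for analysis (d).
#' @return Tibble: `analysis`, `metric`, `estimate`, `statistic`, `p_value`,
#'   `n`.
#' @export
sensitivity_suite <- function(metrics, networks, metric_cols,
                              elevation_cutoff = 2000, min_walks = 5) {
  out <- list()
  ols_row <- function(d, metric, label) {
    d <- d[stats::complete.cases(d[, c(metric, "elevation")]), ]
    fit <- lm(as.formula(paste(metric, "~ elevation")), data = d)
    cf <- summary(fit)$coefficients
    tibble::tibble(
      analysis = label, metric = metric, estimate = cf[2, 1],
      statistic = cf[2, 3], p_value = cf[2, 4], n = nrow(d)
    )
  }
  # (a) site-mean OLS
  site_means <- metrics |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(c(metric_cols, "elevation")),
      ~ mean(.x, na.rm = TRUE)
    ), .groups = "drop")
  out$a <- dplyr::bind_rows(purrr::map(
    metric_cols, ~ ols_row(site_means, .x, "site_mean_ols")
  ))
  # (b) elevation vs LUI AICc
  out$b <- dplyr::bind_rows(purrr::map(metric_cols, function(mc) {
    cmp <- compare_elevation_vs_lui(metrics, mc)
    tibble::tibble(
      analysis = "aicc_lui", metric = mc, estimate = cmp$delta_aicc,
      statistic = NA_real_, p_value = NA_real_, n = cmp$n
    )
  }))
  # (c) low-elevation subset LMM
  low <- dplyr::filter(metrics, .data$elevation < elevation_cutoff)
  if (nrow(low) == 0 || dplyr::n_distinct(low$site_id) < 2) {
    warn("Low-elevation subset is empty or has < 2 sites; analysis (c) skipped.")
  } else {
    out$c <- dplyr::bind_rows(purrr::map(metric_cols, function(mc) {
      fit <- fit_metric_vs_elevation(low, mc)
      sl <- fit$terms[fit$terms$term == "elevation", ]
      tibble::tibble(
        analysis = "below_cutoff_lmm", metric = mc, estimate = sl$estimate,
        statistic = sl$statistic, p_value = sl$p_value, n = fit$n_obs
      )
    }))
  }
  # (d) pooled networks, H2' OLS
  pooled <- pool_site_networks(networks, min_walks = min_walks)
  if (nrow(pooled) == 0) {
    warn("No site has enough walks to pool; analysis (d) skipped.")
  } else {
    pooled_h2 <- network_metrics(pooled) |>
      dplyr::left_join(
        dplyr::distinct(metrics, .data$site_id, .data$elevation),
        by = "site_id"
      )
    out$d <- ols_row(pooled_h2, "H2_prime", "pooled_ols")
  }
  # (e) open habitats
  if ("canopy_cover" %in% names(metrics)) {
    open <- dplyr::filter(
      metrics, .data$canopy_cover <= stats::median(.data$canopy_cover, na.rm = TRUE)
    )
    if (dplyr::n_distinct(open$site_id) >= 2) {
      out$e <- dplyr::bind_rows(purrr::map(metric_cols, function(mc) {
        fit <- fit_metric_vs_elevation(open, mc)
        sl <- fit$terms[fit$terms$term == "elevation", ]
        tibble::tibble(
          analysis = "open_habitat_lmm", metric = mc, estimate = sl$estimate,
          statistic = sl$statistic, p_value = sl$p_value, n = fit$n_obs
        )
      }))
    } else {
      warn("Open-habitat subset has < 2 sites; analysis (e) skipped.")
    }
  }
  dplyr::bind_rows(out)
}
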