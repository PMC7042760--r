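#' Configuration for a synthetic gradient study
#'
#' Defaults emulate the design of a tropical-mountain pollination study:
#' 18 sites spanning 993-4,390 m a.s.l., mean annual temperature falling
#' linearly from 24.0 to 3.1 degrees C over that range, one to eight
#' transect walks per site, species pools of 140 plants and 190
#' pollinators with elevational occupancy windows, plant and pollinator
#' richness declining log-linearly with elevation, and land-use intensity
#' negatively correlated with elevation (target r = -0.57).
#'
#' Specialization is controlled through a Dirichlet-multinomial preference
#' model: each pollinator's preference vector over the local plants is drawn
#' from a Dirichlet with concentration `alpha(MAT) * availability`, with
#' `alpha(MAT) = exp(a0 - a1 * MAT)`. `a1` is the ground-truth
#' temperature-to-specialization effect: `a1 > 0` makes warm-site
#' communities more specialized (small concentration = preferences far from
#' availability). `a1 = 0` gives a null study.
#'
#' @param n_sites Number of study sites.
#' @param elevation_range Lowest and highest site elevation (m a.s.l.).
#' @param mat_anchors MAT at the lowest and highest site (degrees C).
#' @param walks_range Range of transect walks per site (drawn uniformly).
#' @param plant_pool,pollinator_pool Species-pool sizes.
#' @param plant_richness_anchors,pollinator_richness_anchors Expected local
#'   richness at the lowest and highest site (log-linear in between).
#' @param a0,a1 Intercept and temperature slope of the log Dirichlet
#'   concentration per available plant partner.
#' @param site_alpha_sd SD of lognormal site-level heterogeneity in the
#'   concentration (between-site variation in specialization not explained
#'   by temperature).
#' @param lui_elevation_cor Target correlation between the latent land-use
#'   intensity and elevation.
#' @param flower_abundance_anchors Median flower abundance (flower heads) at
#'   the lowest and highest site.
#' @param interaction_rate Interactions per flower head at the reference
#'   walk temperature of 15 C.
#' @param act_sd SD of the walk-temperature deviation around MAT.
#' @param seed Integer study seed; all randomness flows from it through
#'   named substreams.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_sites = 18,
                         elevation_range = c(993, 4390),
                         mat_anchors = c(24.0, 3.1),
                         walks_range = c(1, 8),
                         plant_pool = 140,
                         pollinator_pool = 190,
                         plant_richness_anchors = c(12, 3),
                         pollinator_richness_anchors = c(20, 4),
                         a0 = 1.3,
                         a1 = 0.2,
                         site_alpha_sd = 0.35,
                         lui_elevation_cor = -0.57,
                         flower_abundance_anchors = c(600, 150),
                         interaction_rate = 0.1,
                         act_sd = 1.5,
                         seed = 1) {
  if (abs(lui_elevation_cor) > 1) {
    abort("lui_elevation_cor must lie in [-1, 1].")
  }
  stopifnot(
    n_sites >= 2, diff(elevation_range) > 0,
    all(plant_richness_anchors > 0), all(pollinator_richness_anchors > 0),
    all(flower_abundance_anchors > 0), interaction_rate > 0
  )
  structure(as.list(environment()), class = "study_config")
}

# Log-linear interpolation of per-site expectations along elevation.
loglin_anchor <- function(elev, range, anchors) {
  frac <- (elev - range[1]) / diff(range)
  exp(log(anchors[1]) + frac * (log(anchors[2]) - log(anchors[1])))
}

#' Generate a complete synthetic gradient study
#'
#' Simulates sites, species pools, per-site communities, transect walks and
#' interaction records with known ground truth (see [study_config()] for
#' the generative model). Fixed seeds give identical studies; per-stage
#' substreams make each table reproducible independently of the others.
#'
#' @param config A [study_config()].
#' @return A `synthetic_study` list: `interactions`, `sites`, `walks`,
#'   `traits`, `lui_components`, `truth` (ground-truth parameters) and
#'   `config`.
#' @export
#' @examples
#' study <- generate_study(study_config(seed = 1))
#' nrow(study$interactions)
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  sites <- generate_sites(config)
  pools <- with_seed(
    derive_seed(config$seed, "species"),
    generate_species_pools(config)
  )
  communities <- with_seed(
    derive_seed(config$seed, "communities"),
    generate_communities(config, sites, pools)
  )
  walks <- with_seed(
    derive_seed(config$seed, "walks"),
    generate_walks(config, sites, communities)
  )
  records <- walks$records |>
    dplyr::left_join(
      dplyr::select(pools$traits, "species", pollinator_group = "group"),
      by = c("pollinator_taxon" = "species")
    ) |>
    dplyr::select(
      "site_id", "walk_id", "plant_taxon", "pollinator_taxon",
      "pollinator_group", "count"
    )
  truth <- list(
    a0 = config$a0, a1 = config$a1,
    site_richness = communities$richness,
    lui_rank = rank(sites$latent_intensity),
    lui_elevation_cor_target = config$lui_elevation_cor,
    expected_slope_signs = if (config$a1 > 0) {
      list(
        mean_dprime_pollinators = -1, mean_dprime_plants = -1,
        H2_prime = -1
      )
    } else {
      list(
        mean_dprime_pollinators = 0, mean_dprime_plants = 0, H2_prime = 0
      )
    },
    preferences = communities$preferences
  )
  structure(
    list(
      interactions = records,
      sites = dplyr::select(sites, -"latent_intensity"),
      walks = walks$walks,
      traits = pools$traits,
      lui_components = sites$lui_components[[1]],
      truth = truth,
      config = config
    ),
    class = "synthetic_study"
  )
}

#' @rdname generate_study
#' @param seed Study seed.
#' @param ... Further arguments to [study_config()].
#' @export
simulate_gradient_study <- function(seed = 1, ...) {
  generate_study(study_config(seed = seed, ...))
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", nrow(x$sites), " sites, ", nrow(x$walks),
    " walks, ", sum(x$interactions$count), " interaction events (a1 = ",
    x$config$a1, ", seed = ", x$config$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

generate_sites <- function(config) {
  with_seed(derive_seed(config$seed, "sites"), {
    n <- config$n_sites
    elev <- seq(config$elevation_range[1], config$elevation_range[2],
      length.out = n
    )
    frac <- (elev - elev[1]) / diff(range(elev))
    mat <- config$mat_anchors[1] +
      frac * (config$mat_anchors[2] - config$mat_anchors[1])
    map <- 590 + (2740 - 590) * exp(-((elev - 2200) / 1100)^2)
    zone <- cut(elev,
      breaks = c(0, 1300, 2000, 2800, 3600, 6000),
      labels = c("savanna", "lower_montane", "montane", "subalpine", "alpine")
    )
    canopy_base <- c(
      savanna = 0.15, lower_montane = 0.6, montane = 0.85,
      subalpine = 0.45, alpine = 0.05
    )
    canopy <- clamp01(canopy_base[as.character(zone)] + rnorm(n, 0, 0.08))
    area <- rlnorm(n, log(5), 0.5)
    # Latent land-use intensity with the exact target correlation to
    # elevation (residual of noise on elevation, re-standardized).
    ze <- zscore(elev)
    eps <- rnorm(n)
    eps <- eps - ze * sum(eps * ze) / sum(ze^2)
    u <- config$lui_elevation_cor * ze +
      sqrt(1 - config$lui_elevation_cor^2) * zscore(eps)
    comp <- tibble::tibble(
      site_id = sprintf("s%02d", seq_len(n)),
      biomass_removal = plogis(0.9 * u),
      agri_inputs = 2 + u,
      veg_dissimilarity = exp(0.5 * u),
      landscape_agri_prop = plogis(u - 0.3)
    )
    lui <- compute_lui(comp)
    tibble::tibble(
      site_id = comp$site_id, elevation = elev, MAT = mat, MAP = map,
      lui = lui$lui, area = area, canopy_cover = as.numeric(canopy),
      habitat = as.character(zone), latent_intensity = u,
      lui_components = list(comp)
    )
  })
}

generate_species_pools <- function(config) {
  poll_n <- config$pollinator_pool
  plant_n <- config$plant_pool
  groups <- sample(c("bee", "wasp", "syrphid"), poll_n,
    replace = TRUE, prob = c(0.76, 0.07, 0.17)
  )
  genus <- paste0(substr(groups, 1, 1), "gen", sample(1:45, poll_n, replace = TRUE))
  family <- paste0(substr(groups, 1, 1), "fam", (as.integer(factor(genus)) %% 7) + 1)
  traits <- tibble::tibble(
    species = sprintf("poll%03d", seq_len(poll_n)),
    group = groups,
    order_name = ifelse(groups == "syrphid", "Diptera", "Hymenoptera"),
    family = family, genus = genus,
    proboscis_length = rlnorm(
      poll_n,
      log(c(bee = 4, wasp = 2.5, syrphid = 3)[groups]), 0.35
    ),
    head_width = rlnorm(poll_n, log(2), 0.3),
    is_named = runif(poll_n) < 0.45
  )
  window <- function(n) {
    mid <- runif(n, 900, 4450)
    halfwidth <- rlnorm(n, log(700), 0.45)
    tibble::tibble(mid = mid, lo = mid - halfwidth, hi = mid + halfwidth)
  }
  list(
    traits = traits,
    poll_window = window(poll_n),
    plant_window = dplyr::mutate(
      window(plant_n),
      species = sprintf("plant%03d", seq_len(plant_n))
    )
  )
}

sample_local <- function(window, elev, target) {
  avail <- which(window$lo <= elev & window$hi >= elev)
  if (length(avail) < max(target, 2)) { # fall back to nearest midpoints
    avail <- order(abs(window$mid - elev))[seq_len(max(target, 2))]
  }
  sort(sample(avail, min(length(avail), max(target, 2))))
}

generate_communities <- function(config, sites, pools) {
  richness <- list()
  prefs <- list()
  communities <- purrr::map(seq_len(nrow(sites)), function(i) {
    elev <- sites$elevation[i]
    np <- max(2, round(loglin_anchor(
      elev, config$elevation_range, config$plant_richness_anchors
    )))
    na <- max(2, round(loglin_anchor(
      elev, config$elevation_range, config$pollinator_richness_anchors
    )))
    plants <- sample_local(pools$plant_window, elev, np)
    polls <- sample_local(pools$poll_window, elev, na)
    plant_avail <- rlnorm(length(plants), 0, 0.8)
    plant_avail <- plant_avail / sum(plant_avail)
    activity <- rlnorm(length(polls), 0, 0.8)
    # Dirichlet concentration per available partner: exp(a0 - a1 MAT) with
    # lognormal site-level heterogeneity. Scaling by local plant richness
    # keeps the expected deviation from proportional use independent of
    # community size, so a1 is the only systematic elevational driver of
    # true specialization.
    alpha <- exp(
      config$a0 - config$a1 * sites$MAT[i] +
        rnorm(1, 0, config$site_alpha_sd)
    ) * length(plants)
    pref <- t(vapply(seq_along(polls), function(k) {
      shape <- alpha * plant_avail
      g <- rgamma(length(shape), shape = shape)
      if (sum(g) <= 0) { # degenerate draw: all mass on one plant
        g <- as.numeric(rmultinom(1, 1, plant_avail))
      }
      g / sum(g)
    }, numeric(length(plants))))
    list(
      site_id = sites$site_id[i],
      plants = pools$plant_window$species[plants],
      polls = pools$traits$species[polls],
      plant_avail = plant_avail, activity = activity, pref = pref,
      richness = tibble::tibble(
        site_id = sites$site_id[i], plant_richness = length(plants),
        pollinator_richness = length(polls)
      )
    )
  })
  list(
    by_site = communities,
    richness = dplyr::bind_rows(purrr::map(communities, "richness")),
    preferences = purrr::map(communities, function(cm) {
      m <- cm$pref
      dimnames(m) <- list(cm$polls, cm$plants)
      m
    })
  )
}

generate_walks <- function(config, sites, communities) {
  walk_rows <- list()
  rec_rows <- list()
  for (i in seq_len(nrow(sites))) {
    cm <- communities$by_site[[i]]
    n_walks <- sample(config$walks_range[1]:config$walks_range[2], 1)
    for (w in seq_len(n_walks)) {
      walk_id <- sprintf("%s_w%02d", sites$site_id[i], w)
      act <- sites$MAT[i] + rnorm(1, 0, config$act_sd)
      fa <- rlnorm(1, log(loglin_anchor(
        sites$elevation[i], config$elevation_range,
        config$flower_abundance_anchors
      )), 0.4)
      mu <- config$interaction_rate * fa * exp(0.02 * (act - 15))
      total <- max(1L, rnbinom(1, mu = mu, size = 6))
      by_poll <- as.numeric(rmultinom(1, total, cm$activity))
      plant_idx <- integer(0)
      poll_idx <- integer(0)
      cnt <- numeric(0)
      for (k in which(by_poll > 0)) {
        by_plant <- as.numeric(rmultinom(1, by_poll[k], cm$pref[k, ]))
        nz <- which(by_plant > 0)
        plant_idx <- c(plant_idx, nz)
        poll_idx <- c(poll_idx, rep(k, length(nz)))
        cnt <- c(cnt, by_plant[nz])
      }
      recs <- tibble::tibble(
        site_id = sites$site_id[i], walk_id = walk_id,
        plant_taxon = cm$plants[plant_idx],
        pollinator_taxon = cm$polls[poll_idx],
        count = cnt
      )
      walk_rows[[length(walk_rows) + 1]] <- tibble::tibble(
        walk_id = walk_id, site_id = sites$site_id[i], ACT = act,
        flower_abundance = fa,
        flower_richness = max(1L, min(
          length(cm$plants),
          stats::rpois(1, length(cm$plants))
        )),
        n_interactions = sum(recs$count),
        visitation_rate = sum(recs$count) / fa
      )
      rec_rows[[length(rec_rows) + 1]] <- recs
    }
  }
  list(
    walks = dplyr::bind_rows(walk_rows),
    records = dplyr::bind_rows(rec_rows)
  )
}

#' Write a synthetic study to delimited-text files
#'
#' Emits `interactions.csv`, `sites.csv`, `walks.csv`, `traits.csv`,
#' `lui_components.csv` and `truth.json` into `dir`, in the schemas the
#' readers of this package accept.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(study$interactions, file.path(dir, "interactions.csv"))
  readr::write_csv(
    dplyr::select(study$sites, -dplyr::any_of("lui_components")),
    file.path(dir, "sites.csv")
  )
  readr::write_csv(study$walks, file.path(dir, "walks.csv"))
  readr::write_csv(study$traits, file.path(dir, "traits.csv"))
  readr::write_csv(study$lui_components, file.path(dir, "lui_components.csv"))
  truth <- study$truth
  truth$preferences <- NULL # matrices; not needed for reanalysis
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Run the full pipeline on a synthetic study and score recovery
#'
#' Builds and filters the networks, computes community specialization and
#' H2', fits the elevational mixed models, optionally runs the path-model
#' search for the direct MAT -> specialization edge and the
#' robustness-versus-H2' model, and compares the outcomes with the study's
#' ground truth.
#'
#' @param study A `synthetic_study`.
#' @param include_sem Run the path-model search (default `TRUE`).
#' @param include_robustness Fit robustness against H2' (default `FALSE`;
#'   simulation-heavy).
#' @param n_orders Removal orders for the robustness stage.
#' @param alpha Significance level used for the slope checks.
#' @return A tibble with one row per check: `check`, `value`, `pass`.
#' @export
recover_parameters <- function(study, include_sem = TRUE,
                               include_robustness = FALSE, n_orders = 50,
                               alpha = 0.05) {
  networks <- filter_networks(
    build_networks(study$interactions),
    min_interactions = 5
  )
  tab <- walk_level_table(networks, study)
  strong <- study$config$a1 > 0
  slope_check <- function(metric) {
    d <- tab[is.finite(tab[[metric]]), ]
    fit <- fit_metric_vs_elevation(d, metric)
    sl <- fit$terms[fit$terms$term == "elevation", ]
    signif_neg <- is.finite(sl$p_value) && sl$p_value < alpha && sl$estimate < 0
    tibble::tibble(
      check = paste0("elevation_slope_", metric),
      value = sl$statistic,
      pass = if (strong) signif_neg else NA
    )
  }
  out <- dplyr::bind_rows(
    slope_check("mean_dprime_pollinators"),
    slope_check("mean_dprime_plants"),
    slope_check("H2_prime")
  )
  if (include_sem) {
    best <- mat_dprime_search(tab)
    has_edge <- grepl("MAT->mean_dprime_pollinators", best$edges_included[1])
    out <- dplyr::bind_rows(out, tibble::tibble(
      check = "sem_direct_mat_edge",
      value = as.numeric(has_edge),
      pass = if (strong) has_edge else NA
    ))
  }
  if (include_robustness) {
    rb <- purrr::map_dbl(
      networks$network,
      ~ robustness(.x, "pollinator", n_orders, seed = study$config$seed)$R
    )
    d <- tab
    d$robustness_R <- rb[match(d$walk_id, networks$walk_id)]
    fit <- fit_metric_vs_elevation(
      d[is.finite(d$H2_prime), ], "robustness_R",
      predictor = "H2_prime"
    )
    sl <- fit$terms[fit$terms$term == "H2_prime", ]
    out <- dplyr::bind_rows(out, tibble::tibble(
      check = "robustness_declines_with_H2",
      value = sl$statistic,
      pass = if (strong) sl$estimate < 0 else NA
    ))
  }
  out
}

# Per-walk analysis table: community specialization, H2', covariates.
walk_level_table <- function(networks, study) {
  n <- nrow(networks)
  mp <- mq <- h2 <- numeric(n)
  for (i in seq_len(n)) {
    a <- unclass(networks$network[[i]])
    mp[i] <- community_mean_core(a, "pollinator")
    mq[i] <- community_mean_core(a, "plant")
    h2[i] <- h2prime_core(a)$H2_prime
  }
  tibble::tibble(
    walk_id = networks$walk_id, site_id = networks$site_id,
    mean_dprime_pollinators = mp, mean_dprime_plants = mq, H2_prime = h2
  ) |>
    dplyr::left_join(
      dplyr::select(
        study$sites, "site_id", "elevation", "MAT", "lui", "area"
      ),
      by = "site_id"
    ) |>
    dplyr::left_join(
      dplyr::select(
        study$walks, "walk_id", "ACT", "flower_abundance", "flower_richness",
        "visitation_rate"
      ),
      by = "walk_id"
    ) |>
    dplyr::mutate(log_flower_abundance = log(.data$flower_abundance))
}

# Path-model search for the direct temperature -> specialization edge,
# mirroring the hypothesized structure: MAT -> flower richness ->
# specialization, log flower abundance -> flower richness, MAT ->
# specialization (optional), flower richness -> specialization (optional).
mat_dprime_search <- function(tab) {
  edges <- tibble::tibble(
    from = c(
      "MAT", "MAT", "log_flower_abundance", "MAT", "flower_richness"
    ),
    to = c(
      "log_flower_abundance", "flower_richness", "flower_richness",
      "mean_dprime_pollinators", "mean_dprime_pollinators"
    ),
    optional = c(FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  model <- sem_model(edges)
  data <- tab[is.finite(tab$mean_dprime_pollinators), ]
  exhaustive_path_search(model, data, group = "site_id")
}
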