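# Tibble-free computational cores, shared by the user-facing wrappers and
# the simulation loops where construction overhead matters.
dprime_core <- function(a) {
  m <- sum(a)
  avail <- rowSums(a) / m # partner availability q_k (other level)
  totals <- colSums(a)
  ns <- ncol(a)
  d <- d_min <- numeric(ns)
  for (j in seq_len(ns)) {
    counts <- a[, j]
    A <- totals[j]
    nz <- counts > 0
    d[j] <- sum((counts[nz] / A) * log((counts[nz] / A) / avail[nz]))
    d_min[j] <- kl_alloc(min_kl_allocation(A, avail), avail)
  }
  d_max <- log(m / totals)
  span <- d_max - d_min
  d_prime <- ifelse(span <= 1e-12, 0, clamp01((d - d_min) / span))
  list(
    d = d, d_min = unname(d_min), d_max = unname(d_max),
    d_prime = unname(d_prime), n_events = unname(totals)
  )
}

# Abundance-weighted community mean d' of one level ("pollinator" = columns).
community_mean_core <- function(a, level) {
  if (level == "plant") a <- t(a)
  core <- dprime_core(a)
  sum(core$n_events * core$d_prime) / sum(core$n_events)
}

h2prime_core <- function(a) {
  if (nrow(a) < 2 || ncol(a) < 2 || sum(a) < 2) {
    return(list(
      H2 = NA_real_, H2_min = NA_real_, H2_max = NA_real_,
      H2_prime = NA_real_, computable = FALSE
    ))
  }
  h2 <- shannon_entropy(a)
  r <- rowSums(a)
  c <- colSums(a)
  h2_max <- shannon_entropy(max_entropy_table(r, c))
  h2_min <- shannon_entropy(min_entropy_table(r, c))
  h2p <- if (h2_max - h2_min <= 1e-12) {
    0
  } else {
    clamp01((h2_max - h2) / (h2_max - h2_min))
  }
  list(
    H2 = h2, H2_min = h2_min, H2_max = h2_max, H2_prime = h2p,
    computable = TRUE
  )
}

#' Species-level specialization d and d'
#'
#' For a focal species with interaction counts `a_k` over its potential
#' partners, partner availability is `q_k = A_k / m` (the partners' share of
#' all interaction events in the network). The raw index is the
#' Kullback-Leibler divergence of use versus availability,
#' `d = sum (a_k/A) ln((a_k/A) / q_k)` over used partners, in nats.
#' It is standardized to `d' = (d - d_min) / (d_max - d_min)` in `[0, 1]`:
#' `d_max = ln(m / A)` (all events on the rarest achievable fraction) and
#' `d_min` is the divergence of the most generalized achievable integer
#' allocation of the species' `A` events proportional to availability
#' (largest-remainder allocation refined by unit-exchange descent, which
#' attains the exact integer optimum). `d' = 0` marks a perfect opportunist,
#' `d' = 1` maximal exclusiveness.
#'
#' @param net A [quant_network()].
#' @param level `"pollinator"` (columns, default) or `"plant"` (rows).
#' @return A tibble with one row per species at the focal level: `species`,
#'   `level`, `d`, `d_min`, `d_max`, `d_prime`, `n_events`.
#' @export
#' @examples
#' net <- quant_network(diag(2) * 2)
#' species_dprime(net, "pollinator")$d_prime # perfectly specialized: 1 1
species_dprime <- function(net, level = c("pollinator", "plant")) {
  level <- match.arg(level)
  a <- unclass(net)
  if (level == "plant") a <- t(a)
  core <- dprime_core(a)
  tibble::tibble(
    species = colnames(a), level = level, d = core$d, d_min = core$d_min,
    d_max = core$d_max, d_prime = core$d_prime,
    n_events = core$n_events, walk_id = attr(net, "walk_id")
  )
}

#' Community summary of specialization
#'
#' Community mean d' is the abundance-weighted mean over species (weights =
#' species interaction totals, matching how walk-level communities are
#' summarised); the unweighted mean is also returned. The coefficient of
#' variation is the population standard deviation of the unweighted d'
#' values divided by their mean (switch `sd_type = "sample"` for the n-1
#' denominator), and is missing for singleton communities or zero means.
#'
#' @param scores Output of [species_dprime()].
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return One-row tibble: `mean_dprime`, `mean_dprime_unweighted`,
#'   `cv_dprime`, `n_species`.
#' @export
community_dprime <- function(scores, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (nrow(scores) < 1) {
    abort("community_dprime needs at least one species score.")
  }
  w <- scores$n_events
  d <- scores$d_prime
  n <- length(d)
  mu <- mean(d)
  s <- if (n < 2) {
    NA_real_
  } else if (sd_type == "population") {
    sqrt(mean((d - mu)^2))
  } else {
    sd(d)
  }
  cv <- if (n < 2 || !is.finite(mu) || mu == 0) NA_real_ else s / mu
  tibble::tibble(
    mean_dprime = sum(w * d) / sum(w),
    mean_dprime_unweighted = mu,
    cv_dprime = cv,
    n_species = n
  )
}

#' Species mean d' across networks
#'
#' The average specialization of a species over all networks in which it was
#' observed (unweighted mean of its walk-level d' values). Species observed
#' fewer than `min_obs` times across the study are excluded, since their
#' mean is poorly determined.
#'
#' @param scores Row-bound [species_dprime()] tables over many networks.
#' @param min_obs Minimum number of networks a species must appear in.
#' @return Tibble: `species`, `mean_dprime`, `n_obs`.
#' @export
species_mean_dprime <- function(scores, min_obs = 3) {
  scores |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      mean_dprime = mean(.data$d_prime),
      n_obs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_obs >= min_obs)
}

#' Network-level complementary specialization H2'
#'
#' The two-dimensional Shannon entropy of the interaction matrix,
#' `H2 = -sum (a_ij/m) ln(a_ij/m)`, standardized between the extreme
#' entropies achievable under the observed marginal totals:
#' `H2' = (H2_max - H2) / (H2_max - H2_min)`, clamped to `[0, 1]`.
#' `H2_max` comes from the most-even integer table with the observed
#' marginals (rounded expected values with remainder repair), `H2_min` from
#' the most-heterogeneous one (greedy pairing of the largest remaining row
#' and column totals); both are refined by a unit-transfer local search on
#' small matrices, where they match exhaustive enumeration. High H2' means
#' species partition their partners; 0 means interactions follow abundance.
#'
#' Networks with fewer than two species on either level (or `m < 2`) do not
#' admit the standardization; they yield a typed not-computable result
#' rather than a numeric 0 or 1.
#'
#' @param net A [quant_network()].
#' @return One-row tibble: `H2`, `H2_min`, `H2_max`, `H2_prime`,
#'   `computable`, `reason`.
#' @export
#' @examples
#' h2prime(quant_network(diag(2) * 2))$H2_prime # 1
h2prime <- function(net) {
  core <- h2prime_core(unclass(net))
  tibble::tibble(
    H2 = core$H2, H2_min = core$H2_min, H2_max = core$H2_max,
    H2_prime = core$H2_prime, computable = core$computable,
    reason = if (core$computable) {
      NA_character_
    } else {
      "needs >= 2 species on both levels and m >= 2"
    }
  )
}

#' Weighted nestedness (WNODF)
#'
#' Weighted Nestedness metric based on Overlap and Decreasing Fill, on a
#' 0-100 scale. Rows and columns are sorted by decreasing marginal totals;
#' for each ordered pair with a strictly greater total (`u` richer, `v`
#' poorer) the pairwise score is 100 times the fraction of `v`'s nonzero
#' cells that are strictly smaller than `u`'s corresponding cells; pairs
#' with equal totals score 0. WNODF is the mean over all row pairs and
#' column pairs. High values mean specialists interact with proper subsets
#' of the partners of generalists.
#'
#' @param net A [quant_network()] with at least 2 rows and 2 columns.
#' @return A value in `[0, 100]`.
#' @export
#' @examples
#' wnodf(quant_network(matrix(c(5, 3, 2, 0), 2, 2))) # 100
wnodf <- function(net) {
  a <- unclass(net)
  if (nrow(a) < 2 || ncol(a) < 2) {
    abort("wnodf needs at least 2 plants and 2 pollinators.")
  }
  a <- a[order(rowSums(a), decreasing = TRUE), , drop = FALSE]
  a <- a[, order(colSums(a), decreasing = TRUE), drop = FALSE]
  pair_scores <- function(mat) { # rows of `mat` are compared
    tot <- rowSums(mat)
    n <- nrow(mat)
    out <- numeric(0)
    for (u in seq_len(n - 1)) {
      for (v in (u + 1):n) {
        if (tot[v] >= tot[u]) {
          out <- c(out, 0)
        } else {
          nzv <- mat[v, ] > 0
          out <- c(out, 100 * sum(nzv & mat[v, ] < mat[u, ]) / sum(nzv))
        }
      }
    }
    out
  }
  mean(c(pair_scores(a), pair_scores(t(a))))
}

#' Dependence asymmetry
#'
#' For each realised link, the pollinator's dependence is `a_ij / A_j` and
#' the plant's is `a_ij / A_i`; the link's asymmetry is their difference
#' normalized by the larger of the two, `(d_A - d_P) / max(d_A, d_P)`. The
#' network value is the unweighted mean over links and ranges from -1
#' (plants depend more on pollinators) to 1 (pollinators depend more on
#' plants, the higher trophic level depending more strongly).
#'
#' @param net A [quant_network()].
#' @param variant `"signed_max"` (default, the max-normalized signed form)
#'   or `"raw_diff"` (plain mean difference of dependences).
#' @return A value in `[-1, 1]`.
#' @export
dependence_asymmetry <- function(net, variant = c("signed_max", "raw_diff")) {
  variant <- match.arg(variant)
  a <- unclass(net)
  idx <- which(a > 0, arr.ind = TRUE)
  d_p <- a[idx] / rowSums(a)[idx[, 1]] # plant's dependence on the pollinator
  d_a <- a[idx] / colSums(a)[idx[, 2]] # pollinator's dependence on the plant
  if (variant == "raw_diff") {
    return(mean(d_a - d_p))
  }
  mean((d_a - d_p) / pmax(d_a, d_p))
}

#' Per-network index table
#'
#' Computes the full set of network descriptors for every network in a
#' network tibble: matrix size, H2' (with computability flag), WNODF (NA on
#' degenerate dimensions), dependence asymmetry, and community mean/CV of d'
#' for both trophic levels.
#'
#' @param networks Network tibble from [build_networks()].
#' @param sd_type Passed to [community_dprime()].
#' @return A tibble with one row per network.
#' @export
network_metrics <- function(networks, sd_type = "population") {
  rows <- purrr::map(seq_len(nrow(networks)), function(i) {
    net <- networks$network[[i]]
    h2 <- h2prime(net)
    poll <- community_dprime(species_dprime(net, "pollinator"), sd_type)
    plant <- community_dprime(species_dprime(net, "plant"), sd_type)
    tibble::tibble(
      walk_id = networks$walk_id[i],
      site_id = networks$site_id[i],
      n_plants = nrow(net), n_pollinators = ncol(net),
      matrix_size = matrix_size(net),
      log_matrix_size = log(matrix_size(net)),
      m = grand_total(net),
      H2_prime = h2$H2_prime, H2_computable = h2$computable,
      wnodf = if (nrow(net) >= 2 && ncol(net) >= 2) wnodf(net) else NA_real_,
      dep_asym = dependence_asymmetry(net),
      mean_dprime_pollinators = poll$mean_dprime,
      cv_dprime_pollinators = poll$cv_dprime,
      mean_dprime_plants = plant$mean_dprime,
      cv_dprime_plants = plant$cv_dprime
    )
  })
  dplyr::bind_rows(c(list(tibble::tibble()), rows))
}

#' Long table of species specialization scores over many networks
#'
#' @param networks Network tibble from [build_networks()].
#' @param level Trophic level passed to [species_dprime()].
#' @return Row-bound [species_dprime()] tables with `walk_id` and `site_id`.
#' @export
species_scores <- function(networks, level = "pollinator") {
  rows <- purrr::map(seq_len(nrow(networks)), function(i) {
    out <- species_dprime(networks$network[[i]], level)
    out$site_id <- networks$site_id[i]
    out
  })
  dplyr::bind_rows(rows)
}
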