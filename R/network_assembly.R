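#' Build one quantitative network per transect walk
#'
#' Aggregates interaction records into one plant x pollinator count matrix
#' per walk. Only the retained pollinator groups enter networks; the `other`
#' group (e.g. butterflies, nonsyrphid Diptera) is always dropped. Rows and
#' columns are sorted lexicographically so the result is independent of
#' record order. Taxon labels are scoped per walk: morphospecies identity is
#' only reliable within a network, so species are never merged across walks
#' at this stage (see [pool_site_networks()] for the documented site-level
#' approximation).
#'
#' @param records Tibble of interaction records as returned by
#'   [read_interactions()] or [simulate_gradient_study()].
#' @param groups_keep Pollinator groups to retain; must be a subset of
#'   `c("bee", "wasp", "syrphid")`.
#' @return A tibble with one row per walk that has at least one retained
#'   record: `walk_id`, `site_id`, `network` (list of [quant_network()]),
#'   `n_plants`, `n_pollinators`, `m`.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   site_id = "s1", walk_id = "w1", plant_taxon = c("P1", "P2"),
#'   pollinator_taxon = "B1", pollinator_group = "bee", count = c(2, 1)
#' )
#' build_networks(recs)
build_networks <- function(records, groups_keep = c("bee", "wasp", "syrphid")) {
  allowed <- c("bee", "wasp", "syrphid")
  if (!all(groups_keep %in% allowed)) {
    abort("groups_keep must be a subset of c(\"bee\", \"wasp\", \"syrphid\").")
  }
  records <- dplyr::filter(records, .data$pollinator_group %in% groups_keep)
  if (nrow(records) == 0) {
    return(empty_network_tbl())
  }
  split_recs <- split(records, records$walk_id)
  rows <- purrr::map(split_recs, function(r) {
    plants <- sort(unique(r$plant_taxon))
    polls <- sort(unique(r$pollinator_taxon))
    a <- matrix(0, length(plants), length(polls),
      dimnames = list(plants, polls)
    )
    for (k in seq_len(nrow(r))) {
      a[r$plant_taxon[k], r$pollinator_taxon[k]] <-
        a[r$plant_taxon[k], r$pollinator_taxon[k]] + r$count[k]
    }
    net <- quant_network(a,
      walk_id = r$walk_id[[1]],
      site_id = r$site_id[[1]]
    )
    tibble::tibble(
      walk_id = r$walk_id[[1]], site_id = r$site_id[[1]],
      network = list(net), n_plants = nrow(a), n_pollinators = ncol(a),
      m = sum(a)
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$walk_id)
}

empty_network_tbl <- function() {
  tibble::tibble(
    walk_id = character(), site_id = character(), network = list(),
    n_plants = integer(), n_pollinators = integer(), m = numeric()
  )
}

#' Drop sparsely sampled networks
#'
#' Keeps networks with at least `min_interactions` total interaction events
#' (the grand total `m`, not the number of distinct links).
#'
#' @param networks Network tibble from [build_networks()].
#' @param min_interactions Minimum `m`; defaults to 5.
#' @return The filtered network tibble. The number removed is reported via
#'   a message and stored in the `n_removed` attribute.
#' @export
filter_networks <- function(networks, min_interactions = 5) {
  if (min_interactions < 1) {
    abort("min_interactions must be >= 1.")
  }
  keep <- networks$m >= min_interactions
  removed <- sum(!keep)
  if (removed > 0) {
    inform(paste0(
      "filter_networks: removed ", removed, " network(s) with fewer than ",
      min_interactions, " interactions."
    ))
  }
  out <- networks[keep, , drop = FALSE]
  attr(out, "n_removed") <- removed
  out
}

#' Pool replicated walks into one joint network per site
#'
#' For sites with at least `min_walks` walks, sums interaction counts over
#' all of the site's walks into one joint network, matching species by taxon
#' label within the site. Because morphospecies are only separated within
#' walks, cross-walk label matching is an approximation, accepted for the
#' sampling-effort sensitivity analysis.
#'
#' @param networks Network tibble from [build_networks()].
#' @param min_walks Minimum number of walks a site needs to be pooled.
#' @return A network tibble with one row per qualifying site; `walk_id` is
#'   `"pooled:<site_id>"`.
#' @export
pool_site_networks <- function(networks, min_walks = 5) {
  counts <- table(networks$site_id)
  keep_sites <- names(counts)[counts >= min_walks]
  rows <- purrr::map(keep_sites, function(s) {
    nets <- networks$network[networks$site_id == s]
    plants <- sort(unique(unlist(lapply(nets, rownames))))
    polls <- sort(unique(unlist(lapply(nets, colnames))))
    a <- matrix(0, length(plants), length(polls),
      dimnames = list(plants, polls)
    )
    for (net in nets) {
      a[rownames(net), colnames(net)] <- a[rownames(net), colnames(net)] +
        unclass(net)
    }
    net <- quant_network(a, walk_id = paste0("pooled:", s), site_id = s)
    tibble::tibble(
      walk_id = paste0("pooled:", s), site_id = s, network = list(net),
      n_plants = nrow(a), n_pollinators = ncol(a), m = sum(a)
    )
  })
  dplyr::bind_rows(c(list(empty_network_tbl()), rows))
}

#' Visitation rate of a transect walk
#'
#' The number of observed interactions divided by flower abundance, a
#' per-walk measure of pollinator activity relative to resource supply.
#'
#' @param n_interactions Number of interaction events observed on the walk.
#' @param flower_abundance Total number of flower heads counted on the walk.
#' @return `n_interactions / flower_abundance`.
#' @export
visitation_rate <- function(n_interactions, flower_abundance) {
  if (any(flower_abundance <= 0)) {
    abort("visitation_rate is undefined when flower_abundance is 0; flag the walk instead.")
  }
  n_interactions / flower_abundance
}

#' Elevational range of species
#'
#' Range = maximum minus minimum elevation of occurrence; a species observed
#' at a single elevation has range 0. Sampling can only shrink the true
#' range, never widen it.
#'
#' @param occurrences Tibble/data frame with columns `species` and
#'   `elevation`.
#' @return Tibble with columns `species`, `range` (m).
#' @export
elevational_range <- function(occurrences) {
  occurrences |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      range = max(.data$elevation) - min(.data$elevation),
      .groups = "drop"
    )
}
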