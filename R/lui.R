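#' Vegetation-structure dissimilarity to natural reference habitats
#'
#' Distance of a site's vegetation structure (canopy closure, canopy height,
#' vegetation heterogeneity) from the average structure of natural habitats
#' in the same elevational band. The three structure components are z-scored
#' across all sites first, so a site one standard deviation away in one
#' component scores 1.
#'
#' @param veg Tibble with columns `site_id`, `elevation_level`, `is_natural`
#'   and three numeric structure columns given in `structure_cols`.
#' @param structure_cols Names of the structure columns.
#' @return Tibble `site_id`, `veg_dissimilarity`.
#' @export
vegetation_dissimilarity <- function(veg,
                                     structure_cols = c(
                                       "canopy_closure", "canopy_height",
                                       "veg_heterogeneity"
                                     )) {
  z <- veg
  for (col in structure_cols) z[[col]] <- zscore(veg[[col]])
  out <- purrr::map(seq_len(nrow(z)), function(i) {
    band <- z$elevation_level[i]
    ref <- z[z$elevation_level == band & z$is_natural, structure_cols,
      drop = FALSE
    ]
    if (nrow(ref) == 0) {
      abort(paste0(
        "No natural reference site in elevational band '", band, "'."
      ))
    }
    centroid <- colMeans(ref)
    tibble::tibble(
      site_id = z$site_id[i],
      veg_dissimilarity = sqrt(sum((unlist(z[i, structure_cols]) - centroid)^2))
    )
  })
  dplyr::bind_rows(out)
}

#' Composite land-use intensity index
#'
#' Averages four standardized components per site: annual biomass removal,
#' agricultural inputs, vegetation-structure dissimilarity from natural
#' habitats, and the proportion of agricultural land in the surrounding
#' landscape. Components are z-scored across sites before averaging
#' (`standardize = "minmax"` rescales to `[0, 1]` instead). A component with
#' zero variance contributes 0 for every site and is flagged; a missing
#' component value leads to averaging over the available components with a
#' warning.
#'
#' @param components Tibble with `site_id` and the four numeric columns
#'   named in `component_cols`.
#' @param component_cols Names of the component columns.
#' @param standardize `"zscore"` (default) or `"minmax"`.
#' @return Tibble `site_id`, `lui`, sorted as the input.
#' @export
compute_lui <- function(components,
                        component_cols = c(
                          "biomass_removal", "agri_inputs",
                          "veg_dissimilarity", "landscape_agri_prop"
                        ),
                        standardize = c("zscore", "minmax")) {
  standardize <- match.arg(standardize)
  if (nrow(components) < 2) {
    abort("compute_lui needs at least 2 sites to standardize components.")
  }
  std <- purrr::map(component_cols, function(col) {
    x <- components[[col]]
    if (all(is.finite(x)) && sd(x) == 0) {
      warn(paste0("LUI component '", col, "' has zero variance; it contributes 0."))
    }
    if (standardize == "zscore") {
      z <- (x - mean(x, na.rm = TRUE))
      s <- sd(x, na.rm = TRUE)
      if (!is.finite(s) || s == 0) rep(0, length(x)) else z / s
    } else {
      r <- range(x, na.rm = TRUE)
      if (diff(r) == 0) rep(0, length(x)) else (x - r[1]) / diff(r)
    }
  })
  mat <- do.call(cbind, std)
  if (anyNA(mat)) {
    warn("Missing LUI component values; averaging over available components.")
  }
  tibble::tibble(
    site_id = components$site_id,
    lui = rowMeans(mat, na.rm = TRUE)
  )
}
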