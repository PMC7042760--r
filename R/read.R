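#' Read long-format interaction records
#'
#' Reads a delimited text file (comma by default, tab auto-detected) of
#' interaction records, one row per observed visit event aggregate: site,
#' transect walk, plant taxon, pollinator taxon, pollinator group and count.
#' Pollinator groups other than `bee`, `wasp`, `syrphid` are mapped to
#' `other` (and later excluded from network assembly).
#'
#' @param path Path to a UTF-8 delimited text file whose header names the six
#'   fields `site_id, walk_id, plant_taxon, pollinator_taxon,
#'   pollinator_group, count`.
#' @return A tibble of validated records in file order.
#' @export
read_interactions <- function(path) {
  x <- read_delimited(path)
  required <- c(
    "site_id", "walk_id", "plant_taxon", "pollinator_taxon",
    "pollinator_group", "count"
  )
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0(
      "Interaction table is missing column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  x <- dplyr::select(x, dplyr::all_of(required))
  x$count <- as.numeric(x$count)
  bad <- which(!is.finite(x$count) | x$count < 1 | x$count != round(x$count))
  if (length(bad) > 0) {
    abort(paste0(
      "Invalid count (must be a positive integer) in row(s): ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  known <- c("bee", "wasp", "syrphid")
  x$pollinator_group <- ifelse(x$pollinator_group %in% known,
    x$pollinator_group, "other"
  )
  tibble::as_tibble(x)
}

#' Read site and walk metadata tables
#'
#' Site metadata carries one row per study site (elevation in m a.s.l., mean
#' annual temperature MAT in degrees C, mean annual precipitation MAP in mm,
#' composite land-use intensity LUI, elevational-belt area in km2, canopy
#' cover and habitat label). Walk metadata carries one row per transect walk
#' (walk-time temperature ACT, flower abundance and richness).
#'
#' @param path Path to a delimited text file.
#' @return A tibble.
#' @export
read_sites <- function(path) {
  x <- read_delimited(path)
  required <- c("site_id", "elevation")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0(
      "Site table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (any(x$elevation < 0 | x$elevation > 6000)) {
    abort("Site elevations must lie within [0, 6000] m.")
  }
  tibble::as_tibble(x)
}

#' @rdname read_sites
#' @export
read_walks <- function(path) {
  x <- read_delimited(path)
  required <- c("walk_id", "site_id")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0(
      "Walk table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if ("flower_abundance" %in% names(x) && any(x$flower_abundance < 0)) {
    abort("flower_abundance must be nonnegative.")
  }
  tibble::as_tibble(x)
}

#' @rdname read_sites
#' @export
read_traits <- function(path) {
  tibble::as_tibble(read_delimited(path))
}

read_delimited <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    progress = FALSE, trim_ws = TRUE
  )
}
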