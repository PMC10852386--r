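#' Urbanicity classification of POLs
#'
#' POLs are classified rural / urban non-NYC / NYC from the rural share of
#' their population, estimated by areal interpolation from block groups, with
#' a county-based override for the five New York City counties.
#'
#' @name geo_urbanicity
#' @keywords internal
NULL

#' The five New York City counties
#' @export
NYC_COUNTIES <- c("Bronx", "Kings", "New York", "Queens", "Richmond")

#' Exact block-group / POL area crosswalk for rectangular toy geometries
#'
#' For each (block group, POL) pair with positive overlap, the fraction of
#' the block group's area inside the POL. Axis-aligned rectangles make the
#' intersection area exact; per block group the fractions sum to at most 1.
#'
#' @param block_groups data.frame with `bg_id` and rectangle bounds `xmin`,
#'   `xmax`, `ymin`, `ymax`.
#' @param pol_geometries data.frame with `pol_id` and the same bounds.
#' @return data.frame `bg_id`, `pol_id`, `area_fraction`.
#' @export
compute_crosswalk <- function(block_groups, pol_geometries) {
  out <- list()
  for (i in seq_len(nrow(block_groups))) {
    b <- block_groups[i, ]
    barea <- (b$xmax - b$xmin) * (b$ymax - b$ymin)
    if (barea <= 0) stop("degenerate block-group geometry: ", b$bg_id)
    ox <- pmax(0, pmin(b$xmax, pol_geometries$xmax) -
                 pmax(b$xmin, pol_geometries$xmin))
    oy <- pmax(0, pmin(b$ymax, pol_geometries$ymax) -
                 pmax(b$ymin, pol_geometries$ymin))
    frac <- ox * oy / barea
    hit <- which(frac > 0)
    if (length(hit) > 0L)
      out[[length(out) + 1L]] <- data.frame(bg_id = b$bg_id,
                                            pol_id = pol_geometries$pol_id[hit],
                                            area_fraction = frac[hit])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Areally interpolated rural population share of a POL
#'
#' Population-weighted interpolation: each block group contributes its rural
#' and total population in proportion to the fraction of its area inside the
#' POL; the POL's rural share is the ratio of the interpolated rural to
#' interpolated total population.
#'
#' @param pol_id the POL.
#' @param block_groups data.frame with `bg_id`, `population`, `rural_population`.
#' @param crosswalk data.frame `bg_id`, `pol_id`, `area_fraction` (fractions
#'   per block group summing to at most 1).
#' @return rural share in `[0, 1]`.
#' @export
areal_interpolate_rural_share <- function(pol_id, block_groups, crosswalk) {
  cw <- crosswalk[crosswalk$pol_id == pol_id, , drop = FALSE]
  bi <- match(cw$bg_id, block_groups$bg_id)
  if (anyNA(bi)) stop("crosswalk references unknown block group")
  tot <- sum(block_groups$population[bi] * cw$area_fraction)
  rur <- sum(block_groups$rural_population[bi] * cw$area_fraction)
  if (tot <= 0) stop("uninhabited POL: ", pol_id)
  rur / tot
}

#' Classify a POL's urbanicity
#'
#' A POL in one of the five NYC counties is `nyc` regardless of rural share;
#' otherwise `rural` when strictly more than half of its (interpolated)
#' inhabitants are rural, else `urban_non_nyc`. An unrecognised county label
#' is treated as non-NYC with a warning.
#'
#' @param rural_share fraction in `[0, 1]`.
#' @param county county label.
#' @param known_counties county labels considered valid (in addition to the
#'   NYC set); `NULL` disables the unknown-county warning.
#' @return one of `"rural"`, `"urban_non_nyc"`, `"nyc"`.
#' @export
classify_urbanicity <- function(rural_share, county, known_counties = NULL) {
  if (rural_share < 0 || rural_share > 1) stop("rural_share outside [0,1]")
  if (county %in% NYC_COUNTIES) return("nyc")
  if (!is.null(known_counties) && !(county %in% known_counties))
    warning("unknown county label '", county, "', treated as non-NYC")
  if (rural_share > 0.5) "rural" else "urban_non_nyc"
}

#' Classify every POL in a registry
#'
#' Computes each POL's interpolated rural share and applies
#' [classify_urbanicity()] with the registry's county labels (a POL's county
#' is taken as its area-majority county, which for the toy geometries is the
#' registry label itself).
#'
#' @param pol_table data.frame with `pol_id`, `county`.
#' @param block_groups data.frame with `bg_id`, `population`,
#'   `rural_population`.
#' @param crosswalk area crosswalk (see [compute_crosswalk()]).
#' @return data.frame `pol_id`, `rural_share`, `class`.
#' @export
classify_pols <- function(pol_table, block_groups, crosswalk) {
  share <- vapply(pol_table$pol_id, areal_interpolate_rural_share, 0,
                  block_groups = block_groups, crosswalk = crosswalk)
  cls <- vapply(seq_len(nrow(pol_table)), function(i)
    classify_urbanicity(share[i], pol_table$county[i]), character(1))
  data.frame(pol_id = pol_table$pol_id, rural_share = unname(share),
             class = cls, row.names = NULL)
}
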