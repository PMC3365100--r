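# Habitat assignment for each GPS fix: within 150 m (great-circle) of the
# bird's nest -> territory; otherwise by habitat-map polygon class,
# terrestrial -> salt marsh, intertidal -> mudflats. Territory takes
# precedence over polygon class.

#' Assign a habitat label to each GPS fix
#'
#' @param fixes Tibble with `bird_id`, `lat`, `lon`.
#' @param nests Tibble with `bird_id`, `lat`, `lon` (one nest per bird).
#' @param habitat Habitat polygon table (`class`, `geometry`), e.g. from
#'   [read_habitat_geojson()]; classes `terrestrial` and `intertidal`.
#' @param territory_radius_m Haversine distance to the nest (m) below
#'   which a fix counts as in-territory.
#' @return `fixes` with columns `habitat` (`"territory"`, `"salt marsh"`,
#'   `"mudflats"` or `"unclassified"`) and `nest_dist_m` appended. Fixes
#'   outside every polygon and outside the territory get
#'   `"unclassified"`, with a warning.
#' @export
assign_habitat <- function(fixes, nests, habitat,
                           territory_radius_m = 150) {
  stopifnot(all(c("bird_id", "lat", "lon") %in% names(fixes)),
            all(c("bird_id", "lat", "lon") %in% names(nests)))
  idx <- match(fixes$bird_id, nests$bird_id)
  if (anyNA(idx))
    stop("no nest coordinate for bird(s): ",
         paste(unique(fixes$bird_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  d <- geosphere::distHaversine(cbind(fixes$lon, fixes$lat),
                                cbind(nests$lon[idx], nests$lat[idx]))
  lab <- rep(NA_character_, nrow(fixes))
  for (i in seq_len(nrow(habitat))) {
    ring <- habitat$geometry[[i]]
    inside <- mgcv::in.out(ring, cbind(fixes$lon, fixes$lat))
    cls <- switch(habitat$class[i],
                  terrestrial = "salt marsh",
                  intertidal = "mudflats",
                  habitat$class[i])
    lab[is.na(lab) & inside] <- cls
  }
  lab[d <= territory_radius_m] <- "territory"
  if (anyNA(lab)) {
    warning(sum(is.na(lab)),
            " fix(es) outside all habitat polygons and territory; ",
            "labelled 'unclassified'")
    lab[is.na(lab)] <- "unclassified"
  }
  dplyr::mutate(fixes, habitat = lab, nest_dist_m = as.numeric(d))
}
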