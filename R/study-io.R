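# Plain-text study file set:
#   fixes.csv        bird_id,time_iso8601,lat,lon,alt_m,speed_ms
#   segments.csv     bird_id,start_time_iso8601,axis,s0..s59 (one row/axis)
#   observations.csv bird_id,start_time_iso8601,behaviour,sub_behaviour
#   nests.csv        bird_id,lat,lon
#   truth.csv        bird_id,time_iso8601,behaviour
#   habitat.geojson  FeatureCollection of polygons, property "class"
# Timestamps are UTC ISO-8601; coordinates WGS84 decimal degrees; empty
# speed fields mean "missing".

fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_time <- function(s) {
  out <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  if (anyNA(out) && !all(is.na(s) | s == "")) {
    bad <- which(is.na(out) & !(is.na(s) | s == ""))[1]
    stop("unparseable ISO-8601 timestamp at row ", bad, ": ", s[bad],
         call. = FALSE)
  }
  out
}

fmt_num <- function(x) {
  ifelse(is.na(x), "", formatC(x, digits = 15, format = "g"))
}

#' Write a synthetic study to a directory of plain-text files
#'
#' @param study A `synthetic_study` (see [simulate_study()]).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)

  fx <- study$fixes
  write_lines_csv(
    file.path(dir, "fixes.csv"),
    c("bird_id,time_iso8601,lat,lon,alt_m,speed_ms",
      if (nrow(fx)) paste(fx$bird_id, fmt_time(fx$time), fmt_num(fx$lat),
                          fmt_num(fx$lon), fmt_num(fx$alt_m),
                          fmt_num(fx$speed_ms), sep = ",")))

  sg <- study$segments
  seg_header <- paste0("bird_id,start_time_iso8601,axis,",
                       paste0("s", 0:59, collapse = ","))
  seg_rows <- character(0)
  if (nrow(sg)) {
    rows_axis <- function(axis) {
      vals <- vapply(sg[[tolower(axis)]],
                     function(v) paste(fmt_num(v), collapse = ","), "")
      paste(sg$bird_id, fmt_time(sg$start_time), axis, vals, sep = ",")
    }
    seg_rows <- as.vector(rbind(rows_axis("X"), rows_axis("Y"),
                                rows_axis("Z")))
  }
  write_lines_csv(file.path(dir, "segments.csv"), c(seg_header, seg_rows))

  ob <- study$observations
  write_lines_csv(
    file.path(dir, "observations.csv"),
    c("bird_id,start_time_iso8601,behaviour,sub_behaviour",
      if (nrow(ob)) paste(ob$bird_id, fmt_time(ob$start_time), ob$behaviour,
                          ob$sub_behaviour, sep = ",")))

  ns <- study$nests
  write_lines_csv(
    file.path(dir, "nests.csv"),
    c("bird_id,lat,lon",
      if (nrow(ns)) paste(ns$bird_id, fmt_num(ns$lat), fmt_num(ns$lon),
                          sep = ",")))

  tr <- study$truth
  write_lines_csv(
    file.path(dir, "truth.csv"),
    c("bird_id,time_iso8601,behaviour",
      if (nrow(tr)) paste(tr$bird_id, fmt_time(tr$time), tr$behaviour,
                          sep = ",")))

  write_habitat_geojson(study$habitat, file.path(dir, "habitat.geojson"))
  invisible(file.path(dir, c("fixes.csv", "segments.csv", "observations.csv",
                             "nests.csv", "truth.csv", "habitat.geojson")))
}

write_lines_csv <- function(path, lines) {
  con <- file(path, "wb")  # binary mode: identical bytes across platforms
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

#' Write a habitat polygon table as GeoJSON
#'
#' @param habitat Tibble with columns `class` and `geometry` (a list of
#'   two-column `lon`/`lat` matrices, closed rings).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_habitat_geojson <- function(habitat, path) {
  features <- lapply(seq_len(nrow(habitat)), function(i) {
    ring <- habitat$geometry[[i]]
    list(type = "Feature",
         properties = list(class = habitat$class[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(j) c(ring[j, 1], ring[j, 2])))))
  })
  json <- jsonlite::toJSON(list(type = "FeatureCollection",
                                features = features),
                           auto_unbox = TRUE, digits = NA)
  write_lines_csv(path, as.character(json))
  invisible(path)
}

#' Read a habitat GeoJSON file
#'
#' Expects a `FeatureCollection` of `Polygon` features with a `class`
#' property in `{terrestrial, intertidal}`; only the outer ring is used.
#'
#' @param path GeoJSON file path.
#' @return Tibble with columns `class` and `geometry` (list of lon/lat
#'   matrices).
#' @export
read_habitat_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  rows <- lapply(gj$features, function(f) {
    if (f$geometry$type != "Polygon")
      stop("only Polygon features are supported", call. = FALSE)
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("lon", "lat")
    list(class = f$properties$class, geometry = m)
  })
  tibble::tibble(class = vapply(rows, `[[`, "", "class"),
                 geometry = lapply(rows, `[[`, "geometry"))
}

read_csv_checked <- function(path, required) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop(basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

num_or_na <- function(s, what, path) {
  s[s == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(s))
  bad <- which(is.na(out) & !is.na(s))
  if (length(bad) > 0)
    stop(basename(path), " row ", bad[1], ": non-numeric ", what, " '",
         s[bad[1]], "'", call. = FALSE)
  out
}

#' Read a study directory
#'
#' Parses the plain-text study file set written by [write_study()] (or
#' prepared by hand in the same schemas) into time-sorted tibbles. Empty
#' speed fields become `NA` (missing), never zero. Segment axis rows are
#' re-nested into one row per segment with `x`, `y`, `z` list-columns.
#'
#' @param dir Directory containing `fixes.csv`, `segments.csv`,
#'   `observations.csv` and optionally `nests.csv`, `truth.csv`,
#'   `habitat.geojson`.
#' @return A list with tibbles `fixes`, `segments`, `observations`, and,
#'   when present, `nests`, `truth` and `habitat`.
#' @export
read_study <- function(dir) {
  fx_path <- file.path(dir, "fixes.csv")
  fx <- read_csv_checked(fx_path, c("bird_id", "time_iso8601", "lat", "lon",
                                    "alt_m", "speed_ms"))
  fixes <- tibble::tibble(
    bird_id = fx$bird_id,
    time = parse_time(fx$time_iso8601),
    lat = num_or_na(fx$lat, "lat", fx_path),
    lon = num_or_na(fx$lon, "lon", fx_path),
    alt_m = num_or_na(fx$alt_m, "alt_m", fx_path),
    speed_ms = num_or_na(fx$speed_ms, "speed", fx_path))
  if (any(fixes$lat < -90 | fixes$lat > 90, na.rm = TRUE) ||
      any(fixes$lon < -180 | fixes$lon > 180, na.rm = TRUE))
    stop("fixes.csv: coordinates outside WGS84 bounds", call. = FALSE)
  if (any(fixes$speed_ms < 0, na.rm = TRUE))
    stop("fixes.csv: negative speed", call. = FALSE)
  fixes <- dplyr::arrange(fixes, .data$bird_id, .data$time)

  sg_path <- file.path(dir, "segments.csv")
  sg <- read_csv_checked(sg_path, c("bird_id", "start_time_iso8601", "axis",
                                    paste0("s", 0:59)))
  segments <- nest_segment_rows(sg, sg_path)

  ob_path <- file.path(dir, "observations.csv")
  ob <- read_csv_checked(ob_path, c("bird_id", "start_time_iso8601",
                                    "behaviour", "sub_behaviour"))
  if (nrow(ob)) {
    v <- .vocab()
    key_ok <- paste(ob$behaviour, ob$sub_behaviour) %in%
      paste(v$behaviour, v$sub_behaviour)
    if (!all(key_ok))
      stop("observations.csv row ", which(!key_ok)[1],
           ": behaviour/sub-behaviour pair not in the vocabulary: ",
           ob$behaviour[!key_ok][1], " / ", ob$sub_behaviour[!key_ok][1],
           call. = FALSE)
  }
  observations <- tibble::tibble(
    bird_id = ob$bird_id, start_time = parse_time(ob$start_time_iso8601),
    behaviour = ob$behaviour, sub_behaviour = ob$sub_behaviour)
  observations <- dplyr::arrange(observations, .data$bird_id,
                                 .data$start_time)

  out <- list(fixes = fixes, segments = segments,
              observations = observations)

  ns_path <- file.path(dir, "nests.csv")
  if (file.exists(ns_path)) {
    ns <- read_csv_checked(ns_path, c("bird_id", "lat", "lon"))
    out$nests <- tibble::tibble(bird_id = ns$bird_id,
                                lat = num_or_na(ns$lat, "lat", ns_path),
                                lon = num_or_na(ns$lon, "lon", ns_path))
  }
  tr_path <- file.path(dir, "truth.csv")
  if (file.exists(tr_path)) {
    tr <- read_csv_checked(tr_path, c("bird_id", "time_iso8601",
                                      "behaviour"))
    assert_behaviour(tr$behaviour)
    out$truth <- dplyr::arrange(
      tibble::tibble(bird_id = tr$bird_id,
                     time = parse_time(tr$time_iso8601),
                     behaviour = tr$behaviour),
      .data$bird_id, .data$time)
  }
  hb_path <- file.path(dir, "habitat.geojson")
  if (file.exists(hb_path)) out$habitat <- read_habitat_geojson(hb_path)
  out
}

nest_segment_rows <- function(sg, path) {
  if (nrow(sg) == 0) {
    return(tibble::tibble(bird_id = character(), start_time = parse_time(character()),
                          rate = numeric(), duration = numeric(),
                          x = list(), y = list(), z = list()))
  }
  if (!all(sg$axis %in% c("X", "Y", "Z")))
    stop(basename(path), ": axis must be X, Y or Z", call. = FALSE)
  smat <- as.matrix(sg[paste0("s", 0:59)])
  samples <- lapply(seq_len(nrow(sg)), function(i)
    num_or_na(smat[i, ], "sample", path))
  key <- paste(sg$bird_id, sg$start_time_iso8601)
  pick <- function(axis) {
    idx <- which(sg$axis == axis)
    setNames(samples[idx], key[idx])
  }
  xs <- pick("X"); ys <- pick("Y"); zs <- pick("Z")
  ukey <- unique(key)
  if (!all(ukey %in% names(xs)) || !all(ukey %in% names(ys)) ||
      !all(ukey %in% names(zs)))
    stop(basename(path), ": each segment needs one X, Y and Z row",
         call. = FALSE)
  first <- !duplicated(key)
  seg <- tibble::tibble(
    bird_id = sg$bird_id[first],
    start_time = parse_time(sg$start_time_iso8601[first]),
    rate = 20, duration = 3,
    x = unname(xs[key[first]]), y = unname(ys[key[first]]),
    z = unname(zs[key[first]]))
  dplyr::arrange(seg, .data$bird_id, .data$start_time)
}
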