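# Village sampling tables and their expansion into occurrence point sets.
# The district is the modelling unit: each village centre is expanded into
# 10 presence points (the GPS point plus nine random surrounding points
# within a 1.2 km^2 neighbourhood), so a district contributes 10 points per
# village.

#' Parse and validate a village sampling table
#'
#' Expects a CSV with (case-insensitive) columns
#' `district, village, latitude, longitude, altitude, agroecology`.
#'
#' @param path CSV path.
#' @return data.frame of validated rows with class `sampling_table`.
#' @export
parse_sampling_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("district", "village", "latitude", "longitude", "altitude",
            "agroecology")
  if (!all(need %in% names(tab))) {
    stop("sampling table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[need]
  if (!is.numeric(tab$latitude) || !is.numeric(tab$longitude) ||
      !is.numeric(tab$altitude)) {
    stop("latitude, longitude and altitude must be numeric", call. = FALSE)
  }
  dup <- duplicated(tab[c("district", "village")])
  if (any(dup)) {
    stop("duplicate (district, village) pair(s): ",
         paste(unique(paste(tab$district[dup], tab$village[dup], sep = "/")),
               collapse = ", "), call. = FALSE)
  }
  if (any(tab$latitude < -90 | tab$latitude > 90)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  if (any(tab$longitude < -180 | tab$longitude > 180)) {
    stop("longitude out of range [-180, 180]", call. = FALSE)
  }
  if (any(tab$altitude < 0)) stop("negative altitude", call. = FALSE)
  class(tab) <- c("sampling_table", "data.frame")
  tab
}

#' The packaged Tigray sampling-site transcription
#'
#' A verbatim transcription of the study's 16-district, 32-village sampling
#' table, including its printed agro-ecology labels (kept as printed even
#' where they disagree with the altitude thresholds of
#' [classify_altitude()]).
#'
#' @return A `sampling_table` data.frame with 32 rows.
#' @export
tigray_sampling_table <- function() {
  parse_sampling_table(system.file("extdata", "tigray_sampling_table.csv",
                                   package = "enmecotype", mustWork = TRUE))
}

#' The packaged environmental variable registry
#'
#' The 34 candidate environmental and landscape variables: 22 climatic
#' (bio1-bio19, two water-vapour-pressure layers, elevation), 8 soil and
#' 4 vegetation/land-cover (one of them categorical).
#'
#' @return data.frame with columns `name, group, kind, units, description`.
#' @export
variable_registry <- function() {
  utils::read.csv(system.file("extdata", "variable_registry.csv",
                              package = "enmecotype", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

# metres per degree of latitude/longitude at latitude phi (degrees);
# spherical-earth local scale, adequate at village extent
metres_per_degree <- function(lat) {
  list(lat = 111320, lon = 111320 * cos(lat * pi / 180))
}

#' Expand a village centre into an occurrence point set
#'
#' Returns the centre plus `n_extra` points drawn uniformly at random in a
#' square of area `area_km2` centred on the village (planar approximation at
#' the village latitude). Deterministic for a fixed seed.
#'
#' @param lon,lat village centre (degrees).
#' @param n_extra number of additional points (default 9, for 10 per village).
#' @param area_km2 area of the expansion square in km^2 (default 1.2).
#' @param seed integer seed.
#' @return data.frame `lon, lat, is_center`.
#' @export
expand_village <- function(lon, lat, n_extra = 9, area_km2 = 1.2, seed = 1) {
  stopifnot(n_extra >= 0, area_km2 > 0)
  side_km <- sqrt(area_km2)
  mpd <- metres_per_degree(lat)
  half_lon <- side_km * 1000 / 2 / mpd$lon
  half_lat <- side_km * 1000 / 2 / mpd$lat
  extra <- with_seed(seed, {
    data.frame(lon = runif(n_extra, lon - half_lon, lon + half_lon),
               lat = runif(n_extra, lat - half_lat, lat + half_lat))
  })
  out <- rbind(data.frame(lon = lon, lat = lat),
               extra)
  out$is_center <- c(TRUE, rep(FALSE, n_extra))
  out
}

#' Expand all villages of a district into an occurrence set
#'
#' The district seed is derived from the global seed and the district label
#' by [stable_seed()], then per-village seeds from the district seed and the
#' village label, so occurrence sets are independent across districts and
#' stable under adding or removing other districts.
#'
#' @param table a `sampling_table`.
#' @param district district label present in `table`.
#' @param n_extra,area_km2 see [expand_village()].
#' @param seed global integer seed.
#' @return data.frame `lon, lat, district, village, is_center` with
#'   `n_villages * (n_extra + 1)` rows; attribute `seed` records the district
#'   seed used.
#' @export
expand_district <- function(table, district, n_extra = 9, area_km2 = 1.2,
                            seed = 1) {
  rows <- table[table$district == district, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("unknown district: ", district, call. = FALSE)
  }
  dseed <- stable_seed(seed, district)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    p <- expand_village(rows$longitude[i], rows$latitude[i],
                        n_extra = n_extra, area_km2 = area_km2,
                        seed = stable_seed(dseed, rows$village[i]))
    p$district <- district
    p$village <- rows$village[i]
    p
  }))
  out <- out[c("lon", "lat", "district", "village", "is_center")]
  attr(out, "seed") <- dseed
  out
}

#' Expand every district of a sampling table
#'
#' @inheritParams expand_district
#' @return Named list of per-district occurrence data.frames, in the order
#'   districts first appear in the table.
#' @export
expand_all_districts <- function(table, n_extra = 9, area_km2 = 1.2,
                                 seed = 1) {
  ds <- unique(table$district)
  setNames(lapply(ds, expand_district, table = table, n_extra = n_extra,
                  area_km2 = area_km2, seed = seed), ds)
}

#' Classify altitude into agro-ecological zones
#'
#' Lowland below 1,500 m a.s.l., midland from 1,500 to 2,300 m (closed
#' interval), highland above 2,300 m. Informational only: a printed sampling
#' table's own labels take precedence when echoing it.
#'
#' @param altitude altitude(s) in metres above sea level; must be >= 0.
#' @return Character vector of `"Lowland"`, `"Midland"`, `"Highland"`.
#' @export
classify_altitude <- function(altitude) {
  stopifnot(is.numeric(altitude))
  if (any(altitude < 0)) stop("negative altitude", call. = FALSE)
  ifelse(altitude < 1500, "Lowland",
         ifelse(altitude <= 2300, "Midland", "Highland"))
}
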