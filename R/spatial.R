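## Geodesic distance matrices between site centroids.

EARTH_RADIUS_KM <- 6371.0088  # IUGG mean radius

#' Geodesic distance matrix between site centroids
#'
#' Pairwise distances in kilometres between sites given as decimal-degree
#' centroids. `haversine` (default) uses the great-circle distance on the
#' mean-radius sphere (R = 6371.0088 km); `ellipsoidal` uses WGS84 geodesics.
#' The matrix is exactly symmetric with a zero diagonal. Duplicate
#' coordinates are allowed but flagged with a warning, because zero
#' off-diagonal distances carry no information for a distance-increase fit.
#'
#' @param coords data frame with columns `site_id`, `lon`, `lat` (decimal
#'   degrees; lon in \[-180, 180\], lat in \[-90, 90\]).
#' @param method `"haversine"` or `"ellipsoidal"`.
#' @return symmetric n x n matrix of distances in km, site ids as dimnames.
#' @examples
#' pts <- data.frame(site_id = c("a", "b"), lon = c(0, 1), lat = c(0, 0))
#' geodesic_matrix(pts)["a", "b"]  # 111.1949 km
#' @export
geodesic_matrix <- function(coords, method = c("haversine", "ellipsoidal")) {
  method <- match.arg(method)
  coords <- validate_coords(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 sites", call. = FALSE)
  xy <- as.matrix(coords[, c("lon", "lat")])
  m <- matrix(0, n, n, dimnames = list(coords$site_id, coords$site_id))
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    d <- switch(method,
      haversine = geosphere::distHaversine(xy[i, ], xy[js, , drop = FALSE],
                                           r = EARTH_RADIUS_KM),
      ellipsoidal = geosphere::distGeo(xy[i, ], xy[js, , drop = FALSE]) / 1000)
    m[i, js] <- d
    m[js, i] <- d
  }
  if (any(m[upper.tri(m)] == 0))
    warning("duplicate coordinates detected: some off-diagonal distances are zero",
            call. = FALSE)
  m
}

validate_coords <- function(coords) {
  coords <- as.data.frame(coords)
  need <- c("site_id", "lon", "lat")
  if (!all(need %in% names(coords)))
    stop("coordinates need columns site_id, lon, lat", call. = FALSE)
  if (anyDuplicated(coords$site_id))
    stop("duplicate site ids in coordinates", call. = FALSE)
  if (anyNA(coords$lon) || anyNA(coords$lat) ||
      any(coords$lon < -180 | coords$lon > 180) ||
      any(coords$lat < -90 | coords$lat > 90))
    stop("coordinates out of bounds: lon must be in [-180, 180], lat in [-90, 90]",
         call. = FALSE)
  coords$site_id <- as.character(coords$site_id)
  coords
}
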