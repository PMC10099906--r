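# Spherical geometry on a sphere of radius 6371 km. All functions are
# vectorized over their coordinate arguments and work in degrees.

EARTH_RADIUS_KM <- 6371.0

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorized over all
#' four coordinate arguments.
#'
#' @param lon1,lat1 Coordinates of the first point(s), decimal degrees.
#' @param lon2,lat2 Coordinates of the second point(s), decimal degrees.
#' @return Distance(s) in kilometres.
#' @examples
#' great_circle_distance(0, 0, 0, 1) # one degree of latitude, ~111.19 km
#' @export
great_circle_distance <- function(lon1, lat1, lon2, lat2) {
  phi1 <- deg2rad(lat1)
  phi2 <- deg2rad(lat2)
  dphi <- phi2 - phi1
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(a, 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial great-circle bearing
#'
#' Bearing at the first point of the great circle towards the second,
#' degrees clockwise from north in `[0, 360)`.
#'
#' @inheritParams great_circle_distance
#' @return Bearing(s) in degrees.
#' @export
initial_bearing <- function(lon1, lat1, lon2, lat2) {
  phi1 <- deg2rad(lat1)
  phi2 <- deg2rad(lat2)
  dlam <- deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
  (rad2deg(atan2(y, x)) + 360) %% 360
}

#' Destination point along a great circle
#'
#' Point reached after travelling `dist_km` from (`lon`, `lat`) on the
#' initial bearing `bearing`.
#'
#' @param lon,lat Start coordinates, decimal degrees.
#' @param bearing Initial bearing, degrees clockwise from north.
#' @param dist_km Distance travelled, km.
#' @return A list with components `lon` and `lat` (degrees, lon in
#'   `[-180, 180)`).
#' @export
destination_point <- function(lon, lat, bearing, dist_km) {
  phi1 <- deg2rad(lat)
  lam1 <- deg2rad(lon)
  theta <- deg2rad(bearing)
  delta <- dist_km / EARTH_RADIUS_KM
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(theta))
  lam2 <- lam1 + atan2(
    sin(theta) * sin(delta) * cos(phi1),
    cos(delta) - sin(phi1) * sin(phi2)
  )
  lon2 <- (rad2deg(lam2) + 180) %% 360 - 180
  list(lon = lon2, lat = rad2deg(phi2))
}

# Spherical linear interpolation between two points at fractions f in [0, 1].
# Exact great-circle parameterization via 3-D unit vectors.
slerp_point <- function(lon1, lat1, lon2, lat2, f) {
  to_xyz <- function(lon, lat) {
    phi <- deg2rad(lat)
    lam <- deg2rad(lon)
    cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
  }
  a <- to_xyz(lon1, lat1)[1, ]
  b <- to_xyz(lon2, lat2)[1, ]
  omega <- acos(max(-1, min(1, sum(a * b))))
  if (omega < 1e-12) {
    xyz <- matrix(a, nrow = length(f), ncol = 3, byrow = TRUE)
  } else {
    w1 <- sin((1 - f) * omega) / sin(omega)
    w2 <- sin(f * omega) / sin(omega)
    xyz <- outer(w1, a) + outer(w2, b)
    xyz <- xyz / sqrt(rowSums(xyz^2))
  }
  list(
    lon = (rad2deg(atan2(xyz[, 2], xyz[, 1])) + 180) %% 360 - 180,
    lat = rad2deg(asin(pmax(-1, pmin(1, xyz[, 3]))))
  )
}

# Signed angular difference b - a wrapped to (-180, 180].
angle_diff <- function(a, b) {
  d <- (b - a) %% 360
  ifelse(d > 180, d - 360, d)
}
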