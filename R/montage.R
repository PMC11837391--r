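#' Generic spherical EEG montage
#'
#' Places `n_channels` sensors quasi-uniformly on the upper portion of the
#' unit sphere (Fibonacci lattice over a spherical cap), emulating a
#' high-density net with cheek/neck rows already excluded.  The default of
#' 110 channels mirrors a 129-electrode net with 19 peripheral channels
#' dropped.
#'
#' @param n_channels number of sensors (>= 4; default 110).
#' @param cap_zmin lowest z (inferior limit) of the cap; -0.05 keeps
#'   sensors just below the equator, like a child net without cheek leads.
#' @return list with `positions` [n x 3] unit vectors, `labels`, and
#'   `adjacency` (symmetric logical matrix, zero diagonal).
#' @export
make_montage <- function(n_channels = 110, cap_zmin = -0.05) {
  stopifnot(n_channels >= 4)
  i <- seq_len(n_channels)
  z <- seq(cap_zmin, 1 - 0.5 / n_channels, length.out = n_channels)
  golden <- pi * (3 - sqrt(5))
  theta <- golden * (i - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(theta), y = r * sin(theta), z = z)
  adj <- adjacency_from_positions(pos)
  list(positions = pos,
       labels = sprintf("E%03d", i),
       adjacency = adj)
}

#' Sensor adjacency from 3-D positions
#'
#' Neighbourhood graph by great-circle distance threshold: two sensors are
#' adjacent when closer than `factor` times the median nearest-neighbour
#' distance.  Every sensor is guaranteed at least its single nearest
#' neighbour, so no channel is isolated.
#'
#' @param positions [n x 3] matrix of unit vectors.
#' @param factor distance threshold multiplier (default 1.3).
#' @return symmetric logical matrix with zero diagonal.
#' @export
adjacency_from_positions <- function(positions, factor = 1.3) {
  n <- nrow(positions)
  g <- positions %*% t(positions)
  g[g > 1] <- 1; g[g < -1] <- -1
  d <- acos(g)
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  thr <- factor * stats::median(nn)
  adj <- d <= thr
  # guarantee the nearest neighbour edge
  for (i in seq_len(n)) {
    j <- which.min(d[i, ])
    adj[i, j] <- TRUE; adj[j, i] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  adj
}

#' Smooth scalp topography centred on a seed direction
#'
#' Gaussian fall-off in great-circle distance from a seed unit vector;
#' used to give generated response kernels a realistic spatial profile.
#'
#' @param positions [n x 3] sensor unit vectors.
#' @param seed_dir length-3 unit vector (centre of the patch).
#' @param width_rad Gaussian width in radians (default 0.6).
#' @return numeric vector of channel weights in [0, 1].
#' @export
topography <- function(positions, seed_dir, width_rad = 0.6) {
  seed_dir <- seed_dir / sqrt(sum(seed_dir^2))
  cosd <- pmin(1, pmax(-1, positions %*% seed_dir))
  as.numeric(exp(-(acos(cosd)^2) / (2 * width_rad^2)))
}
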