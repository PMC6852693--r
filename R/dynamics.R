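#' Simulate latent multi-season occupancy dynamics
#'
#' Draws the latent occupancy state of \code{nSites} independent sites over
#' \code{nSeasons} seasons. Season-1 occupancy is Bernoulli(\code{psi});
#' thereafter the process is first-order Markov: an occupied site stays
#' occupied with probability \code{1 - epsilon} and an unoccupied site is
#' colonized with probability \code{gamma}.
#'
#' @param params A [DynamicsParams-class] object.
#' @param nSites Number of sites (>= 1).
#' @param nSeasons Number of seasons (>= 1); default 2.
#' @return An [OccupancyState-class] object.
#' @examples
#' set.seed(1)
#' occ <- simulateOccupancy(DynamicsParams(0.6, 0.25, 0.25), nSites = 100)
#' colMeans(occupancyMatrix(occ))
#' @export
simulateOccupancy <- function(params, nSites, nSeasons = 2L) {
  stopifnot(is(params, "DynamicsParams"))
  validObject(params)
  if (!is.numeric(nSites) || length(nSites) != 1L || nSites < 1)
    stop("'nSites' must be a single integer >= 1")
  if (!is.numeric(nSeasons) || length(nSeasons) != 1L || nSeasons < 1)
    stop("'nSeasons' must be a single integer >= 1")
  nSites <- as.integer(nSites)
  nSeasons <- as.integer(nSeasons)

  z <- matrix(0L, nSites, nSeasons)
  z[, 1L] <- stats::rbinom(nSites, 1L, params@psi)
  if (nSeasons > 1L) {
    for (s in seq_len(nSeasons - 1L)) {
      prev <- z[, s]
      p <- prev * (1 - params@epsilon) + (1 - prev) * params@gamma
      z[, s + 1L] <- stats::rbinom(nSites, 1L, p)
    }
  }
  dimnames(z) <- list(site = NULL, season = NULL)
  OccupancyState(z = z)
}

#' Marginal occupancy probability for a season
#'
#' Closed-form marginal occupancy probability implied by the dynamics:
#' psi for season 1, then the recursion
#' \code{psi[s+1] = psi[s] * (1 - epsilon) + (1 - psi[s]) * gamma}.
#'
#' @param params A [DynamicsParams-class] object.
#' @param season Season index (>= 1).
#' @return The marginal occupancy probability.
#' @examples
#' seasonOccupancyProb(DynamicsParams(0.6, 0.25, 0.25), 2)  # 0.55
#' @export
seasonOccupancyProb <- function(params, season) {
  stopifnot(is(params, "DynamicsParams"))
  validObject(params)
  if (!is.numeric(season) || length(season) != 1L || season < 1)
    stop("'season' must be a single integer >= 1")
  p <- params@psi
  s <- 1L
  while (s < season) {
    p <- p * (1 - params@epsilon) + (1 - p) * params@gamma
    s <- s + 1L
  }
  p
}

#' Export an occupancy matrix as a long table
#'
#' @param occ An [OccupancyState-class] object.
#' @return A \code{data.frame} with columns \code{site_id}, \code{season},
#'   \code{occupied}.
#' @export
occupancyTable <- function(occ) {
  stopifnot(is(occ, "OccupancyState"))
  z <- occ@z
  data.frame(site_id = rep(seq_len(nrow(z)), times = ncol(z)),
             season = rep(seq_len(ncol(z)), each = nrow(z)),
             occupied = as.integer(z))
}
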