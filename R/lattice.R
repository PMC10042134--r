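#' Build the spherical GC lattice
#'
#' Enumerates all integer lattice sites within a sphere of the configured
#' radius (in units of the lattice spacing) and labels the two hemispheres:
#' light zone (LZ, z >= 0, hosting FDC sites and Tfh cells) and dark zone
#' (DZ, z < 0). Mobile agents occupy at most one per site; FDC dendrites are
#' a site property and do not block movement.
#'
#' @param radius_um sphere radius in micrometers.
#' @param spacing_um lattice spacing in micrometers.
#' @param neighborhood `"moore"` (26 neighbors) or `"vonneumann"` (6).
#' @return an object of class `gc_lattice`: list with `coords` (n x 3 integer
#'   matrix, lattice units), `zone` (factor `"DZ"`/`"LZ"`), `occupancy`
#'   (integer vector, `NA` = free), `spacing_um`, `neighborhood`.
#' @export
build_lattice <- function(radius_um = 160, spacing_um = 5,
                          neighborhood = c("moore", "vonneumann")) {
  neighborhood <- match.arg(neighborhood)
  if (radius_um <= 0 || spacing_um <= 0) {
    stop("lattice radius and spacing must be positive")
  }
  k <- floor(radius_um / spacing_um)
  ax <- -k:k
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  keep <- rowSums(g^2) <= (radius_um / spacing_um)^2
  coords <- g[keep, , drop = FALSE]
  storage.mode(coords) <- "integer"
  out <- structure(
    list(
      coords = coords,
      zone = factor(ifelse(coords[, "z"] >= 0L, "LZ", "DZ"),
                    levels = c("DZ", "LZ")),
      occupancy = rep(NA_integer_, nrow(coords)),
      spacing_um = spacing_um,
      neighborhood = neighborhood
    ),
    class = "gc_lattice"
  )
  out$lookup <- .site_lookup(out)
  out
}

#' @export
print.gc_lattice <- function(x, ...) {
  cat(sprintf("<gc_lattice> %d sites (%d DZ / %d LZ), spacing %g um, %s neighborhood\n",
              nrow(x$coords), sum(x$zone == "DZ"), sum(x$zone == "LZ"),
              x$spacing_um, x$neighborhood))
  invisible(x)
}

.neighbor_offsets <- function(neighborhood) {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
  if (neighborhood == "vonneumann") o <- o[rowSums(abs(o)) == 1, , drop = FALSE]
  o
}

.site_lookup <- function(lattice) {
  co <- lattice$coords
  k <- max(abs(co))
  w <- 2L * k + 1L
  idx <- rep(NA_integer_, w^3)
  key <- (co[, 1] + k) + w * ((co[, 2] + k) + w * (co[, 3] + k)) + 1L
  idx[key] <- seq_len(nrow(co))
  list(idx = idx, k = k, w = w)
}

.neighbor_sites <- function(lattice, site, lookup = lattice$lookup) {
  off <- .neighbor_offsets(lattice$neighborhood)
  p <- lattice$coords[site, ]
  nb <- sweep(off, 2L, as.integer(p), `+`)
  k <- lookup$k; w <- lookup$w
  ok <- apply(abs(nb) <= k, 1L, all)
  nb <- nb[ok, , drop = FALSE]
  key <- (nb[, 1] + k) + w * ((nb[, 2] + k) + w * (nb[, 3] + k)) + 1L
  s <- lookup$idx[key]
  s[!is.na(s)]
}

#' Place an agent on the lattice
#'
#' @param lattice a [build_lattice()] object.
#' @param agent_id positive integer identity.
#' @param site site index; default: a uniformly drawn free site (optionally
#'   restricted to a zone).
#' @param zone optional `"DZ"` or `"LZ"` restriction for random placement.
#' @return the updated lattice.
#' @export
place_agent <- function(lattice, agent_id, site = NULL, zone = NULL) {
  if (is.null(site)) {
    free <- which(is.na(lattice$occupancy))
    if (!is.null(zone)) free <- free[lattice$zone[free] == zone]
    if (!length(free)) stop("no free site available")
    site <- free[sample.int(length(free), 1L)]
  }
  if (!is.na(lattice$occupancy[site])) stop("site ", site, " already occupied")
  lattice$occupancy[site] <- as.integer(agent_id)
  lattice
}

#' Agents and FDC sites in contact with an agent
#'
#' Contact is adjacency in the configured neighborhood (Moore 26-site by
#' default). Contacts are symmetric: `a` is in contact with `b` iff `b` is in
#' contact with `a`.
#'
#' @param lattice a lattice with occupancy.
#' @param site the focal agent's site index.
#' @return integer vector of occupied neighboring site indices.
#' @export
contacts <- function(lattice, site) {
  nb <- .neighbor_sites(lattice, site)
  nb[!is.na(lattice$occupancy[nb])]
}

#' One random-walk step of a mobile agent
#'
#' The agent attempts one move to an adjacent free site. When outside its
#' target zone it is biased toward it (with probability `bias` only
#' zone-approaching directions are considered); when inside, moves that would
#' leave the zone are rejected. Blocked moves are legal no-ops.
#'
#' @param lattice a lattice with occupancy.
#' @param site the agent's current site.
#' @param target_zone `"DZ"`, `"LZ"`, or `NULL` for an unbiased, unconfined
#'   walk.
#' @param bias probability of restricting to zone-approaching directions
#'   when outside the target zone.
#' @return the new site index (possibly unchanged).
#' @export
random_walk_step <- function(lattice, site, target_zone = NULL, bias = 0.9) {
  lookup <- lattice$lookup
  off <- .neighbor_offsets(lattice$neighborhood)
  in_target <- is.null(target_zone) || lattice$zone[site] == target_zone
  if (!in_target && stats::runif(1) < bias) {
    want <- if (target_zone == "LZ") 1L else -1L
    off <- off[off[, "dz"] == want, , drop = FALSE]
  }
  d <- off[sample.int(nrow(off), 1L), ]
  p <- lattice$coords[site, ] + d
  k <- lookup$k; w <- lookup$w
  if (any(abs(p) > k)) return(site)
  s <- lookup$idx[(p[1] + k) + w * ((p[2] + k) + w * (p[3] + k)) + 1L]
  if (is.na(s) || !is.na(lattice$occupancy[s])) return(site)
  if (in_target && !is.null(target_zone) && lattice$zone[s] != target_zone) {
    return(site)
  }
  s
}
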