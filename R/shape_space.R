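#' Shape-space representation of B-cell receptors and antigen
#'
#' B-cell receptors (BCRs) and the antigen epitope are points on an abstract
#' integer lattice ("shape space") of dimension `dim` with coordinates in
#' `0..side-1`. The mutation distance between two points is the L1
#' (city-block) distance; somatic hypermutation moves a point by one unit in
#' one randomly chosen dimension. Affinity is a Gaussian-type function of
#' mutation distance to the antigen's optimal point.
#'
#' @param coords integer vector of coordinates.
#' @param dim,side shape-space dimension and side length.
#' @return `shape_point()` returns a validated integer vector.
#' @examples
#' p <- shape_point(c(5, 5, 5, 5))
#' mutation_distance(p, shape_point(c(4, 5, 5, 7)))
#' @export
shape_point <- function(coords, dim = length(coords), side = 10L) {
  coords <- as.integer(coords)
  if (length(coords) != dim) {
    stop("shape point has ", length(coords), " coordinates, expected ", dim)
  }
  if (anyNA(coords) || any(coords < 0L) || any(coords >= side)) {
    stop("shape point coordinates must lie in [0, ", side - 1L, "]")
  }
  coords
}

#' Mutation distance between two shape points
#'
#' L1 (city-block) distance, the number of single-unit mutations separating
#' two receptor sequences in shape space.
#'
#' @param p,q integer coordinate vectors of equal length.
#' @return non-negative integer.
#' @export
mutation_distance <- function(p, q) {
  if (length(p) != length(q)) {
    stop("shape points have different dimensions (", length(p), " vs ",
         length(q), ")")
  }
  sum(abs(as.integer(p) - as.integer(q)))
}

#' Affinity model: Gaussian mapping from mutation distance to binding probability
#'
#' Affinity `exp(-(d/gamma)^eta)` is 1 at zero distance and strictly
#' decreasing; it is used directly as the per-encounter antigen-binding
#' probability. Defaults `gamma = 2.8`, `eta = 2` place founder cells drawn at
#' distance 5-6 in the low-but-viable binding range (~0.01-0.04).
#'
#' @param optimal the antigen's optimal point (a [shape_point()]).
#' @param gamma width of the affinity function (shape-space distance units).
#' @param eta exponent (dimensionless); 2 gives a Gaussian.
#' @param side lattice side length.
#' @return an object of class `affinity_model`.
#' @export
affinity_model <- function(optimal = shape_point(rep(5L, 4L)),
                           gamma = 2.8, eta = 2, side = 10L) {
  stopifnot(gamma > 0, eta > 0)
  structure(
    list(optimal = shape_point(optimal, side = side),
         gamma = gamma, eta = eta, side = as.integer(side)),
    class = "affinity_model"
  )
}

#' @rdname affinity_model
#' @param d non-negative mutation distance(s).
#' @param model an `affinity_model`.
#' @return `affinity()` returns values in (0, 1].
#' @export
affinity <- function(d, model = affinity_model()) {
  stopifnot(all(d >= 0))
  exp(-(d / model$gamma)^model$eta)
}

#' @rdname affinity_model
#' @param p a shape point (a BCR position).
#' @return `bcr_affinity()` returns the affinity of a BCR for the model's
#'   optimal point.
#' @export
bcr_affinity <- function(p, model = affinity_model()) {
  affinity(mutation_distance(p, model$optimal), model)
}

#' Somatic hypermutation operator
#'
#' Shifts exactly one randomly chosen coordinate by +1 or -1; shifts that
#' would leave `[0, side-1]` are redrawn, so the result is always a valid
#' lattice point at L1 distance exactly 1 from the input.
#'
#' @param p a shape point.
#' @param side lattice side length.
#' @return a mutated copy of `p`.
#' @export
mutate_bcr <- function(p, side = 10L) {
  p <- as.integer(p)
  repeat {
    i <- sample.int(length(p), 1L)
    delta <- if (stats::runif(1) < 0.5) -1L else 1L
    v <- p[i] + delta
    if (v >= 0L && v < side) {
      p[i] <- v
      return(p)
    }
  }
}

# Number of lattice points at each L1 distance 0..dmax from `optimal`,
# respecting per-dimension bounds. Column d+1 of the returned matrix holds,
# for the partial lattice over dimensions 1..k, the count at distance d
# (row k). Used for uniform sampling over a distance shell.
.shell_counts <- function(optimal, side, dmax) {
  ndim <- length(optimal)
  counts <- matrix(0, nrow = ndim + 1L, ncol = dmax + 1L)
  counts[1L, 1L] <- 1
  for (k in seq_len(ndim)) {
    lo <- -optimal[k]
    hi <- side - 1L - optimal[k]
    for (d in 0:dmax) {
      tot <- 0
      for (o in lo:hi) {
        r <- d - abs(o)
        if (r >= 0L) tot <- tot + counts[k, r + 1L]
      }
      counts[k + 1L, d + 1L] <- tot
    }
  }
  counts
}

#' Sample a founder-cell BCR at a prescribed mutation distance
#'
#' Draws the distance uniformly over the integer band `d_min..d_max`, then a
#' lattice point uniformly at random among all points at exactly that L1
#' distance from the model's optimal point (dynamic-programming shell
#' sampler). A band of `[5, 6]` corresponds to the default high-affinity
#' founder cells; `[6, 7]` and `[7, 8]` to intermediate and low affinity.
#'
#' @param model an [affinity_model()].
#' @param d_min,d_max inclusive integer band of mutation distances.
#' @return a shape point at distance in `[d_min, d_max]` from the optimum.
#' @export
sample_founder_position <- function(model = affinity_model(),
                                    d_min = 5L, d_max = 6L) {
  d_min <- as.integer(d_min); d_max <- as.integer(d_max)
  ndim <- length(model$optimal)
  side <- model$side
  if (d_min < 0L || d_max < d_min || d_max > ndim * (side - 1L)) {
    stop("invalid founder distance band [", d_min, ", ", d_max, "]")
  }
  counts <- .shell_counts(model$optimal, side, d_max)
  band <- d_min:d_max
  n_at <- counts[ndim + 1L, band + 1L]
  if (all(n_at == 0)) {
    stop("no lattice point at distance in [", d_min, ", ", d_max,
         "] from the optimal point")
  }
  # uniform over the band's distances that are realizable
  ok <- band[n_at > 0]
  d <- ok[sample.int(length(ok), 1L)]
  # backward pass: choose offset per dimension proportional to completions
  offs <- integer(ndim)
  rem <- d
  for (k in ndim:1) {
    lo <- -model$optimal[k]
    hi <- side - 1L - model$optimal[k]
    cand <- lo:hi
    w <- vapply(cand, function(o) {
      r <- rem - abs(o)
      if (r < 0L) 0 else counts[k, r + 1L]
    }, numeric(1))
    o <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L, prob = w)]
    offs[k] <- o
    rem <- rem - abs(o)
  }
  stopifnot(rem == 0L)
  shape_point(model$optimal + offs, side = side)
}
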