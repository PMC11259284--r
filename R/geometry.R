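#' Place neurons on a jittered square lattice
#'
#' N = m x m neurons sit on a regular square lattice of side length L with
#' spacing h = L/(m-1). The neuron at lattice index (ix, iy) has coordinates
#' x = (h/2)(2 ix - 1) + xi_x, y = (h/2)(2 iy - 1) + xi_y, where the jitters
#' xi are i.i.d. uniform on [-jitter_scale, +jitter_scale]. Neurons are
#' enumerated i = ix + (iy - 1) m.
#'
#' @param m lattice side count (>= 2)
#' @param L physical side length (mm)
#' @param jitter_scale jitter magnitude bound (mm); default 0.05 h
#' @param rng_seed optional integer seed for the jitter draws
#' @return an object of class \code{plast_geometry}: list with \code{m},
#'   \code{L}, \code{h}, \code{N}, \code{jitter_scale}, \code{positions}
#'   (N x 2 matrix, mm) and \code{distance} (N x N Euclidean distances, mm)
#' @export
place_neurons <- function(m, L = 1, jitter_scale = 0.05 * L / (m - 1),
                          rng_seed = NULL) {
  if (!is.numeric(m) || length(m) != 1 || m < 2 || m != round(m))
    stop("'m' must be an integer >= 2 (lattice spacing undefined otherwise)")
  stopifnot(L > 0, jitter_scale >= 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  m <- as.integer(m)
  N <- m * m
  h <- L / (m - 1)
  ix <- rep(seq_len(m), times = m)
  iy <- rep(seq_len(m), each = m)
  x <- h / 2 * (2 * ix - 1)
  y <- h / 2 * (2 * iy - 1)
  if (jitter_scale > 0) {
    x <- x + runif(N, -jitter_scale, jitter_scale)
    y <- y + runif(N, -jitter_scale, jitter_scale)
  }
  positions <- cbind(x = x, y = y)
  distance <- as.matrix(dist(positions))
  dimnames(distance) <- NULL
  geom <- list(m = m, L = L, h = h, N = N, jitter_scale = jitter_scale,
               positions = positions, distance = distance)
  class(geom) <- "plast_geometry"
  geom
}

#' Create an empty connectivity state
#'
#' @param N number of neurons
#' @return a \code{plast_conn} object: adjacency \code{A} (N x N, 0/1,
#'   A[i, j] = 1 for a contact from presynaptic j to postsynaptic i), weights
#'   \code{W} (defined only where A = 1), and \code{birth} (structural
#'   iteration at which each live contact appeared)
#' @export
empty_connectivity <- function(N) {
  conn <- list(A = matrix(0L, N, N), W = matrix(0, N, N),
               birth = matrix(NA_integer_, N, N), N = N, max_contacts = 1L)
  class(conn) <- "plast_conn"
  conn
}

#' Wire a random distance-dependent network at a prescribed density
#'
#' Each ordered pair (i, j), i != j, is connected independently with
#' probability p_ij = c * exp(-l_ij / l0). The constant c is chosen so that
#' the expected density (mean node degree density) equals \code{beta0}:
#' c = beta0 / mean(exp(-l/l0)) over all ordered pairs. An error is raised if
#' that would push any pair probability above 1 (density not achievable with
#' this kernel).
#'
#' @param geometry a \code{plast_geometry}
#' @param beta0 desired average node degree density in [0, 1]
#' @param l0 distance decay constant (mm); use \code{Inf} for
#'   distance-independent wiring
#' @param rng_seed optional integer seed
#' @return a \code{plast_conn} with weights 0 and birth iteration 0
#' @export
random_connectivity <- function(geometry, beta0, l0 = 0.5 * geometry$L,
                                rng_seed = NULL) {
  stopifnot(inherits(geometry, "plast_geometry"))
  if (!is.numeric(beta0) || beta0 < 0 || beta0 > 1)
    stop("'beta0' must lie in [0, 1]")
  stopifnot(l0 > 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  N <- geometry$N
  off <- !diag(TRUE, N)
  kern <- exp(-geometry$distance / l0)
  cnorm <- if (beta0 == 0) 0 else beta0 / mean(kern[off])
  p <- cnorm * kern
  if (any(p[off] > 1 + 1e-6))
    stop("density ", beta0, " not achievable with exponential kernel l0 = ", l0,
         ": required pair probability exceeds 1")
  p <- pmin(p, 1)
  conn <- empty_connectivity(N)
  draw <- matrix(runif(N * N), N, N)
  A <- (draw < p) & off
  conn$A[] <- as.integer(A)
  conn$birth[A] <- 0L
  conn
}

#' Assign initial weights to live contacts
#'
#' Live contacts receive i.i.d. weights uniform on
#' [max(0, 2 mean - 1), min(1, 2 mean)], a mean-preserving support inside
#' [0, 1]; entries without a contact are untouched.
#'
#' @param conn a \code{plast_conn}
#' @param mean_weight desired mean weight in [0, 1]
#' @param rng_seed optional integer seed
#' @return the updated \code{plast_conn}
#' @export
init_weights <- function(conn, mean_weight, rng_seed = NULL) {
  stopifnot(inherits(conn, "plast_conn"))
  if (!is.numeric(mean_weight) || mean_weight < 0 || mean_weight > 1)
    stop("'mean_weight' must lie in [0, 1]")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  live <- conn$A == 1L
  lo <- max(0, 2 * mean_weight - 1)
  hi <- min(1, 2 * mean_weight)
  conn$W[live] <- runif(sum(live), lo, hi)
  conn
}

#' @export
print.plast_geometry <- function(x, ...) {
  cat(sprintf("Square lattice: m = %d (N = %d), L = %g mm, h = %g mm, jitter <= %g mm\n",
              x$m, x$N, x$L, x$h, x$jitter_scale))
  invisible(x)
}

#' @export
print.plast_conn <- function(x, ...) {
  E <- sum(x$A)
  cat(sprintf("Directed connectivity: N = %d, contacts = %d, beta = %.4f\n",
              x$N, E, E / (x$N * (x$N - 1))))
  invisible(x)
}
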