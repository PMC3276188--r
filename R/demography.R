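#' Verhulst logistic-growth parameters
#'
#' Parameters of the deterministic logistic trajectory
#' N_t = N0 * K / (N0 + (K - N0) * exp(-r0 * t)) describing a population
#' expanding from N0 founders toward carrying capacity K. Time t is measured
#' in generations and r0 is the intrinsic growth rate per generation.
#'
#' @param N0 founder effective size (0 < N0 <= K).
#' @param K carrying capacity, in effective individuals per generation.
#' @param r0 intrinsic growth rate per generation (> 0).
#' @return Object of class `verhulst_params`.
#' @examples
#' verhulst_params(N0 = 12, K = 12000, r0 = 0.4)
#' @export
verhulst_params <- function(N0, K, r0) {
  if (N0 <= 0 || K <= 0 || N0 > K)
    stop("need 0 < N0 <= K")
  if (r0 <= 0) stop("'r0' must be positive")
  structure(list(N0 = N0, K = K, r0 = r0), class = "verhulst_params")
}

#' @export
print.verhulst_params <- function(x, ...) {
  cat(sprintf("Verhulst logistic growth: N0 = %g, K = %g, r0 = %g/generation\n",
              x$N0, x$K, x$r0))
  invisible(x)
}

#' Population size along the Verhulst trajectory
#'
#' @param params a [verhulst_params()].
#' @param t generation(s), numeric >= 0 (vectorised). Returned sizes are
#'   continuous; rounding is left to callers that need integer censuses.
#' @return Population size(s) N_t.
#' @examples
#' p <- verhulst_params(12, 12000, 0.4)
#' verhulst_size(p, 0)    # 12
#' verhulst_size(p, 1e6)  # -> K
#' @export
verhulst_size <- function(params, t) {
  stopifnot(inherits(params, "verhulst_params"))
  if (any(t < 0)) stop("'t' must be non-negative")
  with(params, N0 * K / (N0 + (K - N0) * exp(-r0 * t)))
}

#' Harmonic-mean effective size over the post-founding period
#'
#' The effective size of a population whose census fluctuates over T
#' generations is the harmonic mean T / sum_{t=1..T} (1 / N_t), which is
#' dominated by the small early sizes after a founding bottleneck. The sum
#' runs over generations 1..T (the t = 0 founder generation is excluded).
#'
#' @param params a [verhulst_params()].
#' @param T number of generations since founding (>= 1).
#' @return Object of class `ne_summary` with `ne` (harmonic mean),
#'   `trajectory` (N_t for t = 1..T) and `T`.
#' @examples
#' harmonic_mean_ne(verhulst_params(90, 12000, 0.4), 100)$ne  # ~3251
#' @export
harmonic_mean_ne <- function(params, T) {
  stopifnot(inherits(params, "verhulst_params"))
  if (T < 1) stop("'T' must be at least 1 generation")
  traj <- verhulst_size(params, seq_len(T))
  structure(list(ne = T / sum(1 / traj), trajectory = traj, T = T,
                 params = params),
            class = "ne_summary")
}

#' @export
print.ne_summary <- function(x, ...) {
  cat(sprintf(
    "Harmonic-mean Ne over %d generations: %.1f (census %.1f -> %.1f)\n",
    x$T, x$ne, x$trajectory[1], x$trajectory[x$T]))
  invisible(x)
}

#' Harmonic-mean Ne over a grid of demographic parameters
#'
#' Explores the sensitivity of the effective size to the founder size N0,
#' the growth rate r0 and the elapsed generations T, at fixed carrying
#' capacity, as done when bracketing Ne between slow-growth/small-founder and
#' fast-growth/large-founder scenarios.
#'
#' @param N0 vector of founder sizes.
#' @param r0 vector of growth rates per generation.
#' @param K carrying capacity (scalar).
#' @param T vector of generation counts.
#' @return data.frame with one row per (N0, r0, T) combination and column
#'   `ne`; the overall range is attached as attribute `"range"`.
#' @examples
#' g <- ne_grid(N0 = c(12, 90), r0 = c(0.1, 0.4), K = 12000, T = c(50, 100))
#' attr(g, "range")
#' @export
ne_grid <- function(N0, r0, K, T) {
  if (!length(N0) || !length(r0) || !length(T))
    stop("all grids must be non-empty")
  grid <- expand.grid(N0 = N0, r0 = r0, T = T, KEEP.OUT.ATTRS = FALSE)
  grid$ne <- mapply(function(n0, r, tt)
    harmonic_mean_ne(verhulst_params(n0, K, r), tt)$ne,
    grid$N0, grid$r0, grid$T)
  grid$K <- K
  attr(grid, "range") <- range(grid$ne)
  grid
}

#' Convert between the population recombination parameter and c
#'
#' Coalescent methods estimate the scaled parameter rho = 4 * Ne * c; with an
#' effective size in hand this converts to the per-generation recombination
#' rate c = rho / (4 * Ne), and conversely `c_to_ne()` gives the Ne implied
#' by a rho and a per-generation rate.
#'
#' @param rho population recombination parameter (> 0).
#' @param ne effective population size (> 0).
#' @param c per-generation recombination rate (> 0).
#' @return `rho_to_c()`: the rate c; `c_to_ne()`: the implied Ne.
#' @examples
#' rho_to_c(4, 1)            # 1
#' c_to_ne(rho = 4 * 871 * 0.0082, c = 0.0041)  # 1742 = 2 * 871
#' @export
rho_to_c <- function(rho, ne) {
  if (any(rho <= 0) || any(ne <= 0)) stop("'rho' and 'ne' must be positive")
  rho / (4 * ne)
}

#' @rdname rho_to_c
#' @export
c_to_ne <- function(rho, c) {
  if (any(rho <= 0) || any(c <= 0)) stop("'rho' and 'c' must be positive")
  rho / (4 * c)
}
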