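#' REMD temperature-ladder parameters
#'
#' The ladder generator is a modified exponential: the plain form
#' T_i = T0 exp(g i) gives geometric spacing, and a per-block step boost
#' widens the steps every `block_size` replicas to keep exchange rates
#' roughly constant over a wide range. Recursively,
#' T_i = T_{i-1} + a_i * Delta_i with Delta_i = T0 (exp(g i) -
#' exp(g (i-1))) and a_i = (1 + step_boost)^floor(i / block_size). With
#' `step_boost = 0` the recursion collapses to the plain exponential
#' exactly.
#'
#' @param t0 Base (lowest) temperature, K.
#' @param growth Exponential growth rate g (> 0).
#' @param n_replicas Number of replicas (>= 2).
#' @param step_boost Fractional increase of the step coefficient per
#'   block (default 0.04, i.e. +4% every `block_size` replicas).
#' @param block_size Replicas per boost block (default 10).
#' @return A `ladder_params` list.
#' @export
ladder_params <- function(t0 = 300, growth, n_replicas,
                          step_boost = remd_defaults()$ladder$step_boost,
                          block_size = remd_defaults()$ladder$block_size) {
  if (t0 <= 0) abort("`t0` must be positive.")
  if (growth <= 0) abort("`growth` must be positive.")
  n_replicas <- as.integer(n_replicas)
  if (n_replicas < 2) abort("need at least 2 replicas.")
  if (step_boost < 0) abort("`step_boost` must be non-negative.")
  structure(list(t0 = t0, growth = growth, n_replicas = n_replicas,
                 step_boost = step_boost, block_size = as.integer(block_size)),
            class = "ladder_params")
}

#' Build a replica temperature ladder
#'
#' @param params A [ladder_params()].
#' @return A `temperature_ladder` tibble with columns `replica`
#'   (0-based index) and `temperature` (K), strictly increasing, starting
#'   at `t0`; generator parameters attached as the `params` attribute.
#' @examples
#' build_ladder(ladder_params(300, growth = 0.0125, n_replicas = 10))
#' @export
build_ladder <- function(params) {
  stopifnot(inherits(params, "ladder_params"))
  n <- params$n_replicas
  temps <- numeric(n)
  temps[1] <- params$t0
  i <- seq_len(n - 1)
  delta <- params$t0 * (exp(params$growth * i) - exp(params$growth * (i - 1)))
  a <- (1 + params$step_boost)^(i %/% params$block_size)
  temps[-1] <- params$t0 + cumsum(a * delta)
  out <- tibble(replica = 0:(n - 1), temperature = temps)
  attr(out, "params") <- params
  class(out) <- unique(c("temperature_ladder", class(tibble())))
  out
}

#' Calibrate the ladder growth rate to a target top temperature
#'
#' Root-finds the growth g so that the ladder's highest temperature hits
#' `t_top` (e.g. a 60-replica ladder from 300 K to 625 K). Bisection via
#' `stats::uniroot()` to 1e-9 relative tolerance; with `step_boost = 0`
#' the result matches the closed form g = log(t_top / t0) / (n - 1).
#'
#' @inheritParams ladder_params
#' @param t_top Target temperature of the last replica, K (> t0).
#' @return The calibrated growth rate (scalar).
#' @examples
#' g <- calibrate_growth(300, 625, n_replicas = 60)
#' max(build_ladder(ladder_params(300, g, 60))$temperature)  # 625
#' @export
calibrate_growth <- function(t0, t_top, n_replicas,
                             step_boost = remd_defaults()$ladder$step_boost,
                             block_size = remd_defaults()$ladder$block_size) {
  if (t_top <= t0) abort("`t_top` must exceed `t0`.")
  top_for <- function(g) {
    max(build_ladder(ladder_params(t0, g, n_replicas, step_boost,
                                   block_size))$temperature)
  }
  g_plain <- log(t_top / t0) / (n_replicas - 1)
  # boosts only enlarge steps, so g_plain is an upper bound for the root
  root <- stats::uniroot(function(g) top_for(g) - t_top,
                         lower = g_plain * 1e-3, upper = g_plain * 1.000001,
                         tol = 1e-12)
  root$root
}

#' Metropolis exchange probability between two replicas
#'
#' w = min(1, exp(-Delta)) with Delta = (beta_j - beta_i)(E_i - E_j) and
#' beta = 1 / (kB T), kB = 0.008314462618 kJ/mol/K. Equal energies give
#' Delta = 0 and certain acceptance.
#'
#' @param t_i,t_j Temperatures of the two replicas, K.
#' @param e_i,e_j Potential energies of the two configurations, kJ/mol.
#' @return Acceptance probability in \[0, 1\]; vectorized.
#' @examples
#' exchange_probability(300, 310, -100, -100)  # 1
#' @export
exchange_probability <- function(t_i, t_j, e_i, e_j) {
  if (any(c(t_i, t_j) <= 0)) abort("temperatures must be positive.")
  pmin(1, exp(-exchange_delta(t_i, t_j, e_i, e_j)))
}

exchange_delta <- function(t_i, t_j, e_i, e_j) {
  (1 / (.kB * t_j) - 1 / (.kB * t_i)) * (e_i - e_j)
}

#' Attempt Metropolis exchanges between adjacent replicas
#'
#' One exchange sweep over adjacent temperature slots: with even parity
#' the pairs (0,1), (2,3), ... are attempted, with odd parity (1,2),
#' (3,4), ...; alternating parities covers every adjacent pair over two
#' sweeps. Each pair is decided independently with its own uniform draw
#' from the current RNG stream.
#'
#' @param energies Potential energies per temperature slot (low to high),
#'   kJ/mol.
#' @param temperatures Slot temperatures, K, same length.
#' @param parity `"even"` or `"odd"`.
#' @return Tibble of decisions: `slot_lo`, `slot_hi` (0-based), `delta`,
#'   `probability`, `rng_draw`, `accepted`.
#' @export
attempt_exchanges <- function(energies, temperatures,
                              parity = c("even", "odd")) {
  parity <- match.arg(parity)
  n <- length(energies)
  stopifnot(length(temperatures) == n)
  first <- if (parity == "even") 1L else 2L
  if (n < 2 || first > n - 1) {
    return(tibble(slot_lo = integer(), slot_hi = integer(), delta = numeric(),
                  probability = numeric(), rng_draw = numeric(),
                  accepted = logical()))
  }
  lo <- seq(first, n - 1, by = 2)
  hi <- lo + 1
  delta <- exchange_delta(temperatures[lo], temperatures[hi],
                          energies[lo], energies[hi])
  prob <- pmin(1, exp(-delta))
  draw <- stats::runif(length(lo))
  tibble(slot_lo = lo - 1L, slot_hi = hi - 1L, delta = delta,
         probability = prob, rng_draw = draw, accepted = draw < prob)
}

#' Export a ladder as an mdp-style temperature list
#'
#' One temperature per line (K), the fragment consumed as `ref_t` values.
#'
#' @param ladder A `temperature_ladder`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ladder <- function(ladder, path) {
  writeLines(sprintf("%.4f", ladder$temperature), path)
  invisible(path)
}
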