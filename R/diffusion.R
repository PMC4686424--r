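#' Dynamic gain (urgency) signal
#'
#' Multiplier applied to the accumulated execution process, modelled as a
#' hyperbolic function of time since process onset:
#' `gamma(t) = cosh(xb * t)`. It equals 1 at onset, is non-decreasing, and
#' accelerates the process toward the response deadline. The hyperbolic
#' form is held in one place (this function) so an alternative can be
#' swapped in without touching the simulators' call sites.
#'
#' @param t Time since process onset in seconds (>= 0). Vectorised.
#' @param xb Gain coefficient (1/s, >= 0). `xb = 0` gives `gamma == 1`.
#' @return Numeric vector of multipliers (>= 1).
#' @examples
#' dynamic_gain(0.5, 0.878) # cosh(0.439)
#' @export
dynamic_gain <- function(t, xb) {
  if (any(!is.finite(t)) || any(t < 0)) {
    rlang::abort("`t` must be finite and >= 0")
  }
  if (!is.numeric(xb) || length(xb) != 1L || !is.finite(xb) || xb < 0) {
    rlang::abort("`xb` must be a single finite value >= 0")
  }
  cosh(xb * t)
}

#' Simulate one execution-process trajectory
#'
#' Euler-Maruyama path of the linear accumulator `phi_e` (drift `v_e`,
#' diffusion `sigma`), started at 0 at time `tr`, with the gain-scaled
#' execution state `theta_e(t) = phi_e(t) * dynamic_gain(t - tr, xb)`. The
#' path terminates at the first grid step where `theta_e >= a` (if
#' `stop_at_boundary`) or at the deadline.
#'
#' @param params A [process_params()] object.
#' @param cfg A [sim_config()] object; `cfg$seed` selects the noise stream.
#' @param stream Integer offset selecting which per-trial substream to use.
#' @param stop_at_boundary Terminate the path at the boundary crossing.
#' @return A tibble with columns `time`, `phi_e`, `theta_e`.
#' @export
integrate_execution <- function(params, cfg = sim_config(),
                                stream = 0L, stop_at_boundary = TRUE) {
  params <- as_process_params(params)
  if (cfg$deadline <= params$tr) {
    rlang::warn("deadline <= tr: the process never starts accumulating")
  }
  tibble::as_tibble(cpp_execution_path(
    params$a, params$tr, params$v_e, params$xb, params$sigma,
    cfg$dt, cfg$deadline, as.double(cfg$seed), as.double(stream),
    isTRUE(stop_at_boundary)
  ))
}

#' First boundary crossing of a simulated path
#'
#' Earliest grid time at which a process weakly crosses a boundary, with no
#' sub-step interpolation (the integration step is small relative to the RT
#' scale).
#'
#' @param trajectory Data frame with a `time` column and a state column.
#' @param boundary Boundary level in evidence units.
#' @param direction `"up"` (state >= boundary) or `"down"` (<= boundary).
#' @param state Name of the state column (default `"theta_e"`).
#' @return Crossing time in seconds, or `NA_real_` if the path never
#'   crosses.
#' @export
first_passage <- function(trajectory, boundary, direction = c("up", "down"),
                          state = "theta_e") {
  direction <- match.arg(direction)
  if (!nrow(trajectory)) rlang::abort("trajectory must be non-empty")
  x <- trajectory[[state]]
  hit <- if (direction == "up") x >= boundary else x <= boundary
  idx <- which(hit)
  if (!length(idx)) return(NA_real_)
  trajectory$time[idx[1L]]
}
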