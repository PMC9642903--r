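#' Channel-mixing weights of the perceived image
#'
#' `alpha_c` weighs the filled-in chromatic surfaces against the low-pass
#' single-opponent planes (`beta_c = 1 - alpha_c`); `alpha_i` plays the same
#' role for the achromatic channel. The betas are derived, never stored
#' independently: controlling alpha alone spans the whole scheme.
#'
#' @param alpha_c,alpha_i weights in `[0, 1]`.
#' @return list of class `perception_weights` with the derived betas.
#' @export
perception_weights <- function(alpha_c = 0.5, alpha_i = 0.5) {
  for (a in c(alpha_c, alpha_i))
    if (!is.finite(a) || a < 0 || a > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  structure(list(alpha_c = alpha_c, alpha_i = alpha_i,
                 beta_c = 1 - alpha_c, beta_i = 1 - alpha_i),
            class = "perception_weights")
}

#' Full perception-run configuration
#'
#' Bundles everything that determines a run: the single-opponent kernel, the
#' channel weights, the filling-in backend and mode, spiking-network
#' parameters, the ablation switch, and the seed. Defaults mirror the model
#' simulation settings: W = 21, sigma = 5, tau = 0.25, 20 neurons per
#' ensemble, iterative backend.
#'
#' @param kernel a [gaussian_kernel_spec()].
#' @param weights a [perception_weights()].
#' @param backend `"iterative"`, `"direct"` or `"snn"`.
#' @param mode `"converge"` or `"snapshot"` (iterative backend only).
#' @param tau filling-in step weight.
#' @param tol,n_steps convergence tolerance / snapshot step count.
#' @param boundary filling-in boundary rule.
#' @param n_neurons,radius,run_time spiking-backend parameters.
#' @param fillin_enabled `FALSE` replaces the filled surfaces by the raw
#'   double-opponent planes (the no-recurrence ablation: the model collapses
#'   to a low-pass/high-pass filter bank).
#' @param seed integer seed for the spiking backend.
#' @return list of class `perception_config`.
#' @export
perception_config <- function(kernel = gaussian_kernel_spec(),
                              weights = perception_weights(),
                              backend = c("iterative", "direct", "snn"),
                              mode = c("converge", "snapshot"),
                              tau = 0.25, tol = 1e-4, n_steps = 200L,
                              boundary = "dirichlet",
                              n_neurons = 20L, radius = 0.6, run_time = 1,
                              fillin_enabled = TRUE, seed = 1L) {
  structure(list(kernel = kernel, weights = weights,
                 backend = match.arg(backend), mode = match.arg(mode),
                 tau = tau, tol = tol, n_steps = as.integer(n_steps),
                 boundary = boundary, n_neurons = as.integer(n_neurons),
                 radius = radius, run_time = run_time,
                 fillin_enabled = isTRUE(fillin_enabled), seed = as.integer(seed)),
            class = "perception_config")
}

solve_channel <- function(source, cfg, seed_offset = 0L) {
  prob <- fillin_problem(source, boundary = cfg$boundary, tau = cfg$tau)
  switch(cfg$backend,
    direct = fillin_direct(prob),
    iterative = fillin_iterative(prob, mode = cfg$mode, tol = cfg$tol,
                                 n_steps = cfg$n_steps),
    snn = fillin_snn(prob,
                     spec = ensemble_spec(n_neurons = cfg$n_neurons,
                                          radius = cfg$radius,
                                          seed = cfg$seed + seed_offset),
                     run_time = cfg$run_time)
  )
}

#' Perceived opponent channels (with all intermediates)
#'
#' The full model forward pass short of the final color conversion:
#' opponent transform, single-/double-opponent filtering, filling-in of each
#' double-opponent plane, and the weighted recombination
#' `P_RG = beta_c * SO_RG + alpha_c * O_RG` (and likewise for BY with the
#' same chromatic weights, and for intensity with the achromatic weights).
#'
#' @param img `H x W x 3` stimulus.
#' @param cfg a [perception_config()].
#' @return list of class `perception` with planes `p_rg`, `p_by`, `p_i`, the
#'   `channels` (channel set), and the per-channel `fillin` results (`NULL`
#'   under the ablation).
#' @export
perceive_channels <- function(img, cfg = perception_config()) {
  stopifnot(inherits(cfg, "perception_config"))
  ch <- channel_responses(img, cfg$kernel)
  w <- cfg$weights
  if (cfg$fillin_enabled) {
    f_rg <- solve_channel(ch$do_rg, cfg, 0L)
    f_by <- solve_channel(ch$do_by, cfg, 1L)
    f_i <- solve_channel(ch$i_onoff, cfg, 2L)
    o_rg <- f_rg$surface; o_by <- f_by$surface; o_i <- f_i$surface
    fillin <- list(rg = f_rg, by = f_by, i = f_i)
  } else {
    o_rg <- ch$do_rg; o_by <- ch$do_by; o_i <- ch$i_onoff
    fillin <- NULL
  }
  structure(list(
    p_rg = w$beta_c * ch$so_rg + w$alpha_c * o_rg,
    p_by = w$beta_c * ch$so_by + w$alpha_c * o_by,
    p_i = w$beta_i * ch$i_lpf + w$alpha_i * o_i,
    channels = ch, fillin = fillin, config = cfg
  ), class = "perception")
}

#' @export
print.perception <- function(x, ...) {
  w <- x$config$weights
  cat(sprintf("<perception %d x %d> alpha_c = %g, alpha_i = %g, backend = %s%s\n",
              nrow(x$p_rg), ncol(x$p_rg), w$alpha_c, w$alpha_i,
              x$config$backend,
              if (x$config$fillin_enabled) "" else " (filling-in disabled)"))
  invisible(x)
}

#' Perceived RGB image
#'
#' Runs [perceive_channels()] and applies the inverse opponent transform.
#' Out-of-gamut values produced by the filled surfaces are preserved through
#' the algebra and clipped only here, at export.
#'
#' @param img `H x W x 3` stimulus.
#' @param cfg a [perception_config()].
#' @param clip clamp the output into `[0, 1]` (default `TRUE`).
#' @param intermediates also return the full `perception` object.
#' @return `H x W x 3` array; with `intermediates = TRUE`, a list
#'   `(image, perception)`.
#' @export
perceive <- function(img, cfg = perception_config(), clip = TRUE,
                     intermediates = FALSE) {
  p <- perceive_channels(img, cfg)
  out <- opponent_to_rgb(list(rg = p$p_rg, by = p$p_by, intensity = p$p_i),
                         clip = clip)
  if (intermediates) list(image = out, perception = p) else out
}
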