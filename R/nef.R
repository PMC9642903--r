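#' Neural ensemble specification
#'
#' A population of spiking rectified-linear neurons jointly representing one
#' scalar in `[-radius, radius]`. Tuning follows standard Neural Engineering
#' Framework conventions: encoders are drawn from \{-1, +1\}, intercepts
#' uniformly on `(-1, 0.95) * radius`, maximum rates uniformly on
#' (100, 200) events/s; gain and bias are then solved so each neuron fires at
#' its maximum rate at the end of the represented range on its preferred side
#' and goes silent at its intercept. Everything regenerates deterministically
#' from `seed`.
#'
#' @param n_neurons population size (default 20, the per-pixel size used by
#'   the filling-in network).
#' @param radius half-width of the represented scalar range.
#' @param seed integer RNG seed.
#' @param max_rate_range,intercept_range sampling ranges for the tuning
#'   parameters (intercepts as fractions of `radius`).
#' @return list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_neurons = 20L, radius = 1, seed = 1L,
                          max_rate_range = c(100, 200),
                          intercept_range = c(-1, 0.95)) {
  n_neurons <- as.integer(n_neurons)
  if (n_neurons < 1L) stop("n_neurons must be >= 1", call. = FALSE)
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0", call. = FALSE)
  structure(list(n_neurons = n_neurons, radius = radius, seed = as.integer(seed),
                 max_rate_range = max_rate_range, intercept_range = intercept_range),
            class = "ensemble_spec")
}

# Sample tuning parameters for n_ens ensembles at once (matrices n_ens x n).
sample_tuning <- function(spec, n_ens = 1L) {
  n <- spec$n_neurons
  with_local_seed(spec$seed, {
    enc <- matrix(sample(c(-1, 1), n_ens * n, replace = TRUE), n_ens, n)
    icpt <- matrix(stats::runif(n_ens * n, spec$intercept_range[1L],
                                spec$intercept_range[2L]), n_ens, n) * spec$radius
    mr <- matrix(stats::runif(n_ens * n, spec$max_rate_range[1L],
                              spec$max_rate_range[2L]), n_ens, n)
    gain <- mr / (spec$radius - icpt)
    bias <- -gain * icpt
    list(encoders = enc, gain = gain, bias = bias, intercepts = icpt, max_rates = mr)
  })
}

#' Realize an ensemble from its specification
#'
#' @param spec an [ensemble_spec()].
#' @return list of class `nef_ensemble` with per-neuron `encoders`, `gain`,
#'   `bias`, `intercepts`, `max_rates` and the originating spec.
#' @export
build_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  tp <- sample_tuning(spec, 1L)
  structure(list(spec = spec,
                 encoders = drop(tp$encoders), gain = drop(tp$gain),
                 bias = drop(tp$bias), intercepts = drop(tp$intercepts),
                 max_rates = drop(tp$max_rates)),
            class = "nef_ensemble")
}

#' Static tuning curves: firing rate of every neuron at stimulus x
#'
#' Rectified-linear rates `max(0, gain * encoder * x + bias)`, the rate-mode
#' view of the spiking neurons.
#'
#' @param ens a `nef_ensemble`.
#' @param x numeric vector of stimulus values.
#' @return matrix `length(x) x n_neurons` of nonnegative rates (events/s).
#' @export
ensemble_rates <- function(ens, x) {
  J <- outer(x, ens$encoders * ens$gain) +
    matrix(ens$bias, length(x), ens$spec$n_neurons, byrow = TRUE)
  pmax(J, 0)
}

#' Least-squares decoders for a target function
#'
#' Solves the regularized least-squares problem for weights `d` such that the
#' rate-weighted sum of tuning curves reconstructs `target_fn(x)` over the
#' evaluation points (Nengo-style L2 regularization, `sigma` a fraction of
#' the maximum activity). With a rank-deficient activity matrix the solve
#' falls back to the pseudo-inverse with a warning.
#'
#' @param ens a `nef_ensemble`.
#' @param target_fn function of the represented value; default identity.
#' @param eval_points stimulus values to fit over; default 500 points spread
#'   uniformly over the represented range.
#' @param regularization regularization fraction (default 0.005).
#' @return numeric vector of decoding weights, one per neuron, with the RMS
#'   fit residual in attribute `"rmse"`.
#' @export
solve_decoders <- function(ens, target_fn = identity, eval_points = NULL,
                           regularization = 0.005) {
  r <- ens$spec$radius
  if (is.null(eval_points))
    eval_points <- seq(-r, r, length.out = max(500L, 5L * ens$spec$n_neurons))
  if (length(eval_points) < ens$spec$n_neurons)
    stop("need at least n_neurons evaluation points", call. = FALSE)
  A <- ensemble_rates(ens, eval_points)
  y <- target_fn(eval_points)
  d <- ridge_decode(A, y, regularization)
  attr(d, "rmse") <- sqrt(mean((A %*% d - y)^2))
  d
}

ridge_decode <- function(A, y, regularization) {
  m <- nrow(A)
  sigma <- regularization * max(abs(A))
  G <- crossprod(A) / m + diag(sigma^2, ncol(A))
  U <- crossprod(A, y) / m
  d <- tryCatch(solve(G, U), error = function(e) {
    warning("rank-deficient activity matrix; using pseudo-inverse", call. = FALSE)
    s <- svd(G)
    keep <- s$d > max(s$d) * 1e-12
    s$v[, keep, drop = FALSE] %*% ((t(s$u[, keep, drop = FALSE]) %*% U) / s$d[keep])
  })
  drop(d)
}

#' Rate-mode decoded estimate (the spiking oracle)
#'
#' Evaluates the static tuning curves and decoder product without spiking;
#' the time-averaged spiking decode of a constant input converges to this
#' value.
#'
#' @param ens a `nef_ensemble`.
#' @param decoders weights from [solve_decoders()].
#' @param x stimulus value(s).
#' @return decoded estimate(s).
#' @export
decode_rate <- function(ens, decoders, x) {
  drop(ensemble_rates(ens, x) %*% decoders)
}

#' Synapse / simulation-step specification
#'
#' First-order low-pass synaptic filter with time constant `tau` (seconds)
#' and simulation step `dt` (seconds, `dt <= tau`).
#'
#' @param tau synaptic time constant, default 5 ms.
#' @param dt simulation step, default 1 ms.
#' @return list of class `synapse_spec`.
#' @export
synapse_spec <- function(tau = 0.005, dt = 0.001) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (dt > tau) stop("dt must not exceed the synaptic time constant", call. = FALSE)
  structure(list(tau = tau, dt = dt), class = "synapse_spec")
}

# Core discrete-time spiking engine shared by simulate_spiking,
# simulate_recurrent and the filling-in grid network.
#
# enc/gain/bias/dec: n_ens x n matrices (one scalar ensemble per row).
# input_fn(xhat, step): total drive per ensemble (length n_ens), built from
# the synapse-filtered decoded state xhat plus any external signal. The
# synaptic low-pass acts once, on the spike trains; the decoded feedback and
# external drive are injected as current without a second filter, so the
# loop has the single-pole dynamics the NEF mapping assumes.
# Spikes use a deterministic integrate-to-threshold realization of the
# rectified-linear rate, so runs are reproducible without Poisson draws.
nef_engine <- function(enc, gain, bias, dec, synapse, n_steps, input_fn,
                       keep_trace = TRUE, average_window = NULL) {
  n_ens <- nrow(enc); n <- ncol(enc)
  dt <- synapse$dt
  decay <- exp(-dt / synapse$tau)
  v <- matrix(0, n_ens, n)       # spike accumulators
  filt <- matrix(0, n_ens, n)    # filtered spike trains (rate units)
  xhat <- numeric(n_ens)
  trace <- if (keep_trace) matrix(0, n_steps, n_ens) else NULL
  acc <- numeric(n_ens); n_acc <- 0L
  avg_from <- if (is.null(average_window)) n_steps + 1L
              else n_steps - average_window + 1L
  for (s in seq_len(n_steps)) {
    z <- input_fn(xhat, s)
    J <- gain * (enc * z) + bias
    rate <- pmax(J, 0)
    v <- v + rate * dt
    spk <- floor(v)
    v <- v - spk
    filt <- filt * decay + (1 - decay) * (spk / dt)
    xhat <- rowSums(filt * dec)
    if (keep_trace) trace[s, ] <- xhat
    if (s >= avg_from) { acc <- acc + xhat; n_acc <- n_acc + 1L }
  }
  list(xhat = xhat, trace = trace,
       average = if (n_acc > 0L) acc / n_acc else xhat)
}

#' Simulate spike-based representation of an input signal
#'
#' Encodes the (synapse-filtered) input into deterministic
#' integrate-to-threshold spikes of the rectified-linear neurons, low-pass
#' filters the spike trains and decodes. For a constant input the
#' time-averaged decode converges to the [decode_rate()] oracle value within
#' a noise band that shrinks with neuron count and averaging time.
#'
#' @param ens a `nef_ensemble`.
#' @param decoders weights from [solve_decoders()].
#' @param input constant value or function of time (seconds).
#' @param T duration in seconds (several synaptic time constants at least).
#' @param synapse a [synapse_spec()].
#' @return list of class `nef_sim` with `times`, `decoded`, and the decoded
#'   `mean` and standard error over the final half of the run.
#' @export
simulate_spiking <- function(ens, decoders, input, T = 1, synapse = synapse_spec()) {
  n_steps <- max(1L, round(T / synapse$dt))
  u <- if (is.function(input)) input else function(t) input
  res <- nef_engine(
    enc = matrix(ens$encoders, 1L), gain = matrix(ens$gain, 1L),
    bias = matrix(ens$bias, 1L), dec = matrix(decoders, 1L),
    synapse = synapse, n_steps = n_steps,
    input_fn = function(xhat, s) u(s * synapse$dt)
  )
  half <- seq.int(n_steps %/% 2L + 1L, n_steps)
  decoded <- drop(res$trace)
  w <- decoded[half]
  # effective number of independent samples under the tau low-pass
  n_eff <- max(1, length(half) * synapse$dt / (2 * synapse$tau))
  structure(list(times = seq_len(n_steps) * synapse$dt, decoded = decoded,
                 mean = mean(w), se = stats::sd(w) / sqrt(n_eff),
                 synapse = synapse),
            class = "nef_sim")
}

#' Simulate NEF recurrent dynamics dx/dt = f(x) + u
#'
#' Realizes the dynamics principle: the recurrent connection decodes
#' `tau_dyn * f(x) + x` and the input connection supplies `tau_dyn * u`,
#' both through the synaptic filter. With `tau_dyn` equal to the synaptic
#' time constant this yields the textbook mapping; a larger `tau_dyn`
#' time-rescales the dynamics (the filling-in network uses this to perform
#' one tau = 0.25 relaxation step per synaptic time constant).
#'
#' @param spec an [ensemble_spec()] applied to every state dimension.
#' @param f function of the decoded state returning its derivative
#'   contribution, or a square matrix `A` for linear dynamics `f(x) = A x`
#'   (in which case the linearized discrete update is checked for stability
#'   and a warning is issued if it is expansive).
#' @param u constant input vector or function of time.
#' @param T duration in seconds.
#' @param n_dims state dimensionality (one scalar ensemble per dimension).
#' @param synapse a [synapse_spec()].
#' @param tau_dyn dynamics time scale; defaults to `synapse$tau`.
#' @param regularization decoder regularization, see [solve_decoders()].
#' @return list with `trace` (steps x n_dims decoded state), `final`, and
#'   the decoders used.
#' @export
simulate_recurrent <- function(spec, f, u = 0, T = 1, n_dims = 1L,
                               synapse = synapse_spec(), tau_dyn = NULL,
                               regularization = 0.005) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (is.null(tau_dyn)) tau_dyn <- synapse$tau
  if (is.matrix(f)) {
    A <- f
    M <- diag(nrow(A)) + (synapse$dt / synapse$tau) * (tau_dyn * A)
    if (max(Mod(eigen(M, only.values = TRUE)$values)) > 1 + 1e-9)
      warning("unstable recurrent dynamics: linearized update is expansive",
              call. = FALSE)
    f <- function(x) drop(A %*% x)
  }
  uf <- if (is.function(u)) u else function(t) rep_len(u, n_dims)
  tp <- sample_tuning(spec, n_dims)
  dec <- grid_identity_decoders(spec, tp, regularization)
  n_steps <- max(1L, round(T / synapse$dt))
  res <- nef_engine(tp$encoders, tp$gain, tp$bias, dec, synapse, n_steps,
                    input_fn = function(xhat, s)
                      tau_dyn * (f(xhat) + uf(s * synapse$dt)) + xhat)
  list(trace = res$trace, final = res$xhat, decoders = dec)
}

# Identity decoders for every row-ensemble of a sampled tuning block.
grid_identity_decoders <- function(spec, tp, regularization = 0.005,
                                   n_eval = NULL) {
  r <- spec$radius
  n <- spec$n_neurons
  if (is.null(n_eval)) n_eval <- max(200L, 5L * n)
  xs <- seq(-r, r, length.out = n_eval)
  n_ens <- nrow(tp$encoders)
  dec <- matrix(0, n_ens, n)
  for (p in seq_len(n_ens)) {
    A <- pmax(outer(xs, tp$encoders[p, ] * tp$gain[p, ]) +
                matrix(tp$bias[p, ], n_eval, n, byrow = TRUE), 0)
    dec[p, ] <- ridge_decode(A, xs, regularization)
  }
  dec
}
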