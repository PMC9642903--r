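#' Specify a filling-in problem
#'
#' Perceptual filling-in is modeled as the steady-state Poisson equation:
#' the filled surface `O` satisfies `lap(O) = -source`, where `source` is a
#' double-opponent plane (the discrete-Laplacian response to the stimulus;
#' note that kernel is the negative of the analyst's five-point stencil, so
#' the fixed point of the diffusion recovers the stimulus plane itself).
#'
#' @param source `H x W` numeric matrix, the DO / on-off plane.
#' @param boundary `"dirichlet"` (zero-clamped one-pixel frame, the default:
#'   it pins the solution uniquely) or `"neumann"` (replicate edges; the
#'   operator is then singular and solutions are normalized to zero mean).
#' @param tau explicit-iteration step weight; `0.25` in all simulations, and
#'   values above `0.25` break the stability bound of the five-point stencil.
#' @return list of class `fillin_problem`.
#' @export
fillin_problem <- function(source, boundary = c("dirichlet", "neumann"),
                           tau = 0.25) {
  source <- as.matrix(source)
  if (!all(is.finite(source))) stop("non-finite source", call. = FALSE)
  boundary <- match.arg(boundary)
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (tau > 0.25)
    warning("tau > 0.25: explicit iteration may be unstable", call. = FALSE)
  structure(list(source = source, boundary = boundary, tau = tau),
            class = "fillin_problem")
}

# Smallest (nonzero) eigenvalue magnitude of the five-point Laplacian on an
# H x W grid; closed form for both boundary rules, used to convert a
# per-step update into a bound on the remaining solution error.
stencil_lambda_min <- function(H, W, boundary) {
  if (boundary == "dirichlet")
    (2 - 2 * cos(pi / (H + 1))) + (2 - 2 * cos(pi / (W + 1)))
  else
    2 - 2 * cos(pi / max(H, W))
}

# Five-point Laplacian (N + S + E + W - 4*center) under the boundary rule.
apply_stencil <- function(I, boundary) {
  H <- nrow(I); W <- ncol(I)
  if (boundary == "dirichlet") {
    up <- rbind(0, I[-H, , drop = FALSE])
    dn <- rbind(I[-1L, , drop = FALSE], 0)
    lf <- cbind(0, I[, -W, drop = FALSE])
    rt <- cbind(I[, -1L, drop = FALSE], 0)
  } else {
    up <- I[c(1L, seq_len(H - 1L)), , drop = FALSE]
    dn <- I[c(seq_len(H - 1L) + 1L, H), , drop = FALSE]
    lf <- I[, c(1L, seq_len(W - 1L)), drop = FALSE]
    rt <- I[, c(seq_len(W - 1L) + 1L, W), drop = FALSE]
  }
  up + dn + lf + rt - 4 * I
}

fillin_result <- function(surface, problem, iterations, converged,
                          backend, extra = list()) {
  res <- max(abs(apply_stencil(surface, problem$boundary) + problem$source -
                   if (problem$boundary == "neumann") mean(problem$source) else 0))
  structure(c(list(surface = surface, iterations = iterations,
                   converged = converged, residual = res, backend = backend,
                   boundary = problem$boundary), extra),
            class = "fillin_result")
}

#' @export
print.fillin_result <- function(x, ...) {
  cat(sprintf("<fillin_result %s/%s> %d x %d, %s steps, residual %.3g%s\n",
              x$backend, x$boundary, nrow(x$surface), ncol(x$surface),
              format(x$iterations), x$residual,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

#' Explicit-iteration filling-in (the reference recurrence)
#'
#' Iterates `I_k = I_{k-1} + tau * (source + lap(I_{k-1}))` from `I_0 = 0`,
#' the per-pixel update in which every cell integrates its four neighbours
#' and itself. `converge` mode stops when the largest per-pixel update falls
#' below `tol`; `snapshot` mode returns after exactly `n_steps` iterations,
#' modeling the partial filling seen in cortical recordings of large
#' surfaces.
#'
#' In converge mode `tol` is calibrated to bound the max-abs error of the
#' returned surface, not merely the last per-step update: the iteration stops
#' when `max|I_k - I_{k-1}| / (tau * lambda_min) < tol`, where `lambda_min`
#' is the smallest (nonzero) eigenvalue magnitude of the five-point Laplacian
#' on the grid. The raw update understates the remaining error by exactly
#' that amplification factor on the slowest diffusion mode, so stopping on
#' the raw update would leave errors two orders of magnitude above `tol` on
#' a 32 x 32 grid.
#'
#' @param problem a [fillin_problem()].
#' @param mode `"converge"` or `"snapshot"`.
#' @param tol convergence threshold on the estimated max-abs solution error.
#' @param n_steps snapshot iteration count (default 200, a calibration under
#'   which a 10-px square fills and an 80-px square does not).
#' @param max_iter safety cap for converge mode.
#' @return a `fillin_result` with the surface, iteration count, and the
#'   max-abs discrete Poisson residual (reported honestly even when not
#'   converged).
#' @export
fillin_iterative <- function(problem, mode = c("converge", "snapshot"),
                             tol = 1e-6, n_steps = 200L, max_iter = 200000L) {
  stopifnot(inherits(problem, "fillin_problem"))
  mode <- match.arg(mode)
  src <- problem$source
  if (problem$boundary == "neumann") src <- src - mean(src)
  tau <- problem$tau
  I <- matrix(0, nrow(src), ncol(src))
  if (mode == "snapshot") {
    for (k in seq_len(n_steps)) I <- I + tau * (src + apply_stencil(I, problem$boundary))
    return(fillin_result(I, problem, n_steps, FALSE, "iterative",
                         list(mode = "snapshot")))
  }
  lam_min <- stencil_lambda_min(nrow(src), ncol(src), problem$boundary)
  thresh <- tol * tau * lam_min
  k <- 0L
  repeat {
    k <- k + 1L
    step <- tau * (src + apply_stencil(I, problem$boundary))
    I <- I + step
    if (max(abs(step)) < thresh || k >= max_iter) break
  }
  fillin_result(I, problem, k, k < max_iter, "iterative", list(mode = "converge"))
}

#' Direct sparse solve of the filling-in problem (oracle backend)
#'
#' Assembles the five-point Laplacian under the boundary rule as a sparse
#' linear system and solves `lap(O) = -source` exactly. Under the pure
#' replicate/Neumann boundary the operator is singular; the system is then
#' grounded at one pixel, the source is projected to zero mean, and the
#' solution is returned mean-centred and flagged.
#'
#' @param problem a [fillin_problem()] (intended for grids up to ~128 x 128).
#' @return a `fillin_result`; residual is at machine-precision level.
#' @export
fillin_direct <- function(problem) {
  stopifnot(inherits(problem, "fillin_problem"))
  H <- nrow(problem$source); W <- ncol(problem$source)
  n <- H * W
  if (n > 128L * 128L)
    stop("direct solver capped at 128 x 128 grids", call. = FALSE)
  idx <- function(r, c) (c - 1L) * H + r   # column-major
  rr <- rep(seq_len(H), W)
  cc <- rep(seq_len(W), each = H)
  ii <- jj <- list(); vv <- list()
  push <- function(i, j, v) {
    ii[[length(ii) + 1L]] <<- i; jj[[length(jj) + 1L]] <<- j
    vv[[length(vv) + 1L]] <<- v
  }
  push(seq_len(n), seq_len(n), rep(-4, n))
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    r2 <- rr + d[1L]; c2 <- cc + d[2L]
    inside <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    push(idx(rr, cc)[inside], idx(r2, c2)[inside], rep(1, sum(inside)))
    if (problem$boundary == "neumann" && any(!inside)) {
      # replicate: out-of-grid neighbour equals the centre
      k <- idx(rr, cc)[!inside]
      push(k, k, rep(1, length(k)))
    }
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(n, n))
  b <- -as.numeric(problem$source)
  singular <- problem$boundary == "neumann"
  if (singular) {
    b <- b - mean(b)
    # ground one pixel; the dropped equation is implied by the zero column
    # sums of A together with the zero-mean right-hand side
    A[1L, ] <- 0
    A[1L, 1L] <- 1
    b[1L] <- 0
  }
  x <- as.numeric(Matrix::solve(A, b))
  if (singular) x <- x - mean(x)
  surface <- matrix(x, H, W)
  fillin_result(surface, problem, 1L, TRUE, "direct",
                list(singular_grounded = singular))
}

#' Spiking-network filling-in backend
#'
#' Builds a grid of one rectified-linear ensemble per pixel, recurrently
#' connected to itself and its four neighbours, and lets the decoded state
#' relax toward the Poisson solution. The recurrent connection decodes the
#' feedback `tau * (source + lap(I)) + I` with `tau = 0.25` through a 5 ms
#' synapse, so each synaptic time constant performs one relaxation step of
#' the reference recurrence. The decoded surface is time-averaged over the
#' final fifth of the run; because every pixel is a spiking approximation,
#' the process never reaches an exact steady state and the result carries
#' the honest residual of the averaged surface.
#'
#' @param problem a [fillin_problem()].
#' @param spec per-pixel [ensemble_spec()]; the radius should cover the
#'   expected surface range (default 20 neurons, radius 0.6 — 1.2 times the
#'   largest chromatic plane magnitude of a `[0, 1]` stimulus).
#' @param run_time simulated seconds (default 1; a warning is issued below
#'   ten synaptic time constants).
#' @param synapse a [synapse_spec()].
#' @param average_frac fraction of the run averaged for the output surface.
#' @param regularization decoder regularization.
#' @return a `fillin_result` with `sim_time` and the spiking parameters.
#' @export
fillin_snn <- function(problem, spec = ensemble_spec(n_neurons = 20L, radius = 0.6),
                       run_time = 1, synapse = synapse_spec(),
                       average_frac = 0.2, regularization = 0.005) {
  stopifnot(inherits(problem, "fillin_problem"), inherits(spec, "ensemble_spec"))
  if (run_time < 10 * synapse$tau)
    warning("run_time shorter than 10 synaptic time constants", call. = FALSE)
  src <- problem$source
  if (problem$boundary == "neumann") src <- src - mean(src)
  H <- nrow(src); W <- ncol(src)
  n_pix <- H * W
  tau_step <- problem$tau
  tp <- sample_tuning(spec, n_pix)
  dec <- grid_identity_decoders(spec, tp, regularization)
  n_steps <- max(1L, round(run_time / synapse$dt))
  svec <- as.numeric(src)
  bnd <- problem$boundary
  res <- nef_engine(
    tp$encoders, tp$gain, tp$bias, dec, synapse, n_steps,
    input_fn = function(xhat, s) {
      lap <- apply_stencil(matrix(xhat, H, W), bnd)
      tau_step * (svec + as.numeric(lap)) + xhat
    },
    keep_trace = FALSE,
    average_window = max(1L, round(average_frac * n_steps))
  )
  surface <- matrix(res$average, H, W)
  if (problem$boundary == "neumann") surface <- surface - mean(surface)
  fillin_result(surface, problem, n_steps, FALSE, "snn",
                list(sim_time = run_time, n_neurons = spec$n_neurons,
                     seed = spec$seed))
}

# Shrink a mask by one pixel (4-neighbour erosion).
erode_mask <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  up <- rbind(FALSE, mask[-H, , drop = FALSE])
  dn <- rbind(mask[-1L, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, mask[, -W, drop = FALSE])
  rt <- cbind(mask[, -1L, drop = FALSE], FALSE)
  mask & up & dn & lf & rt
}

#' Degree of filling of a surface inside a stimulus mask
#'
#' Ratio of the mean surface value over the central ~20%-area core of the
#' mask to the mean over a 2-px band just inside the mask edge. A fully
#' filled (constant) surface gives 1; a hollow surface whose activity sits
#' only at the edges gives about 0. The core is obtained by eroding the mask
#' until its area first drops to 20% of the original (at least one pixel).
#'
#' @param result a `fillin_result` (or a bare surface matrix).
#' @param mask logical matrix marking the stimulus interior.
#' @return numeric fill ratio.
#' @export
fill_ratio <- function(result, mask) {
  surface <- if (inherits(result, "fillin_result")) result$surface else as.matrix(result)
  mask <- as.logical(mask)
  dim(mask) <- dim(surface)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  area <- sum(mask)
  core <- mask
  while (sum(core) > 0.2 * area) {
    nxt <- erode_mask(core)
    if (!any(nxt)) break
    core <- nxt
  }
  band <- mask & !erode_mask(erode_mask(mask))
  mean(surface[core]) / mean(surface[band])
}
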