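# Toy well-tempered metadynamics in 2-D CV space: overdamped Langevin
# sampling on an analytic model potential, Gaussian hill deposition with
# well-tempered height scaling, bias-to-free-energy reconstruction,
# convergence checking, and HILLS-style text I/O.
#
# The bias potential is accumulated on an internal fine grid as hills are
# deposited; bias values and gradients during sampling come from bilinear
# interpolation on that grid, which keeps the cost per step independent of
# the number of hills (the same device production engines use).

#' Sampler configuration for overdamped Langevin dynamics in CV space
#'
#' Position update per step:
#' \eqn{s \leftarrow s - \mu \nabla(U + V_{bias})\,\Delta t +
#' \sqrt{2 \mu k_B T \Delta t}\,\xi}, with reflecting boundaries. At
#' `temperature = 0` the noise vanishes and the update is pure gradient
#' descent.
#'
#' @param temperature Kelvin (>= 0, default 310).
#' @param step_size time step \eqn{\Delta t} in sampler time units
#'   (default 1; step counts are the package's clock).
#' @param n_steps number of steps (>= 1).
#' @param mobility inverse friction \eqn{\mu}, CV-units^2 per (kJ/mol) per
#'   time unit. Together with the defaults this gives an RMS thermal step of
#'   about 0.07 CV-units at 310 K.
#' @param seed integer RNG seed; identical seeds give identical trajectories.
#' @param stride store every `stride`-th frame (default 1).
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(temperature = 310, step_size = 1, n_steps = 1000,
                           mobility = 1e-3, seed = 1, stride = 1) {
  stopifnot(temperature >= 0, step_size > 0, n_steps >= 1, mobility > 0,
            stride >= 1)
  structure(list(temperature = temperature, step_size = step_size,
                 n_steps = as.integer(n_steps), mobility = mobility,
                 seed = as.integer(seed), stride = as.integer(stride)),
            class = "sampler_config")
}

#' Hill-deposition parameters for well-tempered metadynamics
#'
#' @param sigma Gaussian hill width per CV, CV-units (default 0.30).
#' @param height initial hill height, kJ/mol (default 1.20).
#' @param interval deposition interval in steps (default 500).
#' @param bias_factor well-tempered bias factor \eqn{\gamma > 1}
#'   (default 10). Deposited heights are scaled by
#'   \eqn{\exp(-V_{bias}(s)/((\gamma-1)k_BT))}.
#' @return object of class `hill_params`.
#' @export
hill_params <- function(sigma = c(0.30, 0.30), height = 1.20, interval = 500,
                        bias_factor = 10) {
  sigma <- rep(sigma, length.out = 2)
  stopifnot(all(sigma > 0), height > 0, interval >= 1)
  if (!is.finite(bias_factor) && bias_factor > 1) bias_factor <- Inf
  if (bias_factor <= 1) stop("invalid-parameter: bias_factor must be > 1")
  structure(list(sigma = sigma, height = height,
                 interval = as.integer(interval), bias_factor = bias_factor),
            class = "hill_params")
}

#' Bias state: an ordered list of deposited Gaussian hills
#'
#' @param hills data frame with columns `time_index`, `cx`, `cy`, `sx`,
#'   `sy`, `height`; may have zero rows.
#' @param bias_factor well-tempered factor the hills were deposited with.
#' @param interval deposition interval, steps.
#' @return object of class `bias_state`.
#' @export
bias_state <- function(hills = empty_hills(), bias_factor = 10, interval = 500) {
  stopifnot(is.data.frame(hills),
            all(c("time_index", "cx", "cy", "sx", "sy", "height") %in%
                  names(hills)))
  if (nrow(hills) > 0) {
    stopifnot(all(diff(hills$time_index) >= 0), all(hills$sx > 0),
              all(hills$sy > 0), all(hills$height > 0))
  }
  structure(list(hills = hills, bias_factor = bias_factor,
                 interval = interval),
            class = "bias_state")
}

#' @rdname bias_state
#' @export
empty_hills <- function() {
  data.frame(time_index = integer(), cx = numeric(), cy = numeric(),
             sx = numeric(), sy = numeric(), height = numeric())
}

#' Exact bias potential (sum of hills) at arbitrary points
#'
#' @param bias a `bias_state`.
#' @param s 2-vector or n x 2 matrix of CV points.
#' @param n_hills evaluate only the first `n_hills` hills (default all);
#'   lets callers examine the bias as it stood earlier in the run.
#' @return bias energy, kJ/mol.
#' @export
bias_energy <- function(bias, s, n_hills = nrow(bias$hills)) {
  s <- rbind2cols(s)
  v <- numeric(nrow(s))
  h <- bias$hills
  for (k in seq_len(min(n_hills, nrow(h)))) {
    v <- v + h$height[k] * exp(-((s[, 1] - h$cx[k])^2 / (2 * h$sx[k]^2) +
                                 (s[, 2] - h$cy[k])^2 / (2 * h$sy[k]^2)))
  }
  v
}

#' Well-tempered hill height that would be deposited at a point
#'
#' \eqn{w(s, t) = w_0 \exp(-V_{bias}(s, t)/((\gamma - 1) k_B T)}. Because
#' the bias only grows, this is non-increasing in the number of hills for
#' any fixed point.
#'
#' @param bias a `bias_state`.
#' @param s CV point (2-vector).
#' @param height0 initial height, kJ/mol.
#' @param temperature Kelvin.
#' @param n_hills consider only the first n hills.
#' @return height in kJ/mol.
#' @export
tempered_height <- function(bias, s, height0 = 1.20, temperature = 310,
                            n_hills = nrow(bias$hills)) {
  g <- bias$bias_factor
  v <- bias_energy(bias, s, n_hills)
  height0 * exp(-v / ((g - 1) * .KB_KJ * temperature))
}

# ---- internal gridded bias accumulator -------------------------------------

.bias_grid_new <- function(bounds, spacing = 0.1) {
  x <- seq(bounds[1, 1], bounds[1, 2], by = spacing)
  y <- seq(bounds[2, 1], bounds[2, 2], by = spacing)
  list(x = x, y = y, v = matrix(0, length(y), length(x)), spacing = spacing)
}

.bias_grid_add <- function(bg, cx, cy, sx, sy, height) {
  ix <- which(abs(bg$x - cx) <= 6 * sx)
  iy <- which(abs(bg$y - cy) <= 6 * sy)
  if (length(ix) == 0 || length(iy) == 0) return(bg)
  gx <- exp(-(bg$x[ix] - cx)^2 / (2 * sx^2))
  gy <- exp(-(bg$y[iy] - cy)^2 / (2 * sy^2))
  bg$v[iy, ix] <- bg$v[iy, ix] + height * outer(gy, gx)
  bg
}

# bilinear interpolation of the bias and its gradient at one point
.bias_grid_eval <- function(bg, p) {
  nx <- length(bg$x); ny <- length(bg$y); h <- bg$spacing
  fx <- (p[1] - bg$x[1]) / h
  fy <- (p[2] - bg$y[1]) / h
  i <- min(max(floor(fx), 0), nx - 2)
  j <- min(max(floor(fy), 0), ny - 2)
  tx <- min(max(fx - i, 0), 1)
  ty <- min(max(fy - j, 0), 1)
  v00 <- bg$v[j + 1, i + 1]; v01 <- bg$v[j + 1, i + 2]
  v10 <- bg$v[j + 2, i + 1]; v11 <- bg$v[j + 2, i + 2]
  val <- (1 - ty) * ((1 - tx) * v00 + tx * v01) +
         ty * ((1 - tx) * v10 + tx * v11)
  gx <- ((1 - ty) * (v01 - v00) + ty * (v11 - v10)) / h
  gy <- ((1 - tx) * (v10 - v00) + tx * (v11 - v01)) / h
  c(val, gx, gy)
}

# ---- sampling ---------------------------------------------------------------

.reflect <- function(x, lo, hi) {
  # reflecting boundaries; loop handles multiple bounces
  for (k in 1:10) {
    if (x >= lo && x <= hi) return(x)
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
  }
  min(max(x, lo), hi)
}

#' Sample an overdamped Langevin trajectory in CV space
#'
#' @param potential a [model_potential()].
#' @param config a [sampler_config()].
#' @param bias optional [bias_state()] added to the potential (the bias is
#'   static here; use [run_metadynamics()] for on-the-fly deposition).
#' @param start starting CV point (default: first analytic minimum if the
#'   potential records one, else the domain center).
#' @return object of class `cv_trajectory`: list with `frames` (n x 2
#'   matrix), `steps` (step index per frame), `bias_energy` (per frame,
#'   kJ/mol), and the config.
#' @export
sample_langevin <- function(potential, config, bias = NULL, start = NULL) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(config, "sampler_config"))
  bounds <- potential$bounds
  if (is.null(start)) {
    start <- if (!is.null(potential$minima))
      as.numeric(potential$minima[1, c("cv1", "cv2")])
    else rowMeans(bounds)
  }
  kT <- .KB_KJ * max(config$temperature, 0)
  dt <- config$step_size
  mu <- config$mobility
  noise_sd <- sqrt(2 * mu * kT * dt)
  width <- bounds[, 2] - bounds[, 1]
  bg <- NULL
  if (!is.null(bias) && nrow(bias$hills) > 0) {
    bg <- .bias_grid_new(bounds)
    for (k in seq_len(nrow(bias$hills))) {
      h <- bias$hills[k, ]
      bg <- .bias_grid_add(bg, h$cx, h$cy, h$sx, h$sy, h$height)
    }
  }
  n_out <- config$n_steps %/% config$stride
  frames <- matrix(NA_real_, n_out, 2)
  vbias <- numeric(n_out)
  steps <- integer(n_out)
  s <- start
  set.seed(config$seed)
  xi <- matrix(stats::rnorm(2L * config$n_steps), ncol = 2)
  out <- 0L
  for (t in seq_len(config$n_steps)) {
    g <- potential_gradient(potential, s)[1, ]
    vb <- 0
    if (!is.null(bg)) {
      be <- .bias_grid_eval(bg, s)
      vb <- be[1]
      g <- g + be[2:3]
    }
    move <- -mu * g * dt + noise_sd * xi[t, ]
    if (any(abs(move) > width))
      stop("unstable-step: proposed move exceeds the domain size; reduce step_size or mobility")
    s <- c(.reflect(s[1] + move[1], bounds[1, 1], bounds[1, 2]),
           .reflect(s[2] + move[2], bounds[2, 1], bounds[2, 2]))
    if (t %% config$stride == 0L) {
      out <- out + 1L
      frames[out, ] <- s
      vbias[out] <- vb
      steps[out] <- t
    }
  }
  structure(list(frames = frames, steps = steps, bias_energy = vbias,
                 config = config, start = start),
            class = "cv_trajectory")
}

#' Run well-tempered metadynamics on a model potential
#'
#' Overdamped Langevin sampling with Gaussian hills deposited at the
#' current CV position every `hills$interval` steps, with heights scaled by
#' the accumulated bias (well-tempered scheme). The first hill is always
#' deposited at the full initial height.
#'
#' @param potential a [model_potential()].
#' @param config a [sampler_config()].
#' @param hills a [hill_params()].
#' @param start starting CV point (default as in [sample_langevin()]).
#' @return list with `trajectory` (a `cv_trajectory`) and `bias` (a
#'   [bias_state()] carrying all deposited hills in order).
#' @export
run_metadynamics <- function(potential, config, hills = hill_params(),
                             start = NULL) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(config, "sampler_config"),
            inherits(hills, "hill_params"))
  bounds <- potential$bounds
  if (is.null(start)) {
    start <- if (!is.null(potential$minima))
      as.numeric(potential$minima[1, c("cv1", "cv2")])
    else rowMeans(bounds)
  }
  kT <- .KB_KJ * max(config$temperature, 1e-12)
  dt <- config$step_size
  mu <- config$mobility
  noise_sd <- sqrt(2 * mu * .KB_KJ * max(config$temperature, 0) * dt)
  width <- bounds[, 2] - bounds[, 1]
  gamma <- hills$bias_factor
  bg <- .bias_grid_new(bounds)
  n_hill_max <- config$n_steps %/% hills$interval + 1L
  hill_rows <- vector("list", n_hill_max)
  n_hills <- 0L
  n_out <- config$n_steps %/% config$stride
  frames <- matrix(NA_real_, n_out, 2)
  vbias <- numeric(n_out)
  steps <- integer(n_out)
  s <- start
  set.seed(config$seed)
  xi <- matrix(stats::rnorm(2L * config$n_steps), ncol = 2)
  out <- 0L
  for (t in seq_len(config$n_steps)) {
    be <- .bias_grid_eval(bg, s)
    g <- potential_gradient(potential, s)[1, ] + be[2:3]
    move <- -mu * g * dt + noise_sd * xi[t, ]
    if (any(abs(move) > width))
      stop("unstable-step: proposed move exceeds the domain size; reduce step_size or mobility")
    s <- c(.reflect(s[1] + move[1], bounds[1, 1], bounds[1, 2]),
           .reflect(s[2] + move[2], bounds[2, 1], bounds[2, 2]))
    if (t %% hills$interval == 0L) {
      vb <- .bias_grid_eval(bg, s)[1]
      w <- if (is.finite(gamma))
        hills$height * exp(-vb / ((gamma - 1) * kT))
      else hills$height
      n_hills <- n_hills + 1L
      hill_rows[[n_hills]] <- data.frame(time_index = t, cx = s[1], cy = s[2],
                                         sx = hills$sigma[1],
                                         sy = hills$sigma[2], height = w)
      bg <- .bias_grid_add(bg, s[1], s[2], hills$sigma[1], hills$sigma[2], w)
    }
    if (t %% config$stride == 0L) {
      out <- out + 1L
      frames[out, ] <- s
      vbias[out] <- .bias_grid_eval(bg, s)[1]
      steps[out] <- t
    }
  }
  hf <- if (n_hills > 0) do.call(rbind, hill_rows[seq_len(n_hills)]) else empty_hills()
  list(trajectory = structure(list(frames = frames, steps = steps,
                                   bias_energy = vbias, config = config,
                                   start = start),
                              class = "cv_trajectory"),
       bias = bias_state(hf, bias_factor = gamma, interval = hills$interval))
}

#' Reconstruct a free-energy surface from a well-tempered bias
#'
#' \eqn{F(s) = -\frac{\gamma}{\gamma - 1} V_{bias}(s)}, shifted so the
#' global minimum on the grid is exactly 0.
#'
#' @param bias a [bias_state()] with at least one hill.
#' @param bounds 2x2 domain matrix (rows = CVs, cols = lo/hi).
#' @param n grid points per axis (default 101).
#' @param temperature Kelvin, stored on the grid.
#' @param n_hills use only the first n hills (for checkpointing).
#' @return an [fes_grid()].
#' @export
reconstruct_fes <- function(bias, bounds, n = 101, temperature = 310,
                            n_hills = nrow(bias$hills)) {
  stopifnot(inherits(bias, "bias_state"))
  if (nrow(bias$hills) == 0 || n_hills < 1)
    stop("empty-bias: no hills to reconstruct from")
  g <- bias$bias_factor
  scale <- if (is.finite(g)) g / (g - 1) else 1
  cv1 <- seq(bounds[1, 1], bounds[1, 2], length.out = n)
  cv2 <- seq(bounds[2, 1], bounds[2, 2], length.out = n)
  pts <- cbind(rep(cv1, each = length(cv2)), rep(cv2, times = length(cv1)))
  v <- bias_energy(bias, pts, n_hills = n_hills)
  vals <- matrix(-scale * v, nrow = length(cv2))
  fes_grid(vals, cv1, cv2, temperature = temperature,
           metadata = sprintf("well-tempered reconstruction, %d hills, gamma = %g",
                              min(n_hills, nrow(bias$hills)), g))
}

#' Convergence check across FES checkpoints
#'
#' For each consecutive pair of checkpoints (grids on identical axes),
#' reports the maximum absolute free-energy deviation over the low-energy
#' region (both surfaces below `energy_cap` after re-anchoring to min 0).
#'
#' @param checkpoints list of >= 2 [fes_grid()] objects on identical grids.
#' @param energy_cap restrict the comparison to F < cap kJ/mol (default 30).
#' @param tolerance convergence threshold on the last deviation, kJ/mol
#'   (default 2).
#' @return list with `deviations` (kJ/mol per consecutive pair) and
#'   `converged` (logical).
#' @export
convergence_check <- function(checkpoints, energy_cap = 30, tolerance = 2) {
  stopifnot(is.list(checkpoints), length(checkpoints) >= 2)
  ref <- checkpoints[[1]]
  for (g in checkpoints[-1]) {
    if (!identical(dim(g$values), dim(ref$values)) ||
        max(abs(g$cv1 - ref$cv1)) > 1e-9 || max(abs(g$cv2 - ref$cv2)) > 1e-9)
      stop("grid-mismatch: checkpoints must share the same grid")
  }
  devs <- numeric(length(checkpoints) - 1)
  for (k in seq_along(devs)) {
    a <- checkpoints[[k]]$values; a <- a - min(a)
    b <- checkpoints[[k + 1]]$values; b <- b - min(b)
    region <- (a < energy_cap) & (b < energy_cap)
    devs[k] <- if (any(region)) max(abs(a[region] - b[region])) else 0
  }
  list(deviations = devs, converged = devs[length(devs)] <= tolerance)
}

#' Read and write HILLS-style hill logs
#'
#' Whitespace-separated text, one hill per line with columns
#' `time center1 center2 sigma1 sigma2 height bias_factor`; lines starting
#' with `#` are comments. A round trip preserves all fields to the printed
#' precision (17 significant digits).
#'
#' @param bias a [bias_state()].
#' @param path file path.
#' @return `read_hills` returns a [bias_state()]; a file with only comments
#'   yields an empty state with a warning.
#' @export
write_hills <- function(bias, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time center1 center2 sigma1 sigma2 height bias_factor", con)
  h <- bias$hills
  if (nrow(h) > 0) {
    lines <- sprintf("%d %.17g %.17g %.17g %.17g %.17g %.17g",
                     h$time_index, h$cx, h$cy, h$sx, h$sy, h$height,
                     bias$bias_factor)
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0) {
    warning("HILLS file contains no hill lines; returning empty bias state")
    return(bias_state(empty_hills()))
  }
  parts <- strsplit(trimws(raw[keep]), "\\s+")
  nf <- lengths(parts)
  if (any(nf != 7)) {
    bad <- keep[which(nf != 7)[1]]
    stop(sprintf("parse error at line %d: expected 7 columns, found %d",
                 bad, nf[which(nf != 7)[1]]))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 7,
              byrow = TRUE)
  if (any(!is.finite(m))) {
    bad <- keep[which(rowSums(!is.finite(m)) > 0)[1]]
    stop(sprintf("parse error at line %d: non-numeric field", bad))
  }
  hills <- data.frame(time_index = as.integer(m[, 1]), cx = m[, 2],
                      cy = m[, 3], sx = m[, 4], sy = m[, 5], height = m[, 6])
  gamma <- m[1, 7]
  interval <- if (nrow(hills) > 1) hills$time_index[2] - hills$time_index[1]
  else hills$time_index[1]
  bias_state(hills, bias_factor = gamma, interval = max(interval, 1L))
}
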