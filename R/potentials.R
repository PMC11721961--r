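# Analytic 2-D model potentials over collective-variable (CV) space.
# A potential is a sum of 2-D Gaussian terms (negative height = well,
# positive = bump) plus an optional harmonic confinement, on a rectangular
# bounded domain. Critical points are refined numerically at construction
# so tests can query exact minimum/saddle energies.

#' Construct a 2-D model potential
#'
#' @param terms data frame with columns `cx`, `cy` (centers, CV-units),
#'   `sx`, `sy` (widths, CV-units, > 0), `height` (kJ/mol; negative = well).
#' @param bounds 2x2 matrix, rows = CVs, columns = c(lo, hi).
#' @param harmonic optional list(center = c(x, y), k = c(kx, ky)) adding
#'   0.5 * k * (s - center)^2 per axis (kJ/mol per CV-unit^2).
#' @param offset constant added to the potential, kJ/mol.
#' @return object of class `model_potential`. Fields `minima` and `saddles`
#'   (data frames with cv1, cv2, energy) are filled by the constructors that
#'   know their critical points, e.g. [make_double_well()].
#' @export
model_potential <- function(terms, bounds, harmonic = NULL, offset = 0) {
  stopifnot(is.data.frame(terms),
            all(c("cx", "cy", "sx", "sy", "height") %in% names(terms)),
            all(terms$sx > 0), all(terms$sy > 0),
            is.matrix(bounds), all(dim(bounds) == c(2, 2)),
            all(bounds[, 2] > bounds[, 1]))
  structure(list(terms = terms, bounds = bounds, harmonic = harmonic,
                 offset = offset, minima = NULL, saddles = NULL),
            class = "model_potential")
}

#' Evaluate a model potential
#'
#' @param potential a `model_potential`.
#' @param s numeric 2-vector or n x 2 matrix of CV points.
#' @return potential energy kJ/mol (length-n vector).
#' @export
potential_energy <- function(potential, s) {
  s <- rbind2cols(s)
  u <- rep(potential$offset, nrow(s))
  for (k in seq_len(nrow(potential$terms))) {
    tr <- potential$terms[k, ]
    u <- u + tr$height * exp(-((s[, 1] - tr$cx)^2 / (2 * tr$sx^2) +
                               (s[, 2] - tr$cy)^2 / (2 * tr$sy^2)))
  }
  if (!is.null(potential$harmonic)) {
    h <- potential$harmonic
    u <- u + 0.5 * h$k[1] * (s[, 1] - h$center[1])^2 +
             0.5 * h$k[2] * (s[, 2] - h$center[2])^2
  }
  u
}

#' Analytic gradient of a model potential
#'
#' @inheritParams potential_energy
#' @return n x 2 matrix of dU/d(cv1), dU/d(cv2), kJ/mol per CV-unit.
#' @export
potential_gradient <- function(potential, s) {
  s <- rbind2cols(s)
  g <- matrix(0, nrow(s), 2)
  for (k in seq_len(nrow(potential$terms))) {
    tr <- potential$terms[k, ]
    e <- tr$height * exp(-((s[, 1] - tr$cx)^2 / (2 * tr$sx^2) +
                           (s[, 2] - tr$cy)^2 / (2 * tr$sy^2)))
    g[, 1] <- g[, 1] - e * (s[, 1] - tr$cx) / tr$sx^2
    g[, 2] <- g[, 2] - e * (s[, 2] - tr$cy) / tr$sy^2
  }
  if (!is.null(potential$harmonic)) {
    h <- potential$harmonic
    g[, 1] <- g[, 1] + h$k[1] * (s[, 1] - h$center[1])
    g[, 2] <- g[, 2] + h$k[2] * (s[, 2] - h$center[2])
  }
  g
}

# coerce a 2-vector or n x 2 matrix to matrix form
rbind2cols <- function(s) {
  if (is.null(dim(s))) s <- matrix(s, ncol = 2)
  stopifnot(ncol(s) == 2)
  s
}

#' Double-well model potential with prescribed barrier and asymmetry
#'
#' Two Gaussian wells along CV1 at the domain midline, confined
#' harmonically along CV2. Well depths are calibrated iteratively so that,
#' after shifting the deeper minimum to exactly 0 kJ/mol, the second
#' minimum sits at `asymmetry` and the saddle between them at `barrier`
#' (both to ~1e-8 kJ/mol). The refined critical points are stored on the
#' returned object (`$minima`, `$saddles`) for use as test oracles.
#'
#' @param separation distance between the two well centers, CV-units (> 0).
#' @param barrier saddle height above the deeper minimum, kJ/mol (> 0).
#' @param asymmetry energy of the shallower minimum above the deeper one,
#'   kJ/mol (>= 0, < barrier).
#' @param bounds domain, default `cbind(c(0, 0), c(10, 10))`.
#' @param width Gaussian well width, default `separation / 4`.
#' @param k_confine harmonic confinement along CV2, kJ/mol per CV-unit^2.
#' @return a `model_potential` with `minima` (deeper first) and `saddles`.
#' @export
make_double_well <- function(separation, barrier, asymmetry = 0,
                             bounds = cbind(c(0, 0), c(10, 10)),
                             width = separation / 4, k_confine = barrier / 8) {
  if (!is.finite(separation) || separation <= 0)
    stop("invalid-parameter: separation must be > 0")
  if (!is.finite(barrier) || barrier <= 0)
    stop("invalid-parameter: barrier must be > 0")
  if (asymmetry < 0 || asymmetry >= barrier)
    stop("invalid-parameter: asymmetry must be in [0, barrier)")
  mid <- rowMeans(bounds)
  x1 <- mid[1] - separation / 2
  x2 <- mid[1] + separation / 2
  y0 <- mid[2]
  d1 <- barrier
  d2 <- barrier - asymmetry
  pot <- NULL
  crit <- NULL
  for (iter in 1:40) {
    terms <- data.frame(cx = c(x1, x2), cy = y0, sx = width, sy = width,
                        height = c(-d1, -d2))
    pot <- model_potential(terms, bounds,
                           harmonic = list(center = c(mid[1], y0),
                                           k = c(0, k_confine)))
    crit <- .dw_critical_points(pot, x1, x2, y0)
    err_b <- barrier - (crit$saddle_e - crit$min1_e)
    err_a <- asymmetry - (crit$min2_e - crit$min1_e)
    if (abs(err_b) < 1e-10 && abs(err_a) < 1e-10) break
    # deepening well 1 raises (saddle - min1); adjust both depths
    d1 <- d1 + err_b
    d2 <- d2 + (err_b - err_a)
    d2 <- max(d2, 1e-6)
  }
  pot$offset <- -crit$min1_e      # anchor deeper minimum at exactly 0
  e_shift <- crit$min1_e
  pot$minima <- data.frame(cv1 = c(crit$min1_x, crit$min2_x), cv2 = y0,
                           energy = c(crit$min1_e, crit$min2_e) - e_shift)
  pot$saddles <- data.frame(cv1 = crit$saddle_x, cv2 = y0,
                            energy = crit$saddle_e - e_shift)
  pot
}

# refine the two minima and the intervening saddle of a double well whose
# critical points all lie on the line y = y0
.dw_critical_points <- function(pot, x1, x2, y0) {
  f <- function(x) potential_energy(pot, cbind(x, y0))
  m1 <- stats::optimize(f, lower = x1 - (x2 - x1) / 2, upper = (x1 + x2) / 2,
                        tol = 1e-12)
  m2 <- stats::optimize(f, lower = (x1 + x2) / 2, upper = x2 + (x2 - x1) / 2,
                        tol = 1e-12)
  sd <- stats::optimize(f, lower = m1$minimum, upper = m2$minimum,
                        maximum = TRUE, tol = 1e-12)
  list(min1_x = m1$minimum, min1_e = m1$objective,
       min2_x = m2$minimum, min2_e = m2$objective,
       saddle_x = sd$maximum, saddle_e = sd$objective)
}

#' Double-saddle landscape (two parallel transition channels)
#'
#' A gridded free-energy surface with two basins connected by two distinct
#' corridors at different CV2: the lower channel crosses a saddle of height
#' `barrier1`, the upper channel `barrier2 > barrier1`. Each channel is a
#' piecewise-linear corridor whose longitudinal free-energy profile peaks
#' at its prescribed barrier; off-corridor terrain is high. Used to
#' exercise second-pathway discovery, where the saddle heights must be
#' controlled exactly.
#'
#' @param separation well separation, CV-units.
#' @param barrier1,barrier2 saddle heights, kJ/mol (`barrier2 > barrier1`).
#' @param bounds domain, default `cbind(c(0, 0), c(10, 10))`.
#' @param n grid points per axis (default 101).
#' @return an [fes_grid()]; attributes `minima` and `saddles` record the
#'   prescribed critical points.
#' @export
make_double_saddle <- function(separation, barrier1, barrier2,
                               bounds = cbind(c(0, 0), c(10, 10)), n = 101) {
  stopifnot(separation > 0, barrier1 > 0, barrier2 > barrier1)
  mid <- rowMeans(bounds)
  x1 <- mid[1] - separation / 2
  x2 <- mid[1] + separation / 2
  y_lo <- mid[2] - separation / 2
  y_hi <- mid[2] + separation / 2
  base <- barrier2 + 30
  cv1 <- seq(bounds[1, 1], bounds[1, 2], length.out = n)
  cv2 <- seq(bounds[2, 1], bounds[2, 2], length.out = n)
  gx <- rep(cv1, each = length(cv2))
  gy <- rep(cv2, times = length(cv1))
  bowl <- function(cx, cy) pmin(12 * ((gx - cx)^2 + (gy - cy)^2), base)
  # corridor through (x1,mid) -> (mid, yc) -> (x2, mid): longitudinal
  # position t in [0,1], transverse distance d; profile peaks at the saddle
  channel <- function(yc, peak) {
    seg <- function(ax, ay, bx, by) {
      vx <- bx - ax; vy <- by - ay
      L2 <- vx^2 + vy^2
      t <- pmin(pmax(((gx - ax) * vx + (gy - ay) * vy) / L2, 0), 1)
      px <- ax + t * vx; py <- ay + t * vy
      list(t = t, d = sqrt((gx - px)^2 + (gy - py)^2))
    }
    s1 <- seg(x1, mid[2], mid[1], yc)
    s2 <- seg(mid[1], yc, x2, mid[2])
    use1 <- s1$d <= s2$d
    tt <- ifelse(use1, s1$t / 2, 0.5 + s2$t / 2)
    dd <- pmin(s1$d, s2$d)
    peak * exp(-(tt - 0.5)^2 / (2 * 0.12^2)) + pmin(400 * dd^2, base)
  }
  vals <- pmin(base,
               bowl(x1, mid[2]), bowl(x2, mid[2]),
               channel(y_lo, barrier1), channel(y_hi, barrier2))
  g <- fes_grid(matrix(vals, nrow = length(cv2)), cv1, cv2,
                metadata = "double-saddle channel landscape")
  attr(g, "minima") <- data.frame(cv1 = c(x1, x2), cv2 = mid[2],
                                  energy = c(0, 0))
  attr(g, "saddles") <- data.frame(cv1 = mid[1], cv2 = c(y_lo, y_hi),
                                   energy = c(barrier1, barrier2))
  g
}

#' Evaluate a model potential on a regular grid
#'
#' @param potential a `model_potential`.
#' @param n grid points per axis (default 101).
#' @param temperature stored on the resulting grid, K.
#' @param anchor shift so the grid minimum is 0 (default TRUE).
#' @return an [fes_grid()] of the potential values.
#' @export
potential_on_grid <- function(potential, n = 101, temperature = 310,
                              anchor = TRUE) {
  cv1 <- seq(potential$bounds[1, 1], potential$bounds[1, 2], length.out = n)
  cv2 <- seq(potential$bounds[2, 1], potential$bounds[2, 2], length.out = n)
  pts <- cbind(rep(cv1, each = length(cv2)), rep(cv2, times = length(cv1)))
  vals <- matrix(potential_energy(potential, pts), nrow = length(cv2))
  fes_grid(vals, cv1 = cv1, cv2 = cv2, temperature = temperature,
           metadata = "analytic model potential", anchor = anchor)
}
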