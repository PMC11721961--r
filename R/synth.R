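# Synthetic-data generators with known ground truth: planted-feature
# tables, inhibitor panels whose log-potency follows the composite
# descriptor, two-state bead trajectories with designated contact
# differences, and free-energy surfaces interpolating prescribed critical
# points. Every generator is a pure function of its arguments and seed.

#' Feature table with planted informative features
#'
#' Non-planted features are standard normal noise. For a binary label the
#' planted features are shifted by their effect size (in sd units) in the
#' `strong` class; for a continuous label they are linearly coupled to it
#' with slope = effect size plus residual noise of sd `noise_sd`.
#'
#' @param n_samples rows (split evenly between classes for binary labels).
#' @param n_features total feature count; features are named `f001`, ...
#' @param planted indices of informative features (subset of features).
#' @param effect_sizes per-planted-feature effect in sd units (> 0;
#'   recycled).
#' @param label_type `"binary"` or `"continuous"`.
#' @param noise_sd residual noise sd for continuous coupling (default 1).
#' @param seed RNG seed.
#' @return data frame with `label`, `group` (balanced pseudo-systems), and
#'   feature columns; attribute `planted` records the planted names.
#' @export
gen_feature_table <- function(n_samples = 2000, n_features = 200,
                              planted = 1:5, effect_sizes = 1,
                              label_type = c("binary", "continuous"),
                              noise_sd = 1, seed = 1) {
  label_type <- match.arg(label_type)
  if (any(planted < 1) || any(planted > n_features))
    stop("spec error: planted index out of range")
  effect_sizes <- rep(effect_sizes, length.out = length(planted))
  if (any(effect_sizes < 0)) stop("spec error: effect sizes must be >= 0")
  set.seed(seed)
  x <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
  colnames(x) <- sprintf("f%03d", seq_len(n_features))
  if (label_type == "binary") {
    lab <- factor(rep(c("weak", "strong"), length.out = n_samples),
                  levels = c("weak", "strong"))
    for (k in seq_along(planted)) {
      x[lab == "strong", planted[k]] <-
        x[lab == "strong", planted[k]] + effect_sizes[k]
    }
  } else {
    lab <- stats::rnorm(n_samples)
    for (k in seq_along(planted)) {
      x[, planted[k]] <- effect_sizes[k] * lab +
        stats::rnorm(n_samples, 0, noise_sd)
    }
  }
  out <- data.frame(label = lab,
                    group = rep_len(sprintf("g%02d", 1:10), n_samples),
                    x, check.names = FALSE)
  attr(out, "planted") <- colnames(x)[planted]
  out
}

#' Synthetic inhibitor panel linking potency to the composite descriptor
#'
#' Draws dissociation constants Ki' and conformational equilibrium
#' constants Ka' log-uniformly in the given decade ranges, then sets
#' \eqn{\ln \mathrm{IC50} = b + s \ln(K_i' K_a') + \epsilon} with Gaussian
#' noise. The default slope, intercept, and ranges are chosen so the panel
#' spans the decade structure of measured allosteric-inhibitor panels
#' (sub-nanomolar to sub-micromolar IC50, Ki'Ka' products across tens of
#' orders of magnitude) with a negative regression of binding free energy
#' on the log composite descriptor.
#'
#' @param n_inhibitors panel size.
#' @param log10_ki_range,log10_ka_range decade ranges for Ki' (mol/L) and
#'   Ka' (dimensionless).
#' @param slope,intercept coefficients of the ln IC50 relation.
#' @param noise_sd sd of the ln-scale noise (>= 0).
#' @param temperature Kelvin, for the returned dG_exp.
#' @param seed RNG seed.
#' @return data frame with `name`, `Ki_prime`, `Ka_prime`, `IC50_uM`,
#'   `dG_exp`, `composite`; the generating parameters are stored in the
#'   `truth` attribute.
#' @export
gen_inhibitor_panel <- function(n_inhibitors = 20,
                                log10_ki_range = c(-35, -25),
                                log10_ka_range = c(-18, -2),
                                slope = 0.12, intercept = 7.6,
                                noise_sd = 0.5, temperature = 310, seed = 1) {
  stopifnot(noise_sd >= 0, all(is.finite(c(log10_ki_range, log10_ka_range))))
  set.seed(seed)
  ki <- 10^stats::runif(n_inhibitors, log10_ki_range[1], log10_ki_range[2])
  ka <- 10^stats::runif(n_inhibitors, log10_ka_range[1], log10_ka_range[2])
  ln_ic50 <- intercept + slope * log(ki * ka) +
    stats::rnorm(n_inhibitors, 0, noise_sd)
  ic50 <- exp(ln_ic50)
  out <- data.frame(name = sprintf("inh%03d", seq_len(n_inhibitors)),
                    Ki_prime = ki, Ka_prime = ka, IC50_uM = ic50,
                    dG_exp = dg_exp_from_ic50(ic50, temperature),
                    composite = composite_potency(ki, ka))
  attr(out, "truth") <- list(slope = slope, intercept = intercept,
                             noise_sd = noise_sd)
  out
}

#' Two-state bead trajectory with designated contact differences
#'
#' Builds a toy protein of one bead (carbon) per residue laid out on a
#' loose helix, plus one mobile partner bead per designated residue pair.
#' In state A the designated pairs sit within the contact cutoff
#' (~4.5 A); in state B they are displaced beyond it (~9.5 A). Gaussian
#' coordinate noise is added to every atom in every frame.
#'
#' @param n_frames number of frames.
#' @param state_sequence character vector of `"A"`/`"B"` per frame
#'   (default: first half A, second half B).
#' @param n_residues residues in the scaffold (default 20).
#' @param contact_delta_pairs 2-column matrix of residue index pairs whose
#'   contact state differs between A and B (default rbind(c(3, 12))).
#' @param noise coordinate noise sd, Angstrom (default 0.3). A warning is
#'   issued when the displacement is within the noise floor.
#' @param seed RNG seed.
#' @param path optional file path; when given, frames are written as a
#'   multi-model PDB (byte-reproducible).
#' @return list with `frames` (list of `structure_frame`), `states`
#'   (per-frame labels), `pairs` (the designated residue pairs), and
#'   `path` (NULL unless written).
#' @export
gen_two_state_trajectory <- function(n_frames = 50, state_sequence = NULL,
                                     n_residues = 20,
                                     contact_delta_pairs = rbind(c(3, 12)),
                                     noise = 0.3, seed = 1, path = NULL) {
  stopifnot(n_residues >= 2)
  contact_delta_pairs <- rbind(contact_delta_pairs)
  if (any(contact_delta_pairs < 1) || any(contact_delta_pairs > n_residues))
    stop("designated pair outside residue range")
  if (is.null(state_sequence))
    state_sequence <- rep(c("A", "B"), each = ceiling(n_frames / 2))[1:n_frames]
  stopifnot(length(state_sequence) == n_frames,
            all(state_sequence %in% c("A", "B")))
  if (noise > 1.5) warning("noise approaches the A/B displacement; state labels may be unrecoverable")
  # helix scaffold, ~5.5 A rise+turn spacing keeps most pairs' contact
  # status stable
  t <- seq_len(n_residues)
  base <- cbind(6 * cos(t / 2), 6 * sin(t / 2), 2.2 * t)
  set.seed(seed)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- base
    for (k in seq_len(nrow(contact_delta_pairs))) {
      i <- contact_delta_pairs[k, 1]; j <- contact_delta_pairs[k, 2]
      dir <- base[j, ] - base[i, ]
      dir <- dir / sqrt(sum(dir^2))
      # place residue j near i in state A, far in state B
      off <- if (state_sequence[f] == "A") 4.5 else 9.5
      xyz[j, ] <- base[i, ] + dir * off
    }
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise), ncol = 3)
    frames[[f]] <- .new_frame(data.frame(
      atom = "CA", elem = "C", resno = t, resname = "GLY", chain = "A",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      mass = .element_mass("C"), ligand = FALSE, stringsAsFactors = FALSE))
  }
  if (!is.null(path)) write_structures(frames, path)
  list(frames = frames, states = state_sequence,
       pairs = contact_delta_pairs, path = path)
}

#' Synthetic free-energy surface through prescribed critical points
#'
#' Gaussian radial-basis interpolation: the surface equals a high
#' background (`ceiling_energy`) everywhere except near the prescribed
#' minima and saddles, where it interpolates their energies exactly at the
#' prescribed coordinates. The low-energy channel therefore runs through
#' the prescribed points, so pathway searches recover the prescribed
#' barriers to within grid resolution.
#'
#' @param minima data frame / matrix-like with columns `cv1`, `cv2`,
#'   `energy` (>= 2 rows, at least one energy 0, all >= 0).
#' @param saddles same layout (each saddle must lie above its two nearest
#'   minima).
#' @param bounds 2x2 domain matrix (default 0-10 per CV).
#' @param n grid points per axis (default 101).
#' @param kernel_width RBF width, CV-units (default: half the smallest
#'   pairwise distance among prescribed points).
#' @param ceiling_energy background level, kJ/mol (default: max prescribed
#'   energy + 15).
#' @param temperature Kelvin.
#' @return an [fes_grid()] (anchored so its minimum is 0).
#' @export
gen_fes <- function(minima, saddles, bounds = cbind(c(0, 0), c(10, 10)),
                    n = 101, kernel_width = NULL, ceiling_energy = NULL,
                    temperature = 310) {
  minima <- as.data.frame(minima)
  saddles <- as.data.frame(saddles)
  stopifnot(all(c("cv1", "cv2", "energy") %in% names(minima)),
            all(c("cv1", "cv2", "energy") %in% names(saddles)))
  if (nrow(minima) < 2) stop("spec error: need >= 2 minima")
  if (any(minima$energy < 0) || min(minima$energy) != 0)
    stop("spec error: minima energies must be >= 0 with at least one 0")
  pts <- rbind(minima[, c("cv1", "cv2")], saddles[, c("cv1", "cv2")])
  if (anyDuplicated(pts)) stop("spec error: duplicated critical-point coordinates")
  # each saddle must top its two nearest minima
  for (k in seq_len(nrow(saddles))) {
    d <- sqrt((minima$cv1 - saddles$cv1[k])^2 +
                (minima$cv2 - saddles$cv2[k])^2)
    near2 <- order(d)[1:min(2, nrow(minima))]
    if (any(saddles$energy[k] <= minima$energy[near2]))
      stop("spec error: saddle below an adjacent minimum")
  }
  e <- c(minima$energy, saddles$energy)
  if (is.null(ceiling_energy)) ceiling_energy <- max(e) + 15
  p <- as.matrix(pts)
  dmat <- as.matrix(stats::dist(p))
  if (is.null(kernel_width)) {
    kernel_width <- min(dmat[upper.tri(dmat)]) / 2
  }
  K <- exp(-dmat^2 / (2 * kernel_width^2))
  w <- solve(K, e - ceiling_energy)
  cv1 <- seq(bounds[1, 1], bounds[1, 2], length.out = n)
  cv2 <- seq(bounds[2, 1], bounds[2, 2], length.out = n)
  gx <- rep(cv1, each = length(cv2))
  gy <- rep(cv2, times = length(cv1))
  vals <- rep(ceiling_energy, length(gx))
  for (k in seq_len(nrow(p))) {
    vals <- vals + w[k] * exp(-((gx - p[k, 1])^2 + (gy - p[k, 2])^2) /
                                (2 * kernel_width^2))
  }
  fes_grid(matrix(vals, nrow = length(cv2)), cv1, cv2,
           temperature = temperature,
           metadata = "synthetic RBF surface through prescribed critical points")
}
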