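# Per-frame trajectory feature assembly: one row per frame combining the
# geometric descriptors into a flat table ready for the learning stage.

#' Featurize a trajectory into per-frame descriptors
#'
#' Computes, for every frame: optimal-superposition RMSD to the reference
#' (heavy atoms), radius of gyration (total and per lab axis), hydrogen
#' bond count, optional solvent-accessible surface area, and the requested
#' named group-group distances.
#'
#' @param frames list of `structure_frame` objects (see
#'   [read_structures()]).
#' @param reference reference frame for RMSD (default: first frame).
#' @param distances named list of `list(a = <atom indices>, b = <atom
#'   indices>, mode = "com"|"min-heavy-atom")` entries; each contributes a
#'   column `dist_<name>`.
#' @param with_sasa include the SASA column (slower; default FALSE).
#' @param sasa_points quadrature points for [sasa()] (default 240 here;
#'   raise for production accuracy).
#' @return data frame, one row per frame: `frame`, `rmsd`, `rg`, `rg_x`,
#'   `rg_y`, `rg_z`, `hbonds`, optional `sasa`, and distance columns.
#' @export
featurize_trajectory <- function(frames, reference = frames[[1]],
                                 distances = list(), with_sasa = FALSE,
                                 sasa_points = 240) {
  stopifnot(length(frames) >= 1)
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    row <- data.frame(
      frame = i,
      rmsd = rmsd(fr, reference),
      rg = radius_of_gyration(fr),
      rg_x = radius_of_gyration(fr, axis = "X"),
      rg_y = radius_of_gyration(fr, axis = "Y"),
      rg_z = radius_of_gyration(fr, axis = "Z"),
      hbonds = hbond_count(fr)$count)
    if (with_sasa)
      row$sasa <- sasa(fr, n_sphere_points = sasa_points)$total
    for (nm in names(distances)) {
      d <- distances[[nm]]
      mode <- if (is.null(d$mode)) "com" else d$mode
      row[[paste0("dist_", nm)]] <- group_distance(fr, d$a, d$b, mode = mode)
    }
    row
  })
  do.call(rbind, rows)
}

#' Long-format residue contact features across frames
#'
#' Applies [contact_matrix()] to each frame and binds the results with a
#' `frame` column; `wide = TRUE` pivots to one row per frame with one
#' column per residue pair (absent contacts filled with `fill`).
#'
#' @param frames list of `structure_frame` objects.
#' @param cutoff contact cutoff, Angstrom (default 6.5).
#' @param wide pivot to a frames x pairs matrix (default FALSE).
#' @param fill value for pairs beyond the cutoff in wide form (default:
#'   the cutoff itself, a censored distance).
#' @param ... passed to [contact_matrix()].
#' @return long data frame (`frame`, `res_i`, `res_j`, `distance`) or wide
#'   data frame (`frame` + `c<i>_<j>` columns).
#' @export
contact_features <- function(frames, cutoff = 6.5, wide = FALSE,
                             fill = cutoff, ...) {
  long <- do.call(rbind, lapply(seq_along(frames), function(i) {
    cm <- contact_matrix(frames[[i]], cutoff = cutoff, ...)
    if (nrow(cm) == 0) return(NULL)
    cbind(frame = i, cm)
  }))
  if (!wide) return(long)
  pairs <- unique(long[, c("res_i", "res_j")])
  pairs <- pairs[order(pairs$res_i, pairs$res_j), ]
  keys <- sprintf("c%d_%d", pairs$res_i, pairs$res_j)
  out <- matrix(fill, length(frames), nrow(pairs),
                dimnames = list(NULL, keys))
  idx <- match(sprintf("c%d_%d", long$res_i, long$res_j), keys)
  out[cbind(long$frame, idx)] <- long$distance
  data.frame(frame = seq_along(frames), out, check.names = FALSE)
}
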