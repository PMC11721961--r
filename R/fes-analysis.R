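# Analysis of gridded 2-D free-energy surfaces: basin detection, state
# labeling, minimum free energy pathway extraction by a minimax
# (widest-path) Dijkstra search, second-pathway discovery via
# transition-state masking, and 1-D profiles along a path.
#
# Grid convention: rows index CV2, columns CV1; reports use 0-based
# (row, col) indices, matching the JSON sidecar written by write_fes().

#' Find local minima of a free-energy surface
#'
#' Interior nodes strictly lower than all 8 neighbors with energy at or
#' below `energy_cap`, sorted ascending by energy with deterministic
#' (row, col) tie-break.
#'
#' @param grid an [fes_grid()], at least 3 x 3.
#' @param energy_cap ignore minima above this free energy, kJ/mol
#'   (default Inf).
#' @return data frame with 0-based `row`, `col`, coordinates `cv1`, `cv2`,
#'   `energy`, and a `label` column (NA until [label_states()]).
#' @export
find_minima <- function(grid, energy_cap = Inf) {
  stopifnot(inherits(grid, "fes_grid"))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3 || nc < 3) stop("too-small: grid must be at least 3 x 3")
  core <- v[2:(nr - 1), 2:(nc - 1)]
  lower_all <- matrix(TRUE, nr - 2, nc - 2)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- v[(2:(nr - 1)) + dr, (2:(nc - 1)) + dc]
    lower_all <- lower_all & (core < nb)
  }
  idx <- which(lower_all & core <= energy_cap, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(row = integer(), col = integer(), cv1 = numeric(),
                      cv2 = numeric(), energy = numeric(),
                      label = character()))
  }
  r <- idx[, 1] + 1L; c <- idx[, 2] + 1L
  out <- data.frame(row = r - 1L, col = c - 1L,
                    cv1 = grid$cv1[c], cv2 = grid$cv2[r],
                    energy = v[cbind(r, c)],
                    label = NA_character_)
  out[order(out$energy, out$row, out$col), , drop = FALSE]
}

#' Label minima as inactive / active / intermediate
#'
#' The minimum nearest (Euclidean in CV space) each reference coordinate
#' receives that reference's label; all other minima are labeled
#' `intermediate`. If both references are nearest the same minimum the
#' closer reference wins and the other takes its second-nearest minimum.
#' Exact distance ties are broken by lower free energy.
#'
#' @param minima data frame from [find_minima()] (>= 2 rows).
#' @param reference_coords named list with `inactive` and `active`, each a
#'   CV-space 2-vector c(cv1, cv2).
#' @return the minima data frame with `label` filled.
#' @export
label_states <- function(minima, reference_coords) {
  stopifnot(is.data.frame(minima),
            all(c("inactive", "active") %in% names(reference_coords)))
  if (nrow(minima) < 2)
    stop("labeling-conflict: need at least 2 minima to label both states")
  pts <- cbind(minima$cv1, minima$cv2)
  d <- sapply(reference_coords[c("inactive", "active")], function(ref) {
    sqrt((pts[, 1] - ref[1])^2 + (pts[, 2] - ref[2])^2)
  })
  # order candidates per reference: distance, then free energy, then index
  pick <- function(dist, excluded) {
    ord <- order(dist, minima$energy, seq_len(nrow(minima)))
    ord[!ord %in% excluded][1]
  }
  i_in <- pick(d[, 1], integer())
  i_ac <- pick(d[, 2], integer())
  if (i_in == i_ac) {
    if (d[i_in, 1] <= d[i_ac, 2]) i_ac <- pick(d[, 2], i_in)
    else i_in <- pick(d[, 1], i_ac)
  }
  minima$label <- "intermediate"
  minima$label[i_in] <- "inactive"
  minima$label[i_ac] <- "active"
  minima
}

# neighbor offsets for the chosen connectivity
.nbr_offsets <- function(connectivity) {
  if (connectivity == 4) {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  } else {
    o <- expand.grid(dr = -1:1, dc = -1:1)
    as.matrix(o[!(o$dr == 0 & o$dc == 0), ])
  }
}

#' Minimum free energy path between two grid points
#'
#' `mode = "minimax"` (default) minimizes the maximum node energy along the
#' path — the widest-path variant of Dijkstra, appropriate when the
#' quantity of interest is the highest barrier that must be crossed.
#' `mode = "boltzmann-sum"` minimizes
#' \eqn{\sum \exp(F(node)/k_BT)\cdot\ell} over path steps (\eqn{\ell} the
#' CV-space step length), which penalizes long excursions at moderate
#' energy. Ties on the frontier are broken by lower free energy, then by
#' (row, col).
#'
#' @param grid an [fes_grid()].
#' @param source,target 0-based c(row, col) pairs, or single rows of the
#'   data frame returned by [find_minima()].
#' @param mode `"minimax"` or `"boltzmann-sum"`.
#' @param connectivity 8 (default) or 4.
#' @param blocked optional logical matrix, TRUE = unreachable node.
#' @return object of class `fes_path`: list with `nodes` (n x 2, 0-based
#'   row/col), `cv` (n x 2 CV coordinates), `energies`, `barrier_forward`,
#'   `barrier_reverse`, `transition_states` and `intermediates` (indices
#'   into the path), `mode`.
#' @export
mfep <- function(grid, source, target, mode = c("minimax", "boltzmann-sum"),
                 connectivity = 8, blocked = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "fes_grid"), connectivity %in% c(4, 8))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  src <- .as_node(source); tgt <- .as_node(target)
  if (identical(src, tgt)) stop("source and target must differ")
  for (p in list(src, tgt)) {
    if (p[1] < 0 || p[1] >= nr || p[2] < 0 || p[2] >= nc)
      stop("node outside grid")
  }
  if (is.null(blocked)) blocked <- matrix(FALSE, nr, nc)
  if (blocked[src[1] + 1, src[2] + 1] || blocked[tgt[1] + 1, tgt[2] + 1])
    stop("no-path: source or target is masked")
  n <- nr * nc
  id <- function(r, c) (c - 1L) * nr + r            # 1-based linear index
  srci <- id(src[1] + 1L, src[2] + 1L)
  tgti <- id(tgt[1] + 1L, tgt[2] + 1L)
  off <- .nbr_offsets(connectivity)
  h <- fes_spacing(grid)
  kT <- .KB_KJ * grid$temperature
  cost <- rep(Inf, n)
  prev <- integer(n)
  done <- as.vector(blocked)
  fvec <- as.vector(v)
  cost[srci] <- if (mode == "minimax") fvec[srci] else 0
  rows <- rep(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  repeat {
    active <- which(!done & is.finite(cost))
    if (length(active) == 0) stop("no-path: target unreachable from source")
    cm <- min(cost[active])
    cand <- active[cost[active] == cm]
    if (length(cand) > 1) {
      cand <- cand[order(fvec[cand], rows[cand], cols[cand])]
    }
    u <- cand[1]
    if (u == tgti) break
    done[u] <- TRUE
    r <- rows[u]; c <- cols[u]
    for (k in seq_len(nrow(off))) {
      r2 <- r + off[k, 1]; c2 <- c + off[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      w <- id(r2, c2)
      if (done[w]) next
      newcost <- if (mode == "minimax") max(cost[u], fvec[w])
      else cost[u] + exp(pmin(fvec[w], 700 * kT) / kT) *
        sqrt((off[k, 1] * h[2])^2 + (off[k, 2] * h[1])^2)
      if (newcost < cost[w]) {
        cost[w] <- newcost
        prev[w] <- u
      }
    }
  }
  # walk predecessors back from the target
  node_ids <- tgti
  while (node_ids[1] != srci) {
    p <- prev[node_ids[1]]
    if (p == 0L) stop("no-path: target unreachable from source")
    node_ids <- c(p, node_ids)
  }
  .build_path(grid, rows[node_ids], cols[node_ids], mode)
}

.as_node <- function(p) {
  if (is.data.frame(p)) return(c(p$row[1], p$col[1]))
  as.integer(p[1:2])
}

.build_path <- function(grid, r1, c1, mode) {
  e <- grid$values[cbind(r1, c1)]
  n <- length(e)
  ts <- which(e > c(-Inf, e[-n]) & e > c(e[-1], -Inf))
  ts <- setdiff(ts, c(1L, n))
  im <- which(e < c(Inf, e[-n]) & e < c(e[-1], Inf))
  im <- setdiff(im, c(1L, n))
  structure(list(nodes = cbind(row = r1 - 1L, col = c1 - 1L),
                 cv = cbind(cv1 = grid$cv1[c1], cv2 = grid$cv2[r1]),
                 energies = e,
                 barrier_forward = max(e) - e[1],
                 barrier_reverse = max(e) - e[n],
                 transition_states = ts,
                 intermediates = im,
                 mode = mode),
            class = "fes_path")
}

#' @export
print.fes_path <- function(x, ...) {
  cat(sprintf("fes_path (%s): %d nodes, barrier forward %.2f / reverse %.2f kJ/mol\n",
              x$mode, nrow(x$nodes), x$barrier_forward, x$barrier_reverse))
  invisible(x)
}

#' Second (alternative) pathway by transition-state masking
#'
#' Masks all grid nodes within `exclusion_radius` cells (Euclidean, in
#' index space) of the first path's highest-energy node and re-runs
#' [mfep()]. Fails with a `no-second-path` error when the masking
#' disconnects source from target, or when the alternative crosses the
#' same transition-state node.
#'
#' @param grid an [fes_grid()].
#' @param first an `fes_path` from [mfep()].
#' @param exclusion_radius mask radius in cells (>= 1, default 2).
#' @param ... passed to [mfep()] (mode, connectivity).
#' @return an `fes_path` whose transition state differs from the first's.
#' @export
second_path <- function(grid, first, exclusion_radius = 2, ...) {
  stopifnot(inherits(first, "fes_path"))
  if (exclusion_radius < 1) stop("invalid-parameter: exclusion_radius must be >= 1")
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  ts_i <- which.max(first$energies)
  ts <- first$nodes[ts_i, ] + 1L       # 1-based
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  blocked <- (rr - ts[1])^2 + (cc - ts[2])^2 <= exclusion_radius^2
  n <- nrow(first$nodes)
  src <- first$nodes[1, ]; tgt <- first$nodes[n, ]
  if (blocked[src[1] + 1, src[2] + 1] || blocked[tgt[1] + 1, tgt[2] + 1])
    stop("no-second-path: masking removed an endpoint")
  p2 <- tryCatch(mfep(grid, src, tgt, blocked = blocked, ...),
                 error = function(e) {
                   if (grepl("no-path", conditionMessage(e)))
                     stop("no-second-path: masking disconnects source from target")
                   stop(e)
                 })
  ts2 <- p2$nodes[which.max(p2$energies), ]
  # a genuine second channel crosses a saddle away from the masked disk; a
  # path whose highest point hugs the mask boundary is the same channel
  if (sqrt(sum((ts2 - first$nodes[ts_i, ])^2)) <= 2 * exclusion_radius)
    stop("no-second-path: alternative merely skirts the masked transition state")
  p2
}

#' One-dimensional free-energy profile along a path
#'
#' @param path an `fes_path`.
#' @param grid the [fes_grid()] the path lives on.
#' @return data frame with `arc_length` (cumulative Euclidean CV-space
#'   distance, starting at 0) and `F` (kJ/mol).
#' @export
profile_1d <- function(path, grid) {
  stopifnot(inherits(path, "fes_path"))
  cv <- path$cv
  seg <- sqrt(rowSums((cv[-1, , drop = FALSE] -
                         cv[-nrow(cv), , drop = FALSE])^2))
  data.frame(arc_length = c(0, cumsum(seg)), F = path$energies)
}
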