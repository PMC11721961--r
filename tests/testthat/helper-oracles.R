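# Independent oracles and fixture builders used across the test files.

# Exhaustive minimax barrier by depth-first enumeration of simple paths
# (branch-and-bound: a branch is abandoned as soon as its running maximum
# reaches the best complete path found so far). Independent of the
# Dijkstra-based implementation under test.
oracle_minimax <- function(values, src, tgt, connectivity = 8) {
  nr <- nrow(values); nc <- ncol(values)
  off <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else {
    o <- expand.grid(dr = -1:1, dc = -1:1)
    o <- o[!(o$dr == 0 & o$dc == 0), ]
    lapply(seq_len(nrow(o)), function(i) c(o$dr[i], o$dc[i]))
  }
  best <- Inf
  visited <- matrix(FALSE, nr, nc)
  dfs <- function(r, c, cur) {
    if (cur >= best) return(invisible())
    if (r == tgt[1] && c == tgt[2]) { best <<- cur; return(invisible()) }
    visited[r, c] <<- TRUE
    for (d in off) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || visited[r2, c2]) next
      dfs(r2, c2, max(cur, values[r2, c2]))
    }
    visited[r, c] <<- FALSE
  }
  dfs(src[1], src[2], values[src[1], src[2]])
  best
}

# Second independent route: smallest level at which source and target are
# connected through nodes at or below the level (union of flood fills).
oracle_minimax_threshold <- function(values, src, tgt, connectivity = 8) {
  levels <- sort(unique(as.vector(values)))
  levels <- levels[levels >= max(values[src[1], src[2]],
                                 values[tgt[1], tgt[2]])]
  for (lam in levels) {
    open <- values <= lam
    if (!open[src[1], src[2]] || !open[tgt[1], tgt[2]]) next
    # BFS flood fill from src over open nodes
    nr <- nrow(values); nc <- ncol(values)
    seen <- matrix(FALSE, nr, nc)
    queue <- list(src)
    seen[src[1], src[2]] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        if (connectivity == 4 && abs(dr) + abs(dc) == 2) next
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (!open[r2, c2] || seen[r2, c2]) next
        seen[r2, c2] <- TRUE
        queue[[length(queue) + 1]] <- c(r2, c2)
      }
    }
    if (seen[tgt[1], tgt[2]]) return(lam)
  }
  Inf
}

# finite-difference gradient of a model potential (oracle for the
# analytic gradient)
fd_gradient <- function(pot, s, h = 1e-6) {
  c((potential_energy(pot, s + c(h, 0)) - potential_energy(pot, s - c(h, 0))) / (2 * h),
    (potential_energy(pot, s + c(0, h)) - potential_energy(pot, s - c(0, h))) / (2 * h))
}

# minimal structure-frame builder for geometry tests
toy_frame <- function(xyz, elem = "C", atom = elem, resno = seq_len(nrow(xyz)),
                      resname = "GLY", ligand = FALSE, chain = "A") {
  n <- nrow(xyz)
  df <- data.frame(atom = rep_len(atom, n), elem = rep_len(elem, n),
                   resno = rep_len(resno, n),
                   resname = rep_len(resname, n),
                   chain = rep_len(chain, n),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   mass = allokin:::.element_mass(rep_len(elem, n)),
                   ligand = rep_len(ligand, n), stringsAsFactors = FALSE)
  allokin:::.new_frame(df)
}

# random rugged test grid with a fixed seed
random_grid <- function(n, seed, scale = 30) {
  set.seed(seed)
  matrix(stats::runif(n * n, 0, scale), n, n)
}

# rigid rotation (90 deg about z) + translation applied to a frame
rotate_frame <- function(frame, shift = c(5, -3, 2)) {
  xyz <- coords(frame)
  rot <- cbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))
  new <- xyz %*% rot
  frame$x <- new[, 1] + shift[1]
  frame$y <- new[, 2] + shift[2]
  frame$z <- new[, 3] + shift[3]
  frame
}
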