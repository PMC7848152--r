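# Test helpers: a bare porosity-map constructor for hand-built grids, and an
# exhaustive path-enumeration oracle for the weighted geodesic cost,
# independent of the package's Dijkstra implementation.

make_por <- function(mat, pixel_size = 1, threshold = 0.01) {
  structure(list(porosity = mat, pixel_size = pixel_size,
                 air_endpoint = 0, cortical_endpoint = 1,
                 impermeable_threshold = threshold),
            class = "porosity_map")
}

# Minimum porosity-weighted path cost from `src` (c(row, col)) to every
# pixel, by depth-first enumeration of simple paths on the 8-connected
# graph with step cost length_mm / porosity(destination). Branches whose
# running cost already exceeds the best known cost at the current pixel are
# abandoned; with non-negative step costs every prefix of a shortest path
# is itself shortest, so the pruning is exact.
oracle_costs <- function(por, pixel_size = 1, threshold = 0.01,
                         src = c(1, 1)) {
  nr <- nrow(por); nc <- ncol(por)
  best <- matrix(Inf, nr, nc)
  open <- por >= threshold
  if (!open[src[1], src[2]]) stop("oracle: source blocked")
  steps <- expand.grid(dr = -1:1, dc = -1:1)
  steps <- steps[!(steps$dr == 0 & steps$dc == 0), ]
  visited <- matrix(FALSE, nr, nc)
  dfs <- function(i, j, cost) {
    if (cost > best[i, j]) return(invisible())
    best[i, j] <<- cost
    visited[i, j] <<- TRUE
    for (k in seq_len(nrow(steps))) {
      ii <- i + steps$dr[k]; jj <- j + steps$dc[k]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (visited[ii, jj] || !open[ii, jj]) next
      len <- if (steps$dr[k] != 0 && steps$dc[k] != 0)
        sqrt(2) * pixel_size else pixel_size
      dfs(ii, jj, cost + len / por[ii, jj])
    }
    visited[i, j] <<- FALSE
  }
  dfs(src[1], src[2], 0)
  best
}

# random porosity grid with a sprinkling of blocked pixels, source kept open
random_porosity_grid <- function(nr, nc, p_blocked = 0.15) {
  m <- matrix(runif(nr * nc, 0.05, 1), nr, nc)
  m[runif(nr * nc) < p_blocked] <- 0
  m[1, 1] <- max(m[1, 1], 0.5)
  m
}
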