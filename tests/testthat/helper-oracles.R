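# Brute-force texture oracles: direct enumeration implementations kept
# deliberately independent of the package's matrix engines.

offsets13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
)

offsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

in_bounds <- function(p, dm) all(p >= 1) && all(p <= dm)

# symmetric co-occurrence counts for one offset
glcm_oracle <- function(grid, off) {
  dm <- dim(grid)
  ng <- max(grid)
  m <- matrix(0, ng, ng)
  for (v in which(grid > 0)) {
    p <- arrayInd(v, dm)[1, ]
    q <- p + off
    if (!in_bounds(q, dm)) next
    g2 <- grid[q[1], q[2], q[3]]
    if (g2 == 0) next
    g1 <- grid[v]
    m[g1, g2] <- m[g1, g2] + 1
    m[g2, g1] <- m[g2, g1] + 1
  }
  m
}

# run census for one direction: data frame (level, length, count)
glrlm_oracle <- function(grid, off) {
  dm <- dim(grid)
  runs <- list()
  for (v in which(grid > 0)) {
    p <- arrayInd(v, dm)[1, ]
    prev <- p - off
    g <- grid[v]
    if (in_bounds(prev, dm) && grid[prev[1], prev[2], prev[3]] == g) next
    len <- 1
    q <- p + off
    while (in_bounds(q, dm) && grid[q[1], q[2], q[3]] == g) {
      len <- len + 1
      q <- q + off
    }
    runs[[length(runs) + 1]] <- c(g, len)
  }
  do.call(rbind, runs)
}

# 26-connected zones by repeated flood fill (BFS over a queue)
glszm_oracle <- function(grid) {
  dm <- dim(grid)
  seen <- array(FALSE, dm)
  zones <- list()
  for (v in which(grid > 0)) {
    if (seen[v]) next
    level <- grid[v]
    queue <- v
    seen[v] <- TRUE
    size <- 0
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      size <- size + 1
      p <- arrayInd(u, dm)[1, ]
      for (i in seq_len(nrow(offsets26))) {
        q <- p + offsets26[i, ]
        if (!in_bounds(q, dm)) next
        w <- q[1] + (q[2] - 1) * dm[1] + (q[3] - 1) * dm[1] * dm[2]
        if (!seen[w] && grid[w] == level) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level, size)
  }
  do.call(rbind, zones)
}

# NGTDM accumulators (n_i, s_i) by direct neighbor averaging
ngtdm_oracle <- function(grid) {
  dm <- dim(grid)
  ng <- max(grid)
  n_i <- s_i <- numeric(ng)
  for (v in which(grid > 0)) {
    p <- arrayInd(v, dm)[1, ]
    vals <- c()
    for (i in seq_len(nrow(offsets26))) {
      q <- p + offsets26[i, ]
      if (!in_bounds(q, dm)) next
      g2 <- grid[q[1], q[2], q[3]]
      if (g2 > 0) vals <- c(vals, g2)
    }
    if (length(vals)) {
      g <- grid[v]
      n_i[g] <- n_i[g] + 1
      s_i[g] <- s_i[g] + abs(g - mean(vals))
    }
  }
  cbind(n_i, s_i)
}

# GLDM (level, dependence) census by direct neighbor counting
gldm_oracle <- function(grid, alpha = 0) {
  dm <- dim(grid)
  ng <- max(grid)
  m <- matrix(0, ng, 27)
  for (v in which(grid > 0)) {
    p <- arrayInd(v, dm)[1, ]
    dep <- 0
    for (i in seq_len(nrow(offsets26))) {
      q <- p + offsets26[i, ]
      if (!in_bounds(q, dm)) next
      g2 <- grid[q[1], q[2], q[3]]
      if (g2 > 0 && abs(g2 - grid[v]) <= alpha) dep <- dep + 1
    }
    m[grid[v], dep + 1] <- m[grid[v], dep + 1] + 1
  }
  m
}

# a random region-coded grid: 0 outside region, levels 1..ng inside
random_disc_grid <- function(dm = c(5, 5, 5), ng = 4, p_in = 0.85) {
  grid <- array(0L, dm)
  inreg <- array(runif(prod(dm)) < p_in, dm)
  if (!any(inreg)) inreg[1] <- TRUE
  grid[inreg] <- sample.int(ng, sum(inreg), replace = TRUE)
  grid
}

disc_from_grid <- function(grid) {
  structure(
    list(grid = grid, ng = max(1L, max(grid)),
         binning = list(method = "fixed_count", n_bins = max(1L, max(grid))),
         spacing_mm = c(1, 1, 1)),
    class = "disc_volume"
  )
}

# small synthetic case for unit tests (fast geometry)
tiny_config <- function(..., seed = 1L) {
  synthetic_config(
    n_train = 4, n_test = 2, volume_shape = c(24, 24, 24),
    tumor_diameter_range_mm = c(20, 21), seed = seed, ...
  )
}
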