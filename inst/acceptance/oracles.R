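# Brute-force texture oracles used by scripts/acceptance.R: direct
# enumeration, independent of the package's C++ engines.

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

random_disc_grid <- function(dm = c(5, 5, 5), ng = 4, p_in = 0.85) {
  grid <- array(0L, dm)
  inreg <- array(runif(prod(dm)) < p_in, dm)
  if (!any(inreg)) inreg[1] <- TRUE
  grid[inreg] <- sample.int(ng, sum(inreg), replace = TRUE)
  grid
}

# maximum absolute deviation between the package's texture engines and the
# oracles on one grid (one random direction for the directional families)
engine_vs_oracle_dev <- function(grid) {
  ng <- max(grid)
  dm <- dim(grid)
  o <- sample.int(13, 1)
  dev <- 0

  counts <- habitatct:::cpp_glcm(as.integer(grid), as.integer(dm),
                                 as.integer(ng))
  dev <- max(dev, max(abs(matrix(counts[, o], ng, ng) -
                            glcm_oracle(grid, offsets13[o, ]))))

  maxlen <- max(dm)
  rl <- habitatct:::cpp_glrlm(as.integer(grid), as.integer(dm),
                              as.integer(ng), as.integer(maxlen))
  or <- glrlm_oracle(grid, offsets13[o, ])
  m2 <- matrix(0, ng, maxlen)
  for (i in seq_len(nrow(or))) {
    m2[or[i, 1], or[i, 2]] <- m2[or[i, 1], or[i, 2]] + 1
  }
  dev <- max(dev, max(abs(matrix(rl[, o], ng, maxlen, byrow = TRUE) - m2)))

  zones <- habitatct:::cpp_glszm_zones(as.integer(grid), as.integer(dm))
  orz <- glszm_oracle(grid)
  same <- identical(sort(paste(zones[, 1], zones[, 2])),
                    sort(paste(orz[, 1], orz[, 2])))
  dev <- max(dev, as.numeric(!same))

  nt <- habitatct:::cpp_ngtdm(as.integer(grid), as.integer(dm),
                              as.integer(ng))
  dev <- max(dev, max(abs(unname(nt) - unname(ngtdm_oracle(grid)))))

  gd <- habitatct:::cpp_gldm(as.integer(grid), as.integer(dm),
                             as.integer(ng), 0L)
  dev <- max(dev, max(abs(unname(gd) - unname(gldm_oracle(grid, 0)))))
  dev
}
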