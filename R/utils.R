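#' @keywords internal
"_PACKAGE"

#' @useDynLib habitatct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn %||% .data
#' @importFrom stats median sd var cor cov quantile rnorm runif rbinom plogis
#'   qnorm pnorm pt pchisq glm binomial coef predict kmeans fisher.test
#'   setNames
#' @importFrom utils combn head
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package go through this so results are pure functions of (inputs, seed).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Shannon entropy in bits of a count/probability vector, 0*log0 = 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  p <- p / sum(p)
  -sum(p * log2(p))
}

# Shift a 3D array by integer offset (dx, dy, dz), padding with `fill`.
shift_array <- function(a, d, fill = 0L) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      n <- dm[ax] - d[ax]
      if (n <= 0) return(out)
      src[[ax]] <- seq_len(n)
      dst[[ax]] <- seq_len(n) + d[ax]
    } else {
      n <- dm[ax] + d[ax]
      if (n <= 0) return(out)
      src[[ax]] <- seq_len(n) - d[ax]
      dst[[ax]] <- seq_len(n)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Integer offsets within a physical ball of radius r_mm.
ball_offsets <- function(r_mm, spacing) {
  rv <- pmax(0L, floor(r_mm / spacing))
  g <- expand.grid(
    dx = -rv[1]:rv[1],
    dy = -rv[2]:rv[2],
    dz = -rv[3]:rv[3]
  )
  keep <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 +
    (g$dz * spacing[3])^2 <= r_mm^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels per axis.
smooth_gaussian3d <- function(a, sigma_vox) {
  array(cpp_smooth3d(as.numeric(a), as.integer(dim(a)),
                     as.numeric(sigma_vox)), dim(a))
}

# Standardized smooth Gaussian random field on a grid (unit sd, zero mean).
gaussian_field <- function(dim, spacing, corr_len_mm) {
  a <- array(rnorm(prod(dim)), dim)
  if (corr_len_mm > 0) {
    a <- smooth_gaussian3d(a, corr_len_mm / spacing)
  }
  s <- sd(as.vector(a))
  if (s < 1e-12) return(array(0, dim))
  (a - mean(a)) / s
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items, used
#' here to quantify how well recovered habitat maps match planted subregions.
#'
#' @param a,b Integer label vectors of equal length.
#' @return A scalar in \[-1, 1\]; 1 for identical partitions (up to label
#'   permutation), about 0 for independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < 1e-12) return(1)
  (sum_ij - expected) / (maxi - expected)
}
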