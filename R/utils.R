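#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates \code{code}, and restores the caller's RNG
#' state afterwards, so library internals never perturb user-level streams.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a deterministic sub-stream seed
#'
#' One global seed drives every stochastic stage of the pipeline; each stage
#' draws from its own sub-stream so that adding or reordering stages does not
#' shift the random numbers used by the others.
#'
#' @param seed integer master seed.
#' @param label character stage label.
#' @return an integer in \code{[1, 2^31 - 2]}.
#' @export
#' @examples
#' substreamSeed(1, "simulate")
substreamSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 10007 + h * 131 + 17) %% 2147483629 + 1)
}

# population (n-denominator) standard deviation
popSD <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

# adjusted Fisher-Pearson standardized third moment; 0 for constant input
skewnessAdj <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(0)
  g1 <- sum(((x - mean(x)) / s)^3)
  n / ((n - 1) * (n - 2)) * g1
}

# 1D convolution with edge replication (used by the separable smoother)
conv1Replicate <- function(x, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(x * kernel)
  xp <- c(rep(x[1L], r), x, rep(x[length(x)], r))
  n <- length(x)
  out <- numeric(n)
  for (k in seq_along(kernel)) {
    out <- out + kernel[k] * xp[seq_len(n) + (k - 1L)]
  }
  out
}

#' Gaussian smoothing of a matrix (separable, edge-replicated)
#' @keywords internal
gaussianSmooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  sm <- apply(mat, 2L, conv1Replicate, kernel = k)
  t(apply(t(sm), 2L, conv1Replicate, kernel = k))
}

#' Label 8-connected foreground regions of a logical matrix
#'
#' @param mask logical matrix; \code{TRUE} = foreground.
#' @return integer matrix of region labels (0 = background).
#' @keywords internal
labelConnected <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nextLab <- 0L
  offs <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    stack <- start
    lab[start] <- nextLab
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r0 <- ((cur - 1L) %% nr) + 1L
      c0 <- ((cur - 1L) %/% nr) + 1L
      for (k in 1:8) {
        r <- r0 + offs[k, 1L]; cc <- c0 + offs[k, 2L]
        if (r >= 1L && r <= nr && cc >= 1L && cc <= nc) {
          j <- (cc - 1L) * nr + r
          if (mask[j] && lab[j] == 0L) {
            lab[j] <- nextLab
            stack <- c(stack, j)
          }
        }
      }
    }
  }
  lab
}

# binary dilation with a disc structuring element of radius (pixels)
dilateMask <- function(mask, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  r <- max(0L, as.integer(floor(radius)))
  out <- mask
  if (r == 0L) return(out)
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0L && dc == 0L) next
    if (dr * dr + dc * dc > radius * radius) next
    rs <- max(1L, 1L - dr):min(nr, nr - dr)
    cs <- max(1L, 1L - dc):min(nc, nc - dc)
    out[rs + dr, cs + dc] <- out[rs + dr, cs + dc] | mask[rs, cs]
  }
  out
}

# median over a square ring (outer radius ro, excluding inner radius ri)
# around each pixel; NA entries of `values` are ignored.
ringMedianBackground <- function(values, ro, ri = 0L) {
  nr <- nrow(values); nc <- ncol(values)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    r1 <- max(1L, i - ro); r2 <- min(nr, i + ro)
    for (j in seq_len(nc)) {
      c1 <- max(1L, j - ro); c2 <- min(nc, j + ro)
      w <- values[r1:r2, c1:c2]
      if (ri > 0L) {
        ir1 <- max(1L, i - ri) - r1 + 1L; ir2 <- min(nr, i + ri) - r1 + 1L
        ic1 <- max(1L, j - ri) - c1 + 1L; ic2 <- min(nc, j + ri) - c1 + 1L
        w[ir1:ir2, ic1:ic2] <- NA_real_
      }
      w <- w[!is.na(w)]
      if (length(w) > 0L) out[i, j] <- stats::median(w)
    }
  }
  out
}
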