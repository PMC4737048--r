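# Brute-force oracles, kept deliberately naive and independent of the
# package's implementations.

# component count by repeated queue-based flood fill over an explicit
# neighbour list
oracle_count_components <- function(mask, connectivity = 8) {
  mask <- mask != 0
  nr <- nrow(mask)
  nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8) {
    nbr <- expand.grid(di = -1:1, dj = -1:1)
    nbr <- nbr[!(nbr$di == 0 & nbr$dj == 0), ]
  } else {
    nbr <- data.frame(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  }
  count <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j] || seen[i, j]) next
      count <- count + 1L
      queue <- list(c(i, j))
      seen[i, j] <- TRUE
      while (length(queue) > 0L) {
        p <- queue[[1L]]
        queue <- queue[-1L]
        for (q in seq_len(nrow(nbr))) {
          ii <- p[1L] + nbr$di[q]
          jj <- p[2L] + nbr$dj[q]
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] && !seen[ii, jj]) {
            seen[ii, jj] <- TRUE
            queue[[length(queue) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  count
}

# exposed-edge count by per-pixel neighbour inspection
oracle_edge_length <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask)
  nc <- ncol(mask)
  total <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1L]
        jj <- j + d[2L]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj])
          total <- total + 1L
      }
    }
  }
  total
}

# upper-tail t and F probabilities by numerical integration of the density
# written out from the gamma-function form (independent of pbeta/pt/pf)
oracle_t_two_sided_p <- function(t_stat, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(t_stat), Inf, rel.tol = 1e-12)$value
}

oracle_f_upper_p <- function(f_stat, df1, df2) {
  dens <- function(x) {
    exp(lgamma((df1 + df2) / 2) - lgamma(df1 / 2) - lgamma(df2 / 2) +
          (df1 / 2) * log(df1 / df2) + (df1 / 2 - 1) * log(x) -
          ((df1 + df2) / 2) * log(1 + df1 * x / df2))
  }
  stats::integrate(dens, f_stat, Inf, rel.tol = 1e-12)$value
}

random_mask <- function(nr = 16, nc = 16, p = 0.4) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}
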