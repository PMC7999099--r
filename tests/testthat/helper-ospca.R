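# Shared fixtures and independent oracles for the test suite.

# single-group design over n ordered samples
chain_design <- function(n) {
  sample_design(paste0("s", seq_len(n)), rep("a", n), seq_len(n))
}

# random autoscaled instance with a single-group chain design
rand_instance <- function(n, p, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("m", seq_len(p))))
  list(x = suppressWarnings(autoscale(x)), design = chain_design(n))
}

# independent Benjamini-Hochberg step-up implementation (oracle only)
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  i <- order(p)
  q <- pmin(rev(cummin(rev(p[i] * m / seq_len(m)))), 1)
  out <- numeric(m)
  out[i] <- q
  out
}

# brute-force difference operator: per-group stencil convolution by loops
diff_oracle <- function(design, ord) {
  n <- nrow(design)
  sten <- if (ord == 1) c(1, -1) else c(1, -2, 1)
  rows <- list()
  for (g in unique(design$group)) {
    idx <- which(design$group == g)
    if (length(idx) <= ord) next
    for (r in seq_len(length(idx) - ord)) {
      z <- numeric(n)
      z[idx[r:(r + ord)]] <- sten
      rows[[length(rows) + 1L]] <- z
    }
  }
  do.call(rbind, rows)
}

# covariance objective of the orthogonal smoothed decomposition
cov_objective <- function(x, wx, wy) {
  drop(crossprod(x %*% wx, x %*% wy)) / nrow(x)
}

# multi-restart numerical maximization of the objective over the
# constraint surface (unit w_x, unit penalty-norm w_y)
search_objective_max <- function(x, P, restarts = 20, seed = 1) {
  n <- nrow(x)
  p <- ncol(x)
  G <- crossprod(x)
  f <- function(par) {
    a <- par[1:p]
    b <- par[(p + 1):(2 * p)]
    na <- sqrt(sum(a^2))
    nb <- sqrt(drop(crossprod(b, P %*% b)))
    if (na < 1e-8 || nb < 1e-8) return(1e6)
    -drop(crossprod(a, G %*% b)) / (n * na * nb)
  }
  set.seed(seed)
  best <- -Inf
  for (r in seq_len(restarts)) {
    res <- optim(rnorm(2 * p), f, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    best <- max(best, -res$value)
  }
  best
}

# component most associated with the ordered covariate (trend component)
trend_component <- function(fit) {
  unname(which.max(abs(order_association(fit, scores = "s"))))
}

max_abs <- function(x) max(abs(x))
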