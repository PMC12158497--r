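# Fixtures and independent oracles shared across the test files.

# one canonical gradual/binary block of the trial schema
makeBlock <- function(participant = 1, session = 1, block = 1,
                      condition = "NU", responses = rep("yes", 6),
                      missed = rep(FALSE, 6),
                      alphas = NULL) {
  if (is.null(alphas))
    alphas <- switch(condition,
      NU = seq(1, 0, by = -0.2), UN = seq(0, 1, by = 0.2),
      BINARY = c(1, 0, 1, 0, 1, 0))
  data.frame(participant = participant, session = session, block = block,
             condition = condition, position = 1:6,
             alpha = round(alphas, 10),
             response = ifelse(missed, NA_character_, responses),
             rt = ifelse(missed, NA_real_, 0.7), missed = missed,
             stringsAsFactors = FALSE)
}

# hand-rolled sequential update, independent of runBlock
oracleTrace <- function(alphas, C, lam, sigma, initialPrior = 0.5,
                        eps = 1e-9) {
  clip <- function(p) pmin(pmax(p, eps), 1 - eps)
  q <- clip(initialPrior)
  out <- data.frame(alpha = alphas, likelihood = NA_real_,
                    prior = NA_real_, posterior = NA_real_)
  for (t in seq_along(alphas)) {
    L <- clip(pnorm(2 * alphas[t] - C, mean = alphas[t], sd = sigma))
    ey <- clip(q)^lam * L^(1 - lam)
    en <- (1 - clip(q))^lam * (1 - L)^(1 - lam)
    p <- ey / (ey + en)
    out$likelihood[t] <- L
    out$prior[t] <- clip(q)
    out$posterior[t] <- clip(p)
    q <- p
  }
  out
}

# per-trial Bernoulli log-likelihood sum, independent of responseLogLik
oracleLogLik <- function(trials, C, lam, sigma, initialPrior = 0.5) {
  ll <- 0
  for (key in unique(paste(trials$session, trials$block))) {
    b <- trials[paste(trials$session, trials$block) == key, ]
    b <- b[order(b$position), ]
    tr <- oracleTrace(b$alpha, C, lam, sigma, initialPrior)
    for (t in seq_len(nrow(b))) {
      if (b$missed[t] || !b$response[t] %in% c("yes", "no")) next
      ll <- ll + if (b$response[t] == "yes") log(tr$posterior[t])
                 else log(1 - tr$posterior[t])
    }
  }
  ll
}

# brute-force anisotropic Gaussian KDE on the cell-center grid
oracleFdm <- function(x, y, gridShape, extent, bw) {
  xc <- (seq_len(gridShape[1]) - 0.5) * extent[1] / gridShape[1]
  yc <- (seq_len(gridShape[2]) - 0.5) * extent[2] / gridShape[2]
  dens <- matrix(0, nrow = gridShape[2], ncol = gridShape[1])
  for (r in seq_len(gridShape[2]))
    for (cc in seq_len(gridShape[1]))
      for (i in seq_along(x))
        dens[r, cc] <- dens[r, cc] +
          dnorm(xc[cc], x[i], bw[1]) * dnorm(yc[r], y[i], bw[2])
  dens / sum(dens)
}

# explicit projection-matrix residualization
oracleResid <- function(yv, X) {
  X <- cbind(1, X)
  P <- X %*% solve(crossprod(X)) %*% t(X)
  as.numeric(yv - P %*% yv)
}

# exact two-sided signed-rank p-value by enumeration of sign patterns
oracleSignedRank <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vnull <- as.numeric(signs %*% r)
  p <- 2 * min(mean(vnull <= v), mean(vnull >= v))
  list(statistic = v, p = min(1, p))
}

# DFT via explicit transform matrices (independent of stats::fft)
oracleSpectralComplexity <- function(img) {
  M <- nrow(img); N <- ncol(img)
  Wm <- outer(0:(M - 1), 0:(M - 1),
              function(k, m) exp(-2i * pi * k * m / M))
  Wn <- outer(0:(N - 1), 0:(N - 1),
              function(l, n) exp(-2i * pi * l * n / N))
  F <- Wm %*% img %*% t(Wn) / sqrt(M * N)
  P <- Mod(F)^2
  (sum(P) - P[1, 1]) / (M * N - 1)
}
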