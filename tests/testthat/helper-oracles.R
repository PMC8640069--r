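# Independent oracles used across test files. These deliberately avoid the
# package's own fitting paths: normal equations + t distribution for OLS,
# Newton-Raphson on the logistic log-likelihood, a literal running-sum walk
# for the enrichment score.

ols_oracle <- function(y, X) {
  xtx <- t(X) %*% X
  b <- solve(xtx, t(X) %*% y)
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(solve(xtx)))
  tval <- b / se
  list(coef = drop(b), se = se, t = drop(tval),
       p = 2 * pt(abs(drop(tval)), df, lower.tail = FALSE), df = df)
}

logistic_nr_oracle <- function(y, X, tol = 1e-12, maxit = 200) {
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  b <- rep(0, ncol(X))
  ll <- loglik(b)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    score <- t(X) %*% (y - mu)
    info <- t(X) %*% (X * w)
    step <- drop(solve(info, score))
    # step halving keeps the walk on the likelihood surface
    lambda <- 1
    repeat {
      cand <- b + lambda * step
      if (loglik(cand) >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    b <- b + lambda * step
    ll_new <- loglik(b)
    if (abs(ll_new - ll) < tol && max(abs(lambda * step)) < 1e-8) break
    ll <- ll_new
  }
  se <- sqrt(diag(solve(info)))
  list(coef = b, se = se)
}

# Literal O(N) running-sum walk over the whole ranked list.
es_brute <- function(scores, members, p = 1) {
  N <- length(scores)
  hit <- seq_len(N) %in% members
  w <- abs(scores)^p
  step <- ifelse(hit, w / sum(w[hit]), -1 / (N - sum(hit)))
  run <- cumsum(step)
  run[which(abs(run) >= max(abs(run)) - 1e-9)[1]]
}

nb_loglik <- function(beta, y, X, offset, alpha) {
  mu <- exp(drop(X %*% beta) + offset)
  size <- 1 / alpha
  sum(dnbinom(y, size = size, mu = mu, log = TRUE))
}

nb_score <- function(beta, y, X, offset, alpha) {
  mu <- exp(drop(X %*% beta) + offset)
  size <- 1 / alpha
  drop(t(X) %*% (y - (y + size) * mu / (mu + size)))
}

nb_mle_oracle <- function(y, X, offset, alpha) {
  o <- optim(rep(0, ncol(X)), nb_loglik, gr = nb_score, y = y, X = X,
             offset = offset, alpha = alpha, method = "BFGS",
             control = list(fnscale = -1, maxit = 1000, reltol = 1e-15))
  o$par
}
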