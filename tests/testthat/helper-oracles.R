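# Independent oracles: explicit-formula / direct-likelihood implementations
# used only to check the package's results, never sharing its code paths.

# OLS by explicit normal equations
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(coef = drop(b), se = sqrt(diag(solve(XtX)) * s2))
}

# Bartlett's homogeneity-of-variance statistic from the textbook formula
bartlett_oracle <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  s2 <- vapply(groups, var, 0)
  sp2 <- sum((n - 1) * s2) / (N - k)
  num <- (N - k) * log(sp2) - sum((n - 1) * log(s2))
  C <- 1 + (sum(1 / (n - 1)) - 1 / (N - k)) / (3 * (k - 1))
  K2 <- num / C
  list(K2 = K2, df = k - 1, p = pchisq(K2, k - 1, lower.tail = FALSE))
}

# One-way ANOVA from between/within mean squares
anova_oracle <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  gm <- mean(unlist(groups))
  ssb <- sum(n * (vapply(groups, mean, 0) - gm)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  Fv <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fv, df1 = k - 1, df2 = N - k,
       p = pf(Fv, k - 1, N - k, lower.tail = FALSE))
}

# Poisson log-link ML by straight Newton-Raphson on the log-likelihood
poisson_ml_oracle <- function(X, y, tol = 1e-13, maxit = 200) {
  b <- c(log(mean(y) + 0.01), rep(0, ncol(X) - 1))
  for (i in seq_len(maxit)) {
    mu <- exp(drop(X %*% b))
    step <- solve(crossprod(X * mu, X), crossprod(X, y - mu))
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  list(coef = drop(b),
       logLik = sum(dpois(y, exp(drop(X %*% b)), log = TRUE)))
}

# Negative-binomial (mean/size, log link) ML by quasi-Newton on
# (beta, log theta), started from the Poisson solution
nb_ml_oracle <- function(X, y) {
  nll <- function(par) {
    b <- par[-length(par)]
    th <- exp(par[length(par)])
    mu <- exp(drop(X %*% b))
    -sum(dnbinom(y, size = th, mu = mu, log = TRUE))
  }
  start <- c(poisson_ml_oracle(X, y)$coef, log(2))
  o <- optim(start, nll, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-15))
  o <- optim(o$par, nll, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-15))
  list(coef = o$par[-length(o$par)], theta = exp(o$par[length(o$par)]),
       logLik = -o$value)
}
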