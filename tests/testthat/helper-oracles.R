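# Independent oracles for the unit tests. These deliberately avoid the
# package's own code paths (and lme4's): dense linear algebra only.

# Direct solve of Henderson's mixed-model equations for the
# one-environment model y = mu + Z_g g + Z_r r + eps with given
# variance components.
hendersonBlup <- function(y, genotype, replicate, s2g, s2r, s2e) {
  g <- factor(genotype); r <- factor(replicate)
  Zg <- stats::model.matrix(~ g - 1)
  Zr <- stats::model.matrix(~ r - 1)
  X <- matrix(1, length(y), 1)
  Z <- cbind(Zg, Zr)
  lambda <- diag(c(rep(s2e / s2g, ncol(Zg)), rep(s2e / s2r, ncol(Zr))))
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(C, rhs)
  list(mu = sol[1], g = sol[1 + seq_len(ncol(Zg))])
}

# REML log-likelihood of the all-random across-environment model,
# computed from the marginal covariance of y (dense algebra).
remlLogLik <- function(y, genotype, environment, replicate, s2) {
  Zg <- stats::model.matrix(~ factor(genotype) - 1)
  Ze <- stats::model.matrix(~ factor(environment) - 1)
  Zr <- stats::model.matrix(~ interaction(environment, replicate) - 1)
  Zge <- stats::model.matrix(~ interaction(genotype, environment) - 1)
  V <- diag(s2[["eps"]], length(y)) + s2[["g"]] * tcrossprod(Zg) +
    s2[["e"]] * tcrossprod(Ze) + s2[["rep"]] * tcrossprod(Zr) +
    s2[["gxe"]] * tcrossprod(Zge)
  X <- matrix(1, length(y), 1)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtViX)$modulus) +
            sum(y * (P %*% y)))
}

# Brute-force REML for the across-environment model: maximize the
# dense log-likelihood over log-variances from several starts, then
# polish with a coordinate grid refinement.
bruteForceReml <- function(y, genotype, environment, replicate, starts) {
  obj <- function(logs2) {
    s2 <- exp(logs2)
    names(s2) <- c("g", "e", "gxe", "rep", "eps")
    -remlLogLik(y, genotype, environment, replicate, s2)
  }
  best <- NULL
  for (st in starts) {
    o <- stats::optim(log(pmax(st, 1e-8)), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # coordinate grid polish around the optimum
  par <- best$par
  for (pass in 1:3) {
    for (i in seq_along(par)) {
      grid <- par[i] + seq(-0.002, 0.002, by = 1e-4)
      vals <- vapply(grid, function(v) {
        p <- par; p[i] <- v; obj(p)
      }, numeric(1))
      par[i] <- grid[which.min(vals)]
    }
  }
  s2 <- exp(par)
  names(s2) <- c("g", "e", "gxe", "rep", "eps")
  s2
}

# Closed-form two-class OLS: slope is the class-mean difference, PVE is
# the squared point-biserial correlation x 100.
twoClassOls <- function(y, x) {
  slope <- mean(y[x == 1]) - mean(y[x == 0])
  r <- stats::cor(x, y)
  n1 <- sum(x == 1); n0 <- sum(x == 0)
  sp2 <- (sum((y[x == 1] - mean(y[x == 1]))^2) +
            sum((y[x == 0] - mean(y[x == 0]))^2)) / (n0 + n1 - 2)
  se <- sqrt(sp2 * (1 / n0 + 1 / n1))
  t <- slope / se
  list(slope = slope, pve = 100 * r^2,
       p = 2 * stats::pt(-abs(t), n0 + n1 - 2))
}
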