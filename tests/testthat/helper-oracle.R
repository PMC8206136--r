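# Independent dense-matrix REML oracle for the random-intercept + AR(1)
# model. Deliberately naive: builds each individual's full covariance,
# computes the restricted log-likelihood from the closed-form expression
# with generic dense solves, and (optionally) maximises it with optim from
# a grid of starts. Shares no code with the package's fitter.
oracle_reml_loglik <- function(y, X, id, time, tau2, sigma2, phi) {
  ids <- unique(id)
  p <- ncol(X)
  logdetV <- 0
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  yVy <- 0
  for (g in ids) {
    sel <- id == g
    ti <- time[sel]
    Vi <- tau2 * matrix(1, sum(sel), sum(sel)) +
      sigma2 * phi^abs(outer(ti, ti, "-"))
    Vinv <- solve(Vi)
    Xi <- X[sel, , drop = FALSE]
    yi <- y[sel]
    logdetV <- logdetV + determinant(Vi, logarithm = TRUE)$modulus
    XtVX <- XtVX + t(Xi) %*% Vinv %*% Xi
    XtVy <- XtVy + t(Xi) %*% Vinv %*% yi
    yVy <- yVy + drop(t(yi) %*% Vinv %*% yi)
  }
  beta <- solve(XtVX, XtVy)
  quad <- yVy - drop(t(XtVy) %*% beta)
  as.numeric(
    -0.5 * (as.numeric(logdetV) +
              as.numeric(determinant(XtVX, logarithm = TRUE)$modulus) +
              quad + (length(y) - p) * log(2 * pi))
  )
}

oracle_reml_maximise <- function(y, X, id, time) {
  obj <- function(par) {
    -oracle_reml_loglik(y, X, id, time, exp(par[1]), exp(par[2]),
                        tanh(par[3]))
  }
  starts <- expand.grid(lt = log(c(0.05, 0.5)), ls = log(c(0.1, 1)),
                        az = atanh(c(0, 0.5)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                 lower = c(-20, -20, atanh(-0.99)),
                 upper = c(10, 10, atanh(0.99)),
                 control = list(factr = 10))
    if (is.null(best) || res$value < best$value) best <- res
  }
  list(loglik = -best$value, tau2 = exp(best$par[1]),
       sigma2 = exp(best$par[2]), phi = tanh(best$par[3]))
}
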