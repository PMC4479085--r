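# Freidlin-Wentzell Hamiltonian of a jump process with channels
# (rate a_j(x), jump nu_j):  H(x, p) = sum_j a_j(x) (exp(nu_j . p) - 1).
# H(x, 0) = 0 for every x and H_p(x, 0) is the mean-field drift; the
# quasi-potential solves the Hamilton-Jacobi equation H(x, grad S) = 0.

EXP_CAP <- 500  # cap on exponent arguments; overflow guard, reported

capExp <- function(z) {
  capped <- any(z > EXP_CAP)
  if (capped) z <- pmin(z, EXP_CAP)
  structure(exp(z), capped = capped)
}

#' Freidlin-Wentzell Hamiltonian of a channel set
#'
#' @param x state vector (length d, non-negative)
#' @param p momentum vector (length d)
#' @param channels a channel set as returned by [reducedChannels()]: a
#'   list with `jumps` (nChannels x d matrix) and `rate(x)`; an optional
#'   `rateJac(x)` (nChannels x d matrix of rate derivatives) enables
#'   analytic state-gradients
#' @param params optional parameter set; if supplied, `channels` defaults
#'   to [reducedChannels()] of it
#' @return scalar H with attributes `Hp` (gradient in p), `Hpp` (Hessian
#'   in p) and `capped` (TRUE if the overflow guard engaged)
#' @examples
#' p <- paramsPreset("fast")
#' hamiltonian(c(10, 500), c(0, 0), params = p)  # exactly 0 at p = 0
#' @export
hamiltonian <- function(x, p, channels = NULL, params = NULL) {
  if (is.null(channels)) {
    stopifnot(!is.null(params))
    channels <- reducedChannels(params)
  }
  if (any(x < 0)) stop("state must be non-negative")
  a <- channels$rate(x)
  e <- capExp(as.vector(channels$jumps %*% p))
  H <- sum(a * (e - 1))
  Hp <- as.vector(t(channels$jumps) %*% (a * e))
  Hpp <- t(channels$jumps) %*% (channels$jumps * (a * as.vector(e)))
  structure(H, Hp = Hp, Hpp = Hpp, capped = attr(e, "capped"))
}

# gradient of H in x at fixed p (needs rateJac; finite-difference fallback)
hamiltonianGradX <- function(x, p, channels) {
  e <- capExp(as.vector(channels$jumps %*% p))
  if (!is.null(channels$rateJac)) {
    as.vector(t(channels$rateJac(x)) %*% (e - 1))
  } else {
    d <- length(x)
    h <- pmax(1e-6 * abs(x), 1e-6)
    vapply(seq_len(d), function(i) {
      xp <- x; xp[i] <- x[i] + h[i]
      xm <- x; xm[i] <- max(x[i] - h[i], 0)
      ap <- channels$rate(xp); am <- channels$rate(xm)
      sum((ap - am) * (e - 1)) / (xp[i] - xm[i])
    }, numeric(1))
  }
}

# Support-function solve: l(x, delta) = sup { p . delta : H(x, p) <= 0 },
# the per-segment geometric action density.  The maximiser satisfies
# delta = mu * H_p(x, p) with mu > 0 and H(x, p) = 0.  The (p, mu) system
# is solved jointly by damped Newton (H is strictly convex in p wherever
# enough rates are positive), seeded from the warm start of the previous
# evaluation or from the closed form of the quadratic (Gaussian)
# approximation  mu0 = sqrt(delta' A^-1 delta / b' A^-1 b)  with
# A = H_pp(0), b = drift.  A bracketed bisection on log(mu) with a nested
# p-Newton is kept as the fallback.  Returns l with the maximiser p and
# the multiplier mu attached.
supportAction <- function(x, delta, channels, warm = NULL, tol = 1e-11) {
  a0 <- channels$rate(x)
  if (all(a0 <= 0)) return(structure(0, p = delta * 0, mu = NA_real_))
  nu <- channels$jumps
  d <- ncol(nu)
  b <- as.vector(crossprod(nu, a0))             # drift
  A <- crossprod(nu, nu * a0)                   # H_pp at p = 0
  quad <- tryCatch({
    u <- solve(A, delta); v <- solve(A, b)
    sqrt(max(sum(delta * u), 0) / max(sum(b * v), 1e-300))
  }, error = function(e) 1)
  if (!is.finite(quad) || quad <= 0) quad <- 1

  hparts <- function(p) {
    z <- pmin(as.vector(nu %*% p), EXP_CAP)
    e <- exp(z)
    ae <- a0 * e
    list(H = sum(ae) - sum(a0), Hp = as.vector(crossprod(nu, ae)),
         Hpp = crossprod(nu, nu * ae))
  }

  scl <- max(abs(delta), 1e-12)
  atol <- 1e-12 * max(sum(a0), 1)

  # joint Newton on F = (mu*Hp - delta, H)
  p <- if (!is.null(warm$p)) warm$p else
    tryCatch(as.vector(solve(A, delta / quad - b)), error = function(e)
      numeric(d))
  mu <- if (!is.null(warm$mu) && is.finite(warm$mu) && warm$mu > 0)
    warm$mu else quad
  okJoint <- FALSE
  for (it in 1:40) {
    hp <- hparts(p)
    Fv <- c(mu * hp$Hp - delta, hp$H)
    if (max(abs(Fv[1:d])) < tol * scl * max(mu, 1) &&
        abs(Fv[d + 1]) < atol * 10) { okJoint <- TRUE; break }
    J <- rbind(cbind(mu * hp$Hpp, hp$Hp), c(hp$Hp, 0))
    stepv <- tryCatch(solve(J, Fv), error = function(e) NULL)
    if (is.null(stepv) || any(!is.finite(stepv))) break
    sc <- 1
    repeat {
      pN <- p - sc * stepv[1:d]
      muN <- mu - sc * stepv[d + 1]
      if ((muN > 0 && max(abs(nu %*% pN)) < EXP_CAP) || sc < 1e-8) break
      sc <- sc / 2
    }
    if (muN <= 0) break
    p <- pN; mu <- muN
  }
  if (okJoint) {
    l <- sum(p * delta)
    # the sup is >= 0 (p = 0 is feasible); a negative branch means the
    # Newton landed on the antipodal tangency point
    if (l >= -atol) return(structure(max(l, 0), p = p, mu = mu))
  }

  # fallback: bisection on log(mu) around the quadratic seed
  solveP <- function(mu, pInit) {
    p <- pInit
    for (it in 1:60) {
      hp <- hparts(p)
      g <- mu * hp$Hp - delta
      if (max(abs(g)) < tol * max(1, scl)) break
      stepv <- tryCatch(solve(mu * hp$Hpp, g), error = function(e) g * 0)
      if (all(stepv == 0)) break
      sc <- 1
      repeat {
        pNew <- p - sc * stepv
        if (max(abs(nu %*% pNew)) < EXP_CAP || sc < 1e-6) break
        sc <- sc / 2
      }
      p <- pNew
    }
    p
  }
  pw <- numeric(d)
  phi <- function(logMu) {
    pw <<- solveP(exp(logMu), pw)
    hparts(pw)$H
  }
  lm0 <- log(quad)
  f0 <- phi(lm0)
  if (abs(f0) <= atol)
    return(structure(max(sum(pw * delta), 0), p = pw, mu = exp(lm0)))
  lo <- hi <- lm0; flo <- fhi <- f0
  for (it in 1:80) {
    if (fhi > 0) { lo <- hi; flo <- fhi; hi <- hi + 0.5; fhi <- phi(hi) }
    else break
  }
  for (it in 1:80) {
    if (flo < 0) { hi <- lo; fhi <- flo; lo <- lo - 0.5; flo <- phi(lo) }
    else break
  }
  if (flo < 0 || fhi > 0) {
    p <- solveP(quad, pw)
    return(structure(max(sum(p * delta), 0), p = p, mu = quad))
  }
  root <- stats::uniroot(phi, c(lo, hi), f.lower = flo, f.upper = fhi,
                         tol = 1e-9)
  mu <- exp(root$root)
  p <- solveP(mu, pw)
  structure(max(sum(p * delta), 0), p = p, mu = mu)
}
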