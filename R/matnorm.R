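## Matrix-variate normal distribution.
##
## M ~ MN(H, Omega, Sigma) (n x p) means vec(M) ~ N(vec(H), Sigma (x) Omega):
## Omega is the among-row covariance, Sigma the among-column covariance.
## Densities and draws are computed without ever forming the np x np
## Kronecker product.

#' Matrix-variate normal log-density
#'
#' Log-density of an n x p matrix \code{M} under the matrix-variate normal
#' distribution with location \code{H}, row covariance \code{Omega} (n x n)
#' and column covariance \code{Sigma} (p x p), i.e. of \code{vec(M)} under
#' a multivariate normal with covariance \code{Sigma \%x\% Omega}. Uses the
#' trace identity
#' \deqn{-\tfrac{np}{2}\log 2\pi - \tfrac{p}{2}\log|\Omega|
#'       - \tfrac{n}{2}\log|\Sigma|
#'       - \tfrac12 \mathrm{tr}\{\Sigma^{-1}(M-H)^T\Omega^{-1}(M-H)\}}
#' so the cost is two Cholesky factorisations, never an np x np solve.
#'
#' @param M,H n x p numeric matrices (observation and location).
#' @param Omega n x n positive-definite row covariance.
#' @param Sigma p x p positive-definite column covariance.
#' @return The log-density (a scalar).
#' @export
dmatnorm <- function(M, H, Omega, Sigma) {
  M <- as.matrix(M); H <- as.matrix(H)
  n <- nrow(M); p <- ncol(M)
  stopifnot(nrow(H) == n, ncol(H) == p,
            nrow(Omega) == n, ncol(Omega) == n,
            nrow(Sigma) == p, ncol(Sigma) == p)
  Ro <- tryCatch(chol(Omega),
                 error = function(e) stop("Omega is not positive definite",
                                          call. = FALSE))
  Rs <- tryCatch(chol(Sigma),
                 error = function(e) stop("Sigma is not positive definite",
                                          call. = FALSE))
  D <- M - H
  ## tr(Sigma^-1 D' Omega^-1 D) = || Ro^-T D Rs^-1 ||_F^2
  A <- backsolve(Ro, D, transpose = TRUE)          # Ro^-T D
  B <- t(backsolve(Rs, t(A), transpose = TRUE))    # A Rs^-1
  quad <- sum(B * B)
  -0.5 * n * p * log(2 * pi) - p * sum(log(diag(Ro))) -
    n * sum(log(diag(Rs))) - 0.5 * quad
}

#' Draw from the matrix-variate normal distribution
#'
#' Returns \code{H + A Z B'} with \code{A A' = Omega}, \code{B B' = Sigma}
#' and \code{Z} an n x p matrix of i.i.d. standard normals, so that
#' \code{vec(draw)} has mean \code{vec(H)} and covariance
#' \code{Sigma \%x\% Omega}.
#'
#' @param H n x p location matrix.
#' @param Omega n x n positive-(semi)definite row covariance.
#' @param Sigma p x p positive-(semi)definite column covariance.
#' @return One n x p draw.
#' @export
rmatnorm <- function(H, Omega, Sigma) {
  H <- as.matrix(H)
  n <- nrow(H); p <- ncol(H)
  stopifnot(nrow(Omega) == n, ncol(Omega) == n,
            nrow(Sigma) == p, ncol(Sigma) == p)
  A <- psd_factor(Omega)
  B <- psd_factor(Sigma)
  Z <- matrix(stats::rnorm(n * p), n, p)
  H + A %*% Z %*% t(B)
}

## Lower-triangular-ish factor F with F F' = S; falls back to an
## eigendecomposition for positive semi-definite S.
psd_factor <- function(S) {
  F <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (!is.null(F)) return(F)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S))
}

## Inverse-Wishart draw: X ~ IW(nu, S) iff X^-1 ~ Wishart(nu, S^-1),
## density of X proportional to |X|^-(nu+d+1)/2 exp(-tr(S X^-1)/2).
## Mean S / (nu - d - 1) for nu > d + 1. Uses stats::rWishart.
rinvwishart <- function(nu, S) {
  d <- nrow(S)
  stopifnot(nu > d - 1)
  Sinv <- chol2inv(chol(S))
  Sinv <- (Sinv + t(Sinv)) / 2
  W <- stats::rWishart(1, df = nu, Sigma = Sinv)[, , 1]
  X <- chol2inv(chol(W))
  (X + t(X)) / 2
}

## Draw from N(P^-1 r, P^-1) given the precision matrix P and the
## canonical mean vector r (the "information form" used by every Gibbs
## block). Returns a plain numeric vector.
rmvn_canonical <- function(P, r) {
  R <- tryCatch(chol(P), error = function(e)
    stop("singular conditional precision; consider jittering the GRM",
         call. = FALSE))
  mu <- backsolve(R, backsolve(R, r, transpose = TRUE))
  mu + backsolve(R, stats::rnorm(length(r)))
}
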