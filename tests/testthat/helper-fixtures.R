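## Shared fixtures, built in code at test time.

## A tiny fully observed dataset with a known GRM.
tiny_dataset <- function(J = 6, I = 2, L = 2, p = 40, seed = 101, ...) {
  simulate_dataset(J = J, I = I, L = L, p = p, seed = seed, ...)
}

## Hand-buildable phenotype table for constructor tests.
toy_pheno <- function() {
  data.frame(
    Line = rep(c("A", "B", "C"), times = 2),
    Env = rep(c("E1", "E2"), each = 3),
    T1 = c(1, 2, 3, 4, 5, 6),
    T2 = c(6, 5, 4, 3, 2, 1)
  )
}

toy_grm <- function(lines = c("A", "B", "C")) {
  G <- diag(length(lines)) + 0.1
  dimnames(G) <- list(lines, lines)
  G
}

## Brute-force multivariate-normal log-density of vec(M) via the explicit
## Kronecker covariance; the oracle dmatnorm() is tested against.
kron_logpdf <- function(M, H, Omega, Sigma) {
  S <- kronecker(Sigma, Omega)
  x <- as.vector(M - H)
  d <- length(x)
  -0.5 * (d * log(2 * pi) +
            as.numeric(determinant(S, logarithm = TRUE)$modulus) +
            sum(x * solve(S, x)))
}

## Conditional mean of the vectorised fast-path Gibbs sampler (noise
## zeroed); mirrors sample_rows_canonical() for the equivalence tests.
with_mean_only <- function(Rt, Sti, Rei, w, cc) {
  L <- ncol(Rt)
  Ui <- backsolve(chol(Rei), diag(L))
  e <- eigen(crossprod(Ui, Sti %*% Ui), symmetric = TRUE)
  Q <- Ui %*% e$vectors
  D <- outer(w, e$values) + cc
  ((Rt %*% Q) / D) %*% t(Q)
}

## Naive Pearson correlation from first principles.
naive_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
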