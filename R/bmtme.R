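## Bayesian multi-trait multi-environment mixed model (matrix-variate
## GBLUP) fitted by Gibbs sampling.
##
## Model, with n = J lines x I environments rows and L trait columns:
##
##   Y = X beta + Z1 b1 + Z2 b2 + E
##
##   b1 ~ MN(0, Gg, Sigma_t)            genotype x trait effects (J x L)
##   b2 ~ MN(0, Sigma_E (x) Gg, Sigma_t) genotype x environment x trait
##                                        effects (IJ x L, optional)
##   E  ~ MN(0, I_n, Re)                 residuals
##
## Gg is the genomic relationship matrix, Sigma_t / Sigma_E / Re are
## unstructured trait / environment / residual covariances with
## inverse-Wishart priors. Cells held out for prediction are dropped from
## every likelihood contribution by row-subsetting the design matrices.
##
## Full conditionals follow from multivariate-normal and inverse-Wishart
## conjugacy:
##   vec(beta) | .  ~ N with precision Re^-1 (x) X'X + lambda I
##   vec(b1)   | .  ~ N with precision Sigma_t^-1 (x) Gg^-1 + Re^-1 (x) Z1'Z1
##   vec(b2)   | .  ~ N with precision
##                    Sigma_t^-1 (x) Sigma_E^-1 (x) Gg^-1 + Re^-1 (x) Z2'Z2
##   Sigma_t   | .  ~ IW(nu_t + J + IJ,
##                       S_t + b1' Gg^-1 b1 + b2' (Sigma_E^-1 (x) Gg^-1) b2)
##   Sigma_E   | .  ~ IW(nu_E + J L, S_E + Q),
##                    Q[i,i'] = tr(Sigma_t^-1 b2_(i')' Gg^-1 b2_(i))
##   Re        | .  ~ IW(nu_e + n_obs, S_e + E'E)
## Correctness of these blocks is certified by brute-force oracles, a
## Metropolis single-site comparison and a Geweke joint-distribution test
## in the package test suite.

#' Prior specification for the Bayesian multi-trait model
#'
#' Defaults are weakly informative proper priors: inverse-Wishart with
#' degrees of freedom dim + 2 and identity scale for each covariance
#' matrix, and a flat (improper) prior on the fixed environment-by-trait
#' means (\code{beta_precision = 0}). Any component left \code{NULL} is
#' resolved at fit time from the data dimensions.
#'
#' @param nu_t,S_t Inverse-Wishart degrees of freedom and scale for the
#'   genetic trait covariance \code{Sigma_t} (L x L).
#' @param nu_E,S_E Inverse-Wishart parameters for the environment
#'   covariance \code{Sigma_E} (I x I; only used with the
#'   genotype-by-environment term).
#' @param nu_e,S_e Inverse-Wishart parameters for the residual covariance
#'   \code{Re} (L x L).
#' @param beta_precision Ridge precision on each element of beta; 0 gives
#'   a flat prior.
#' @return An object of class \code{bmtme_priors}.
#' @export
bmtme_priors <- function(nu_t = NULL, S_t = NULL, nu_E = NULL, S_E = NULL,
                         nu_e = NULL, S_e = NULL, beta_precision = 0) {
  stopifnot(beta_precision >= 0)
  structure(list(nu_t = nu_t, S_t = S_t, nu_E = nu_E, S_E = S_E,
                 nu_e = nu_e, S_e = S_e, beta_precision = beta_precision),
            class = "bmtme_priors")
}

resolve_priors <- function(priors, L, I) {
  if (is.null(priors)) priors <- bmtme_priors()
  stopifnot(inherits(priors, "bmtme_priors"))
  p <- priors
  if (is.null(p$nu_t)) p$nu_t <- L + 2
  if (is.null(p$S_t)) p$S_t <- diag(L)
  if (is.null(p$nu_E)) p$nu_E <- I + 2
  if (is.null(p$S_E)) p$S_E <- diag(I)
  if (is.null(p$nu_e)) p$nu_e <- L + 2
  if (is.null(p$S_e)) p$S_e <- diag(L)
  if (p$nu_t <= L - 1 || p$nu_e <= L - 1 || p$nu_E <= I - 1)
    stop("inverse-Wishart degrees of freedom must exceed dim - 1",
         call. = FALSE)
  check_pd(p$S_t, "S_t"); check_pd(p$S_E, "S_E"); check_pd(p$S_e, "S_e")
  p
}

## Precompute everything the Gibbs blocks need: observed-row designs,
## cross-products, counts, and the GRM eigendecomposition (with a small
## diagonal jitter when Gg is numerically singular, so Gg^-1 exists).
gibbs_prep <- function(ds, include_gxe, rows = observed_rows(ds)) {
  J <- length(ds$line_ids); I <- length(ds$env_ids)
  L <- length(ds$trait_ids)
  if (length(rows) == 0) stop("no observed cells to fit on", call. = FALSE)
  env_idx <- match(ds$cells$Env[rows], ds$env_ids)
  line_idx <- match(ds$cells$Line[rows], ds$line_ids)
  if (length(unique(env_idx)) < I)
    stop("every environment needs at least one observed cell",
         call. = FALSE)
  cell_idx <- (env_idx - 1L) * J + line_idx

  G <- ds$grm
  eg <- eigen(G, symmetric = TRUE)
  dmax <- max(eg$values)
  if (min(eg$values) < 1e-8 * dmax) {
    eps <- max(1e-8 * sum(diag(G)) / J, 1e-8 * dmax, 1e-12)
    G <- G + diag(eps, J)
    eg <- eigen(G, symmetric = TRUE)
  }
  Ginv <- eg$vectors %*% (t(eg$vectors) / eg$values)
  Ginv <- (Ginv + t(Ginv)) / 2

  X <- matrix(0, length(rows), I)
  X[cbind(seq_along(rows), env_idx)] <- 1
  k1 <- tabulate(line_idx, nbins = J)          # Z1'Z1 diagonal
  k2 <- tabulate(cell_idx, nbins = I * J)      # Z2'Z2 diagonal (0/1)

  list(J = J, I = I, L = L, n_obs = length(rows), rows = rows,
       env_idx = env_idx, line_idx = line_idx, cell_idx = cell_idx,
       X = X, XtX = crossprod(X), k1 = k1, k2 = k2,
       balanced1 = length(unique(k1)) == 1L && k1[1] > 0,
       balanced2 = all(k2 == 1L),
       G = G, U = eg$vectors, d = eg$values, Ginv = Ginv,
       include_gxe = include_gxe)
}

## Linear predictor at the observed rows for the current state.
lp_obs <- function(state, prep) {
  out <- state$beta[prep$env_idx, , drop = FALSE] +
    state$b1[prep$line_idx, , drop = FALSE]
  if (prep$include_gxe) out <- out + state$b2[prep$cell_idx, , drop = FALSE]
  out
}

# ---- conditional blocks -------------------------------------------------

gibbs_step_beta <- function(Y, state, prep, priors) {
  resid <- Y - state$b1[prep$line_idx, , drop = FALSE]
  if (prep$include_gxe)
    resid <- resid - state$b2[prep$cell_idx, , drop = FALSE]
  Rei <- chol2inv(chol(state$Re))
  P <- kronecker(Rei, prep$XtX)
  if (priors$beta_precision > 0)
    P <- P + diag(priors$beta_precision, nrow(P))
  rhs <- as.vector(crossprod(prep$X, resid) %*% Rei)
  state$beta <- matrix(rmvn_canonical(P, rhs), prep$I, prep$L)
  state
}

## Canonical form (precision, rhs) of the b1 conditional; used by the
## dense sampler and by the equivalence tests against the eigen fast path.
b1_canonical <- function(Y, state, prep) {
  resid <- Y - state$beta[prep$env_idx, , drop = FALSE]
  if (prep$include_gxe)
    resid <- resid - state$b2[prep$cell_idx, , drop = FALSE]
  T1 <- rowsum_by(resid, prep$line_idx, prep$J)
  Rei <- chol2inv(chol(state$Re))
  Sti <- chol2inv(chol(state$Sigma_t))
  P <- kronecker(Sti, prep$Ginv) + kronecker(Rei, diag(prep$k1, prep$J))
  list(P = P, rhs = as.vector(T1 %*% Rei), T1 = T1, Rei = Rei, Sti = Sti)
}

gibbs_step_b1 <- function(Y, state, prep, method = c("auto", "eigen",
                                                     "dense")) {
  method <- match.arg(method)
  use_eigen <- (method == "eigen") ||
    (method == "auto" && prep$balanced1)
  if (use_eigen && !prep$balanced1)
    stop("eigen fast path requires balanced line replication",
         call. = FALSE)
  if (use_eigen) {
    resid <- Y - state$beta[prep$env_idx, , drop = FALSE]
    if (prep$include_gxe)
      resid <- resid - state$b2[prep$cell_idx, , drop = FALSE]
    T1 <- rowsum_by(resid, prep$line_idx, prep$J)
    Rei <- chol2inv(chol(state$Re))
    Sti <- chol2inv(chol(state$Sigma_t))
    cc <- prep$k1[1]
    Rt <- crossprod(prep$U, T1) %*% Rei        # rotated canonical mean
    state$b1 <- prep$U %*%
      sample_rows_canonical(Rt, Sti, Rei, 1 / prep$d, cc)
  } else {
    can <- b1_canonical(Y, state, prep)
    state$b1 <- matrix(rmvn_canonical(can$P, can$rhs), prep$J, prep$L)
  }
  state
}

b2_canonical <- function(Y, state, prep) {
  resid <- Y - state$beta[prep$env_idx, , drop = FALSE] -
    state$b1[prep$line_idx, , drop = FALSE]
  T2 <- rowsum_by(resid, prep$cell_idx, prep$I * prep$J)
  Rei <- chol2inv(chol(state$Re))
  Sti <- chol2inv(chol(state$Sigma_t))
  SEi <- chol2inv(chol(state$Sigma_E))
  P <- kronecker(Sti, kronecker(SEi, prep$Ginv)) +
    kronecker(Rei, diag(prep$k2, prep$I * prep$J))
  list(P = P, rhs = as.vector(T2 %*% Rei), T2 = T2,
       Rei = Rei, Sti = Sti, SEi = SEi)
}

gibbs_step_b2 <- function(Y, state, prep, method = c("auto", "eigen",
                                                     "dense")) {
  method <- match.arg(method)
  if (!prep$include_gxe)
    stop("genotype x environment term is not part of this model",
         call. = FALSE)
  use_eigen <- (method == "eigen") ||
    (method == "auto" && prep$balanced2)
  if (use_eigen && !prep$balanced2)
    stop("eigen fast path requires every cell observed", call. = FALSE)
  J <- prep$J; I <- prep$I; L <- prep$L
  if (use_eigen) {
    resid <- Y - state$beta[prep$env_idx, , drop = FALSE] -
      state$b1[prep$line_idx, , drop = FALSE]
    T2 <- rowsum_by(resid, prep$cell_idx, I * J)
    Rei <- chol2inv(chol(state$Re))
    Sti <- chol2inv(chol(state$Sigma_t))
    ee <- eigen(state$Sigma_E, symmetric = TRUE)
    ## rotate by (V (x) U): apply U' over lines, V over environments
    Rt <- T2 %*% Rei
    Rt <- apply_kron_rotation(Rt, t(prep$U), t(ee$vectors), J, I)
    lam <- as.vector(outer(prep$d, ee$values))  # d_j * e_i, j fastest
    btil <- sample_rows_canonical(Rt, Sti, Rei, 1 / lam, 1)
    state$b2 <- apply_kron_rotation(btil, prep$U, ee$vectors, J, I)
  } else {
    can <- b2_canonical(Y, state, prep)
    state$b2 <- matrix(rmvn_canonical(can$P, can$rhs), I * J, L)
  }
  state
}

gibbs_step_sigma_t <- function(state, prep, priors) {
  S <- priors$S_t + crossprod(state$b1, prep$Ginv %*% state$b1)
  df <- priors$nu_t + prep$J
  if (prep$include_gxe) {
    SEi <- chol2inv(chol(state$Sigma_E))
    S <- S + quad_form_kron(state$b2, SEi, prep$Ginv, prep$J, prep$I)
    df <- df + prep$I * prep$J
  }
  state$Sigma_t <- rinvwishart(df, (S + t(S)) / 2)
  state
}

gibbs_step_sigma_E <- function(state, prep, priors) {
  if (!prep$include_gxe)
    stop("Sigma_E is not part of the model without the G x E term",
         call. = FALSE)
  J <- prep$J; I <- prep$I
  Sti <- chol2inv(chol(state$Sigma_t))
  blocks <- lapply(seq_len(I), function(i)
    state$b2[((i - 1) * J + 1):(i * J), , drop = FALSE])
  GA <- lapply(blocks, function(B) prep$Ginv %*% B)
  Q <- matrix(0, I, I)
  for (i in seq_len(I))
    for (ip in seq_len(i)) {
      Q[i, ip] <- sum(Sti * (crossprod(blocks[[ip]], GA[[i]])))
      Q[ip, i] <- Q[i, ip]
    }
  state$Sigma_E <- rinvwishart(priors$nu_E + J * prep$L, priors$S_E + Q)
  state
}

gibbs_step_Re <- function(Y, state, prep, priors) {
  Eres <- Y - lp_obs(state, prep)
  state$Re <- rinvwishart(priors$nu_e + prep$n_obs,
                          priors$S_e + crossprod(Eres))
  state
}

## Draw all rows of a matrix whose row r has conditional precision
## P_r = w_r * Sti + cc * Rei and canonical mean Rt[r, ]. Uses the
## simultaneous diagonalisation Q' Rei Q = I, Q' Sti Q = diag(a), under
## which P_r^-1 = Q diag(1 / (w_r a + cc)) Q', so every row is sampled
## with a handful of dense matrix products instead of a per-row Cholesky.
sample_rows_canonical <- function(Rt, Sti, Rei, w, cc) {
  L <- ncol(Rt)
  Ur <- chol(Rei)
  Ui <- backsolve(Ur, diag(L))
  e <- eigen(crossprod(Ui, Sti %*% Ui), symmetric = TRUE)
  Q <- Ui %*% e$vectors                       # Q' Rei Q = I
  D <- outer(w, e$values) + cc                # row r, diag entry l
  S1 <- Rt %*% Q
  Z <- matrix(stats::rnorm(length(Rt)), nrow(Rt), L)
  (S1 / D + Z / sqrt(D)) %*% t(Q)
}

## b2' (SEi (x) Ginv) b2 as an L x L matrix (environment-major row blocks
## of size J).
quad_form_kron <- function(b2, SEi, Ginv, J, I) {
  L <- ncol(b2)
  out <- matrix(0, L, L)
  blocks <- lapply(seq_len(I), function(i)
    b2[((i - 1) * J + 1):(i * J), , drop = FALSE])
  for (i in seq_len(I)) {
    Gb <- Ginv %*% blocks[[i]]
    for (ip in seq_len(I))
      out <- out + SEi[ip, i] * crossprod(blocks[[ip]], Gb)
  }
  out
}

## Column sums of `m` grouped by `idx` (1..nbins); rows with no
## contribution are zero.
rowsum_by <- function(m, idx, nbins) {
  out <- matrix(0, nbins, ncol(m))
  agg <- rowsum(m, group = idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

## Apply the Kronecker rotation (V (x) U) to an (I*J) x L matrix whose
## rows are ordered environment-major (line index fastest).
apply_kron_rotation <- function(M, U, V, J, I) {
  L <- ncol(M)
  out <- matrix(0, I * J, L)
  for (l in seq_len(L)) {
    A <- matrix(M[, l], J, I)
    out[, l] <- as.vector(U %*% A %*% t(V))
  }
  out
}

# ---- the sampler --------------------------------------------------------

init_state <- function(Y, prep) {
  L <- prep$L
  beta <- matrix(0, prep$I, L)
  for (i in seq_len(prep$I)) {
    ri <- prep$env_idx == i
    beta[i, ] <- colMeans(Y[ri, , drop = FALSE])
  }
  list(beta = beta,
       b1 = matrix(0, prep$J, L),
       b2 = matrix(0, prep$I * prep$J, L),
       Sigma_t = diag(L), Sigma_E = diag(prep$I), Re = diag(L))
}

one_sweep <- function(Y, state, prep, priors) {
  state <- gibbs_step_beta(Y, state, prep, priors)
  state <- gibbs_step_b1(Y, state, prep)
  if (prep$include_gxe) state <- gibbs_step_b2(Y, state, prep)
  state <- gibbs_step_sigma_t(state, prep, priors)
  if (prep$include_gxe) state <- gibbs_step_sigma_E(state, prep, priors)
  state <- gibbs_step_Re(Y, state, prep, priors)
  state
}

#' Fit the Bayesian multi-trait multi-environment model by Gibbs sampling
#'
#' Cycles exact draws from the full conditionals of the fixed
#' environment-by-trait means, the genotype-by-trait effects, the
#' (optional) genotype-by-environment-by-trait effects and the three
#' covariance matrices. Cells with missing trait values (the prediction
#' targets under cell-level cross-validation) are excluded from every
#' likelihood contribution.
#'
#' @param data An \code{\link{mtme_data}} object.
#' @param gxe Include the genotype-by-environment interaction term? When
#'   \code{FALSE}, the interaction effects and the environment covariance
#'   \code{Sigma_E} are simply not part of the model.
#' @param n_iter,burn_in,thin Chain length, burn-in and thinning; the
#'   number of retained draws is \code{floor((n_iter - burn_in) / thin)}.
#' @param priors A \code{\link{bmtme_priors}} object (\code{NULL} for
#'   defaults).
#' @param seed Integer seed making the chain fully reproducible.
#' @param keep_effects Retain per-draw chains of the random-effect
#'   matrices (posterior means are always available).
#' @param verbose Print progress every 1000 iterations.
#' @return An object of class \code{bmtme_fit} with posterior-mean
#'   parameters, retained chains, split-chain Rhat diagnostics and the
#'   run metadata.
#' @export
bmtme <- function(data, gxe = TRUE, n_iter = 10000, burn_in = 5000,
                  thin = 2, priors = NULL, seed = NULL,
                  keep_effects = TRUE, verbose = FALSE) {
  stopifnot(inherits(data, "mtme_data"), n_iter > burn_in, thin >= 1)
  prep <- gibbs_prep(data, include_gxe = gxe)
  priors <- resolve_priors(priors, prep$L, prep$I)
  Y <- data$Y[prep$rows, , drop = FALSE]
  n_keep <- floor((n_iter - burn_in) / thin)
  if (n_keep < 1) stop("no retained draws: increase n_iter", call. = FALSE)

  I <- prep$I; J <- prep$J; L <- prep$L
  chains <- list(
    beta = matrix(NA_real_, n_keep, I * L,
                  dimnames = list(NULL, label_grid("beta", data$env_ids,
                                                   data$trait_ids))),
    Sigma_t = matrix(NA_real_, n_keep, L * (L + 1) / 2,
                     dimnames = list(NULL, label_tri("Sigma_t", L))),
    Re = matrix(NA_real_, n_keep, L * (L + 1) / 2,
                dimnames = list(NULL, label_tri("Re", L)))
  )
  if (gxe)
    chains$Sigma_E <- matrix(NA_real_, n_keep, I * (I + 1) / 2,
                             dimnames = list(NULL, label_tri("Sigma_E", I)))
  if (keep_effects) {
    chains$b1 <- matrix(NA_real_, n_keep, J * L)
    if (gxe) chains$b2 <- matrix(NA_real_, n_keep, I * J * L)
  }
  mean_beta <- matrix(0, I, L); mean_b1 <- matrix(0, J, L)
  mean_b2 <- matrix(0, I * J, L)

  run <- function() {
    state <- init_state(Y, prep)
    kept <- 0L
    for (it in seq_len(n_iter)) {
      state <- one_sweep(Y, state, prep, priors)
      if (!all(vapply(state, function(x) all(is.finite(x)), logical(1))))
        stop(sprintf("sampler diverged (non-finite state) at iteration %d",
                     it), call. = FALSE)
      if (it > burn_in && (it - burn_in) %% thin == 0 && kept < n_keep) {
        kept <- kept + 1L
        chains$beta[kept, ] <<- as.vector(state$beta)
        chains$Sigma_t[kept, ] <<- lower_tri(state$Sigma_t)
        chains$Re[kept, ] <<- lower_tri(state$Re)
        if (gxe) chains$Sigma_E[kept, ] <<- lower_tri(state$Sigma_E)
        if (keep_effects) {
          chains$b1[kept, ] <<- as.vector(state$b1)
          if (gxe) chains$b2[kept, ] <<- as.vector(state$b2)
        }
        mean_beta <<- mean_beta + state$beta
        mean_b1 <<- mean_b1 + state$b1
        if (gxe) mean_b2 <<- mean_b2 + state$b2
      }
      if (verbose && it %% 1000 == 0)
        message(sprintf("iteration %d / %d", it, n_iter))
    }
    kept
  }
  kept <- with_seed(seed, run())

  post_mean <- list(beta = mean_beta / kept, b1 = mean_b1 / kept,
                    b2 = if (gxe) mean_b2 / kept else NULL)
  scalar_chains <- do.call(cbind, chains[c("beta", "Sigma_t", "Re",
                                           if (gxe) "Sigma_E")])
  structure(
    list(chains = chains, post_mean = post_mean,
         rhat = apply(scalar_chains, 2, split_rhat),
         line_ids = data$line_ids, env_ids = data$env_ids,
         trait_ids = data$trait_ids, gxe = gxe,
         settings = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                         seed = seed, n_keep = kept),
         priors = priors),
    class = "bmtme_fit")
}

label_grid <- function(what, rows, cols)
  paste0(what, "[", rep(rows, times = length(cols)), ",",
         rep(cols, each = length(rows)), "]")

label_tri <- function(what, d) {
  idx <- which(lower.tri(diag(d), diag = TRUE), arr.ind = TRUE)
  paste0(what, "[", idx[, 1], ",", idx[, 2], "]")
}

lower_tri <- function(S) S[lower.tri(S, diag = TRUE)]

## Split-chain potential scale reduction factor on one scalar chain.
split_rhat <- function(x) {
  n <- length(x) %/% 2
  if (n < 2) return(NA_real_)
  halves <- cbind(x[seq_len(n)], x[(length(x) - n + 1):length(x)])
  W <- mean(apply(halves, 2, stats::var))
  B <- n * stats::var(colMeans(halves))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.bmtme_fit <- function(x, ...) {
  cat(sprintf(
    "bmtme_fit: %d lines, %d environments, %d trait(s); G x E term: %s\n",
    length(x$line_ids), length(x$env_ids), length(x$trait_ids),
    if (x$gxe) "included" else "excluded"))
  cat(sprintf("  %d retained draws (n_iter = %d, burn_in = %d, thin = %d)\n",
              x$settings$n_keep, x$settings$n_iter, x$settings$burn_in,
              x$settings$thin))
  cat(sprintf("  max split-chain Rhat: %.3f\n", max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Posterior-mean predictions for line-by-environment cells
#'
#' Predictions are the posterior mean of the linear predictor
#' \code{X beta + Z1 b1 (+ Z2 b2)} at the requested cells. Cells that were
#' unobserved during fitting are predictable because the genomic
#' relationship matrix propagates information to their line effects.
#'
#' @param object A \code{bmtme_fit}.
#' @param cells A data.frame with columns \code{Line} and \code{Env};
#'   defaults to every cell of the training grid.
#' @param ... Unused.
#' @return A numeric matrix with one row per requested cell and one
#'   column per trait.
#' @export
predict.bmtme_fit <- function(object, cells = NULL, ...) {
  if (is.null(cells))
    cells <- data.frame(
      Line = rep(object$line_ids, times = length(object$env_ids)),
      Env = rep(object$env_ids, each = length(object$line_ids)),
      stringsAsFactors = FALSE)
  li <- match(as.character(cells$Line), object$line_ids)
  ei <- match(as.character(cells$Env), object$env_ids)
  if (anyNA(li))
    stop("unknown line id(s): ",
         paste(unique(cells$Line[is.na(li)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(ei))
    stop("unknown environment id(s): ",
         paste(unique(cells$Env[is.na(ei)]), collapse = ", "),
         call. = FALSE)
  J <- length(object$line_ids)
  pred <- object$post_mean$beta[ei, , drop = FALSE] +
    object$post_mean$b1[li, , drop = FALSE]
  if (object$gxe)
    pred <- pred + object$post_mean$b2[(ei - 1L) * J + li, , drop = FALSE]
  colnames(pred) <- object$trait_ids
  pred
}
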