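## Joint-distribution ("getting it right") validation of the Gibbs
## sampler. Two samplers target the same joint distribution p(theta, Y):
##
##   marginal-conditional:  theta ~ prior, Y | theta ~ model  (i.i.d.)
##   successive-conditional: alternate one Gibbs sweep of theta | Y with a
##     fresh simulation of Y | theta; started from an exact joint draw,
##     this chain is stationary from the first sweep.
##
## If every full conditional is correct, moments of any function of
## (theta, Y) agree between the two samplers; a coding error in any block
## shows up as a large z-score.

#' Joint-distribution check of the Gibbs sampler
#'
#' Runs the marginal-conditional and successive-conditional samplers on a
#' small simulated design and compares the means of a battery of test
#' statistics (covariance elements, fixed-effect and random-effect
#' moments, data moments). Under a correct sampler the z-scores are
#' approximately standard normal; |z| above about 4 on any statistic
#' indicates a defective conditional. Proper priors with finite second
#' moments are required, so the inverse-Wishart degrees of freedom
#' default to dim + 6 here and the prior on the fixed effects is a unit
#' normal rather than flat.
#'
#' @param J,I,L,p Lines, environments, traits and markers of the test
#'   design.
#' @param n_sweeps Number of draws from each sampler.
#' @param gxe Include the genotype-by-environment block.
#' @param priors Proper priors (finite-variance defaults if \code{NULL}).
#' @param seed Integer seed.
#' @return A data.frame with one row per test statistic: the two sampler
#'   means, the pooled standard error and the z-score.
#' @export
geweke_check <- function(J = 5, I = 2, L = 2, p = 30, n_sweeps = 50000,
                         gxe = TRUE, priors = NULL, seed = 1) {
  if (is.null(priors))
    priors <- bmtme_priors(nu_t = L + 6, nu_E = I + 6, nu_e = L + 6,
                           beta_precision = 1)
  if (priors$beta_precision <= 0)
    stop("the joint-distribution check needs a proper prior on beta",
         call. = FALSE)
  with_seed(seed, {
    W <- simulate_markers(J, p, seed = NULL)
    G <- compute_grm(W)
    ds <- skeleton_dataset(J, I, L, G)
    prep <- gibbs_prep(ds, include_gxe = gxe,
                       rows = seq_len(nrow(ds$cells)))
    priors <- resolve_priors(priors, L, I)

    draw_prior <- function() {
      st <- list(
        Sigma_t = rinvwishart(priors$nu_t, priors$S_t),
        Sigma_E = rinvwishart(priors$nu_E, priors$S_E),
        Re = rinvwishart(priors$nu_e, priors$S_e),
        beta = matrix(stats::rnorm(I * L,
                                   sd = 1 / sqrt(priors$beta_precision)),
                      I, L))
      st$b1 <- rmatnorm(matrix(0, J, L), prep$G, st$Sigma_t)
      st$b2 <- if (gxe)
        rmatnorm(matrix(0, I * J, L), kronecker(st$Sigma_E, prep$G),
                 st$Sigma_t)
      else matrix(0, I * J, L)
      st
    }
    draw_data <- function(st) {
      F <- psd_factor(st$Re)
      lp_obs(st, prep) +
        matrix(stats::rnorm(prep$n_obs * L), prep$n_obs, L) %*% t(F)
    }

    stats_fwd <- matrix(NA_real_, n_sweeps,
                        length(geweke_stats(draw_prior(),
                                            draw_data(draw_prior()), gxe)))
    for (s in seq_len(n_sweeps)) {
      st <- draw_prior()
      stats_fwd[s, ] <- geweke_stats(st, draw_data(st), gxe)
    }

    st <- draw_prior()
    Y <- draw_data(st)
    stats_gibbs <- matrix(NA_real_, n_sweeps, ncol(stats_fwd))
    for (s in seq_len(n_sweeps)) {
      st <- one_sweep(Y, st, prep, priors)
      Y <- draw_data(st)
      stats_gibbs[s, ] <- geweke_stats(st, Y, gxe)
    }

    nm <- names(geweke_stats(st, Y, gxe))
    se_fwd <- apply(stats_fwd, 2, stats::sd) / sqrt(n_sweeps)
    se_gibbs <- apply(stats_gibbs, 2, batch_means_se)
    z <- (colMeans(stats_fwd) - colMeans(stats_gibbs)) /
      sqrt(se_fwd^2 + se_gibbs^2)
    data.frame(stat = nm, mean_forward = colMeans(stats_fwd),
               mean_gibbs = colMeans(stats_gibbs),
               se = sqrt(se_fwd^2 + se_gibbs^2), z = z,
               row.names = NULL)
  })
}

## Test statistics monitored by the joint-distribution check (L = 2,
## I = 2 designs give >= 20 statistics).
geweke_stats <- function(state, Y, gxe) {
  out <- c(
    Sigma_t = lower_tri(state$Sigma_t),
    Re = lower_tri(state$Re),
    beta_mean = mean(state$beta),
    beta_sq = mean(state$beta^2),
    b1_mean = mean(state$b1),
    b1_sq = mean(state$b1^2),
    b1_cross = mean(state$b1[, 1] * state$b1[, ncol(state$b1)]),
    Y_mean = mean(Y),
    Y_sq = mean(Y^2),
    Y_cross = mean(Y[, 1] * Y[, ncol(Y)]),
    tr_SigmaT_Re = sum(diag(state$Sigma_t %*% state$Re))
  )
  if (gxe)
    out <- c(out,
             Sigma_E = lower_tri(state$Sigma_E),
             b2_mean = mean(state$b2),
             b2_sq = mean(state$b2^2))
  out
}

## Standard error of a correlated chain via non-overlapping batch means.
batch_means_se <- function(x, n_batches = 50) {
  n <- length(x)
  b <- max(2L, n %/% n_batches)
  nb <- n %/% b
  bm <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
  stats::sd(bm) / sqrt(nb)
}

## All-cells-observed dataset shell used by validation tools: trait
## values are placeholders that callers overwrite per sweep.
skeleton_dataset <- function(J, I, L, G) {
  pheno <- data.frame(
    Line = rep(rownames(G), times = I),
    Env = rep(paste0("Env", seq_len(I)), each = J))
  for (l in seq_len(L)) pheno[[paste0("T", l)]] <- 0
  mtme_data(pheno, G)
}
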