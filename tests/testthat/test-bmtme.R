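## Conditional-correctness oracles and sampler behaviour. The
## joint-distribution (Geweke) certification of all blocks together runs
## in test-acceptance.R.

make_state <- function(sim, prep) {
  within(list(), {
    beta <- sim$truth$beta
    b1 <- sim$truth$b1
    b2 <- if (is.null(sim$truth$b2)) matrix(0, prep$I * prep$J, prep$L)
          else sim$truth$b2
    Sigma_t <- sim$truth$Sigma_t
    Sigma_E <- if (is.null(sim$truth$Sigma_E)) diag(prep$I)
               else sim$truth$Sigma_E
    Re <- sim$truth$Re
  })
}

test_that("eigen fast path and dense sampler share the same conditional", {
  sim <- tiny_dataset(J = 8, I = 2, p = 50, seed = 2)
  prep <- mtmegp:::gibbs_prep(sim$data, include_gxe = TRUE)
  st <- make_state(sim, prep)
  Y <- sim$data$Y

  ## b1: dense canonical mean vs simultaneous-diagonalisation mean
  can <- mtmegp:::b1_canonical(Y, st, prep)
  mu_dense <- matrix(solve(can$P, can$rhs), prep$J, prep$L)
  Rt <- crossprod(prep$U, can$T1) %*% can$Rei
  mu_eigen <- prep$U %*% with_mean_only(Rt, can$Sti, can$Rei,
                                        1 / prep$d, prep$k1[1])
  expect_lt(max(abs(mu_dense - mu_eigen)), 1e-8)

  ## b2 likewise, with the per-iteration Sigma_E rotation
  can2 <- mtmegp:::b2_canonical(Y, st, prep)
  mu2_dense <- matrix(solve(can2$P, can2$rhs), prep$I * prep$J, prep$L)
  ee <- eigen(st$Sigma_E, symmetric = TRUE)
  Rt2 <- mtmegp:::apply_kron_rotation(can2$T2 %*% can2$Rei, t(prep$U),
                                      t(ee$vectors), prep$J, prep$I)
  lam <- as.vector(outer(prep$d, ee$values))
  mu2_eigen <- mtmegp:::apply_kron_rotation(
    with_mean_only(Rt2, can2$Sti, can2$Rei, 1 / lam, 1),
    prep$U, ee$vectors, prep$J, prep$I)
  expect_lt(max(abs(mu2_dense - mu2_eigen)), 1e-8)
})

test_that("flat-prior beta conditional collapses to least squares", {
  sim <- tiny_dataset(J = 10, I = 3, seed = 4)
  prep <- mtmegp:::gibbs_prep(sim$data, include_gxe = FALSE)
  priors <- mtmegp:::resolve_priors(NULL, prep$L, prep$I)
  st <- make_state(sim, prep)
  st$b1 <- st$b1 * 0
  st$Re <- diag(prep$L) * 1e-10       # noise-free limit
  Y <- sim$data$Y
  set.seed(1)
  drawn <- mtmegp:::gibbs_step_beta(Y, st, prep, priors)$beta
  ols <- solve(prep$XtX, crossprod(prep$X, Y))
  expect_equal(unname(drawn), unname(ols), tolerance = 1e-4)
})

test_that("Re conditional matches the inverse-Wishart mean oracle", {
  ## 4 observations x 2 traits with known residuals: empirical mean of
  ## repeated draws must equal (S0 + E'E) / (nu0 + n - L - 1)
  pheno <- data.frame(Line = c("A", "B", "C", "D"), Env = "E1",
                      T1 = c(0.3, -1, 2, 0.5), T2 = c(1, 0, -0.5, 0.2))
  G <- toy_grm(c("A", "B", "C", "D"))
  ds <- mtme_data(pheno, G)
  prep <- mtmegp:::gibbs_prep(ds, include_gxe = FALSE)
  priors <- mtmegp:::resolve_priors(NULL, 2, 1)
  st <- list(beta = matrix(0, 1, 2), b1 = matrix(0, 4, 2),
             b2 = matrix(0, 4, 2), Sigma_t = diag(2),
             Sigma_E = diag(1), Re = diag(2))
  E <- ds$Y                                   # residuals = Y here
  expected <- (priors$S_e + crossprod(E)) / (priors$nu_e + 4 - 2 - 1)
  set.seed(3)
  draws <- replicate(4000,
                     mtmegp:::gibbs_step_Re(ds$Y, st, prep, priors)$Re)
  expect_equal(apply(draws, 1:2, mean), expected, tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("covariance conditionals recover the prior without data", {
  ## with b1 = b2 = 0 forced, the Sigma_t conditional is IW(nu_t + J, S_t)
  sim <- tiny_dataset(J = 5, I = 2, seed = 6)
  prep <- mtmegp:::gibbs_prep(sim$data, include_gxe = FALSE)
  priors <- mtmegp:::resolve_priors(bmtme_priors(nu_t = 10), 2, 2)
  st <- make_state(sim, prep)
  st$b1 <- st$b1 * 0
  set.seed(5)
  draws <- replicate(4000,
                     mtmegp:::gibbs_step_sigma_t(st, prep, priors)$Sigma_t)
  expect_equal(apply(draws, 1:2, mean),
               priors$S_t / (priors$nu_t + prep$J - 2 - 1),
               tolerance = 0.05)
})

test_that("b1 conditional draws match a Metropolis chain on one site", {
  ## 3 lines, 2 environments, 2 traits; everything else held fixed
  sim <- tiny_dataset(J = 3, I = 2, p = 30, seed = 12)
  prep <- mtmegp:::gibbs_prep(sim$data, include_gxe = FALSE)
  st <- make_state(sim, prep)
  Y <- sim$data$Y
  n_draw <- 50000

  set.seed(21)
  gibbs_draws <- t(replicate(n_draw,
    as.vector(mtmegp:::gibbs_step_b1(Y, st, prep)$b1)))

  ## independent Metropolis targeting the same conditional density:
  ## log p(b1 | .) = log MN(b1; 0, Gg, Sigma_t)
  ##              + log MN(Y - X beta; Z1 b1, I, Re)
  log_target <- function(b1v) {
    b1 <- matrix(b1v, prep$J, prep$L)
    resid <- Y - st$beta[prep$env_idx, , drop = FALSE]
    dmatnorm(b1, b1 * 0, prep$G, st$Sigma_t) +
      dmatnorm(resid, b1[prep$line_idx, , drop = FALSE],
               diag(prep$n_obs), st$Re)
  }
  set.seed(22)
  cur <- rep(0, prep$J * prep$L); cur_lp <- log_target(cur)
  mh <- matrix(NA_real_, n_draw, length(cur))
  for (s in seq_len(n_draw)) {
    prop <- cur + rnorm(length(cur), sd = 0.35)
    lp <- log_target(prop)
    if (log(runif(1)) < lp - cur_lp) { cur <- prop; cur_lp <- lp }
    mh[s, ] <- cur
  }
  mh <- mh[-(1:2000), ]

  ## same conditional: every coordinate passes a two-sample KS test at a
  ## conservative level (Metropolis draws are thinned for independence)
  for (k in seq_len(ncol(mh))) {
    ks <- suppressWarnings(
      ks.test(gibbs_draws[seq(1, n_draw, by = 10), k],
              mh[seq(1, nrow(mh), by = 50), k]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("the sampler is deterministic and keeps covariances PD", {
  sim <- tiny_dataset(J = 10, I = 2, seed = 31)
  f1 <- bmtme(sim$data, gxe = TRUE, n_iter = 200, burn_in = 100,
              thin = 1, seed = 77)
  f2 <- bmtme(sim$data, gxe = TRUE, n_iter = 200, burn_in = 100,
              thin = 1, seed = 77)
  expect_identical(f1$chains, f2$chains)
  expect_equal(f1$settings$n_keep, 100)

  ## PD preservation of every retained covariance draw
  for (nm in c("Sigma_t", "Re", "Sigma_E")) {
    tri <- f1$chains[[nm]]
    d <- if (nm == "Sigma_E") 2 else 2
    for (r in seq_len(nrow(tri))) {
      S <- matrix(0, d, d)
      S[lower.tri(S, diag = TRUE)] <- tri[r, ]
      S <- S + t(S) - diag(diag(S))
      expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
                0)
    }
  }
})

test_that("fixed-effect-only data is recovered and prediction is
           cell-order equivariant", {
  beta <- matrix(c(3, 7, -2, 4), 2, 2)
  sim <- simulate_dataset(J = 12, I = 2, L = 2, p = 60, beta = beta,
                          Sigma_t = diag(2) * 1e-10,
                          Re = diag(2) * 1e-10, gxe = FALSE, seed = 44)
  fit <- bmtme(sim$data, gxe = FALSE, n_iter = 400, burn_in = 200,
               thin = 1, seed = 5)
  pred <- predict(fit)
  for (i in 1:2) {
    rows <- sim$data$cells$Env == paste0("Env", i)
    expect_equal(unname(colMeans(pred[rows, ])), beta[i, ],
                 tolerance = 0.05)
  }

  ## permutation equivariance of target cells
  cells <- data.frame(Line = sim$data$cells$Line[c(3, 1, 20)],
                      Env = sim$data$cells$Env[c(3, 1, 20)])
  p1 <- predict(fit, cells)
  p2 <- predict(fit, cells[c(2, 3, 1), ])
  expect_equal(p1[c(2, 3, 1), ], p2, ignore_attr = TRUE)

  expect_error(predict(fit, data.frame(Line = "nope", Env = "Env1")),
               "unknown line")
})

test_that("held-out cells are predicted better than environment means", {
  sim <- simulate_dataset(J = 40, I = 3, L = 2, p = 150, gxe = FALSE,
                          Re = 0.3 * diag(2) + 0.05, seed = 55)
  parts <- cv2_partition(sim$data, seed = 9, n_partitions = 1)
  masked <- mask_cells(sim$data, parts[[1]])
  fit <- bmtme(masked, gxe = FALSE, n_iter = 1500, burn_in = 700,
               seed = 3, keep_effects = FALSE)
  test_rows <- mtmegp:::cell_rows(sim$data, parts[[1]]$test_cells)
  pred <- predict(fit, parts[[1]]$test_cells)

  ## within each stratum the predictions track the true genetic values,
  ## which an environment-mean predictor (constant per stratum) cannot
  gen <- sim$truth$genetic[test_rows, ]
  colnames(gen) <- sim$data$trait_ids
  tab <- pearson_by_trait_env(pred, gen, parts[[1]]$test_cells)
  expect_gt(mean(tab$r, na.rm = TRUE), 0.3)

  ## pooled over cells, genomic information beats environment means at
  ## predicting the held-out phenotypes
  env_mean <- fit$post_mean$beta[match(parts[[1]]$test_cells$Env,
                                       fit$env_ids), ]
  truth <- sim$data$Y[test_rows, ]
  r_fit <- cor(as.vector(pred), as.vector(truth))
  r_env <- cor(as.vector(env_mean), as.vector(truth))
  expect_gt(r_fit, r_env)
})

test_that("omitting a real G x E term inflates the residual covariance", {
  sim <- simulate_dataset(J = 30, I = 3, L = 2, p = 120, gxe = TRUE,
                          Re = 0.4 * diag(2) + 0.1, seed = 66)
  f_with <- bmtme(sim$data, gxe = TRUE, n_iter = 1200, burn_in = 600,
                  seed = 8, keep_effects = FALSE)
  f_without <- bmtme(sim$data, gxe = FALSE, n_iter = 1200, burn_in = 600,
                     seed = 8, keep_effects = FALSE)
  ## total residual variance absorbs the unmodelled interaction
  tr_with <- sum(colMeans(f_with$chains$Re)[c(1, 3)])
  tr_without <- sum(colMeans(f_without$chains$Re)[c(1, 3)])
  expect_gt(tr_without, tr_with)
})

test_that("fitting requires observed cells in every environment", {
  ds <- mtme_data(toy_pheno(), toy_grm())
  ds$Y[4:6, ] <- NA                        # all of E2 missing
  expect_error(bmtme(ds, n_iter = 10, burn_in = 5),
               "every environment")
})
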