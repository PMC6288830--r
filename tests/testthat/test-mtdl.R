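test_that("hyperparameter grids enumerate the full factorial design", {
  g <- mtdl_grid()
  expect_equal(nrow(g), 108)                 # 6 units x 6 epochs x 3 layers
  expect_setequal(unique(g$units), seq(50, 100, 10))
  g2 <- mtdl_grid(units = c(8, 16, 32), epochs = 10, layers = 1:2)
  expect_equal(nrow(g2), 3 * 1 * 2)
  expect_error(mtdl_grid(units = integer(0)))
})

test_that("feature encoding reproduces the GRM and counts columns", {
  sim <- tiny_dataset(J = 5, I = 2)
  F0 <- encode_features(sim$data, gxe = FALSE)
  F1 <- encode_features(sim$data, gxe = TRUE)
  J <- 5; I <- 2
  expect_equal(ncol(F0), I + J)
  expect_equal(ncol(F1), I + J + I * J)      # interaction block appended

  ## genomic block times its transpose reconstructs the GRM
  bl <- attr(F0, "blocks")
  Lg <- F0[seq_len(J), bl$genomic]
  expect_lt(max(abs(tcrossprod(Lg) - sim$data$grm)), 1e-10)

  ## identity GRM: one-hot environment and (scaled) one-hot genomic parts
  pheno <- data.frame(Line = rep(c("A", "B"), 2),
                      Env = rep(c("E1", "E2"), each = 2), T1 = 1:4)
  G <- diag(2); dimnames(G) <- list(c("A", "B"), c("A", "B"))
  Fi <- encode_features(mtme_data(pheno, G))
  expect_equal(ncol(Fi), 4)
  expect_true(all(rowSums(Fi[, 1:2]) == 1))
  expect_equal(unname(Fi[, 3:4] != 0), unname(rbind(diag(2), diag(2)) == 1))

  ## interaction block = environment indicator times genomic columns
  bl1 <- attr(F1, "blocks")
  env1_rows <- sim$data$cells$Env == "Env1"
  expect_equal(F1[env1_rows, bl1$interaction[seq_len(J)]],
               F1[env1_rows, bl1$genomic], ignore_attr = TRUE)
  expect_true(all(F1[!env1_rows, bl1$interaction[seq_len(J)]] == 0))
})

test_that("the network fits a noiseless linear map almost exactly", {
  set.seed(1)
  n <- 120; q <- 10
  X <- matrix(rnorm(n * q), n, q)
  Y <- X %*% matrix(rnorm(q * 2), q, 2)
  colnames(Y) <- c("a", "b")
  cfg <- mtdl_config(units = 64, epochs = 300, n_layers = 1,
                     dropout_rate = 0)
  fit <- train_mtdl(X, Y, cfg, seed = 4)
  pred <- predict(fit, X)
  r2 <- 1 - sum((pred - Y)^2) / sum(scale(Y, scale = FALSE)^2)
  expect_gt(r2, 0.99)
  ## training loss keeps decreasing over the last half of the run
  late <- fit$loss_history[151:300]
  expect_lt(mean(tail(late, 30)), mean(head(late, 30)))
  expect_lt(tail(late, 1), 0.05)
})

test_that("dropout raises training loss; training is seed-deterministic", {
  set.seed(2)
  X <- matrix(rnorm(80 * 6), 80, 6)
  Y <- cbind(X %*% rnorm(6), X %*% rnorm(6))
  base <- mtdl_config(units = 32, epochs = 80, n_layers = 1,
                      dropout_rate = 0)
  drop <- mtdl_config(units = 32, epochs = 80, n_layers = 1,
                      dropout_rate = 0.3)
  f0 <- train_mtdl(X, Y, base, seed = 9)
  f3 <- train_mtdl(X, Y, drop, seed = 9)
  expect_gte(tail(f3$loss_history, 1), tail(f0$loss_history, 1))

  f0b <- train_mtdl(X, Y, base, seed = 9)
  expect_identical(f0$par, f0b$par)
  ## inference forward pass is deterministic (dropout off)
  expect_identical(predict(f3, X), predict(f3, X))
})

test_that("predictions are back-transformed and row-equivariant", {
  set.seed(3)
  X <- matrix(rnorm(60 * 5), 60, 5)
  Y <- cbind(T1 = 100 + 10 * (X %*% rnorm(5))[, 1],
             T2 = -50 + 5 * rnorm(60))
  cfg <- mtdl_config(units = 16, epochs = 50, n_layers = 1,
                     dropout_rate = 0)
  fit <- train_mtdl(X, Y, cfg, seed = 7)

  ## zero-weight network predicts the training trait means
  fit0 <- fit
  fit0$par$W <- lapply(fit0$par$W, function(w) w * 0)
  fit0$par$b <- lapply(fit0$par$b, function(b) b * 0)
  p0 <- predict(fit0, X)
  expect_equal(unname(colMeans(Y))[1], unname(p0[1, 1]))
  expect_equal(unname(p0[5, ]), unname(colMeans(Y)))

  ## permuting rows permutes predictions identically
  perm <- sample(nrow(X))
  expect_equal(predict(fit, X[perm, ]), predict(fit, X)[perm, ])

  expect_error(predict(fit, X[, 1:3]), "dimension")
})

test_that("inner validation split selects by loss with ordered ties", {
  set.seed(4)
  X <- matrix(rnorm(100 * 6), 100, 6)
  Y <- cbind(X %*% rnorm(6), X %*% rnorm(6)) + matrix(rnorm(200, sd = 0.1),
                                                      100, 2)
  ## single-configuration grid returns that configuration
  g1 <- mtdl_grid(units = 12, epochs = 40, layers = 2)
  sel1 <- inner_cv_select(X, Y, g1, seed = 5)
  expect_equal(sel1$config$units, 12L)
  expect_equal(sel1$config$n_layers, 2L)

  ## argmin property: winner's validation loss is the minimum
  g <- mtdl_grid(units = c(8, 24), epochs = c(30, 60), layers = 1:2)
  sel <- inner_cv_select(X, Y, g, seed = 5, dropout_rate = 0)
  expect_equal(nrow(sel$scores), 8)
  win <- sel$scores[sel$scores$units == sel$config$units &
                      sel$scores$epochs == sel$config$epochs &
                      sel$scores$n_layers == sel$config$n_layers, ]
  expect_equal(win$val_loss, min(sel$scores$val_loss))
  expect_lte(sel$config$n_layers, 3)

  expect_error(inner_cv_select(X[1:2, ], Y[1:2, ], g1,
                               validation_fraction = 0.9))
})

test_that("genomic signal is learned better than a permuted-genotype null", {
  sim <- simulate_dataset(J = 30, I = 2, L = 2, p = 120, gxe = FALSE,
                          Re = 0.2 * diag(2) + 0.05, seed = 91)
  F <- encode_features(sim$data, gxe = FALSE)
  parts <- cv2_partition(sim$data, seed = 2, n_partitions = 1)
  tr <- mtmegp:::cell_rows(sim$data,  parts[[1]]$train_cells)
  te <- mtmegp:::cell_rows(sim$data, parts[[1]]$test_cells)
  cfg <- mtdl_config(units = 32, epochs = 80, n_layers = 1)
  fit <- train_mtdl(F[tr, ], sim$data$Y[tr, ], cfg, seed = 6)
  r_true <- cor(as.vector(predict(fit, F[te, ])),
                as.vector(sim$data$Y[te, ]))

  ## permute the genomic rows: breaks the line-feature correspondence
  set.seed(7)
  bl <- attr(F, "blocks")$genomic
  Fp <- F
  line_perm <- sample(length(sim$data$line_ids))
  li <- match(sim$data$cells$Line, sim$data$line_ids)
  Lg <- F[seq_along(sim$data$line_ids) , bl]
  Fp[, bl] <- Lg[line_perm[li], ]
  fitp <- train_mtdl(Fp[tr, ], sim$data$Y[tr, ], cfg, seed = 6)
  r_null <- cor(as.vector(predict(fitp, Fp[te, ])),
                as.vector(sim$data$Y[te, ]))
  expect_gt(r_true, r_null)
})
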