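## Multi-trait densely connected network (MTDL).
##
## A feedforward network with `n_layers` ReLU hidden layers of `units`
## units each, inverted-dropout regularisation after every hidden layer
## during training, and a single linear head with L output units (one per
## trait). Trained by mini-batch Adam on the mean squared error of the
## standardised responses. The network is small enough that the forward
## and backward passes are plain matrix algebra; no external deep-learning
## backend is involved.

#' MTDL hyperparameter configuration
#'
#' @param units Hidden-layer width (the same for every hidden layer).
#' @param epochs Number of full passes over the training data.
#' @param n_layers Number of hidden layers.
#' @param dropout_rate Fraction of hidden units zeroed during training
#'   (default 0.3; inference always runs with dropout disabled).
#' @param validation_fraction Fraction of training rows held out by the
#'   inner model-selection split.
#' @param learning_rate,batch_size Adam step size and mini-batch size;
#'   \code{batch_size = NULL} uses \code{min(32, n)}.
#' @return An object of class \code{mtdl_config}.
#' @export
mtdl_config <- function(units, epochs, n_layers, dropout_rate = 0.3,
                        validation_fraction = 0.2, learning_rate = 0.001,
                        batch_size = NULL) {
  stopifnot(units >= 1, epochs >= 1, n_layers >= 1,
            dropout_rate >= 0, dropout_rate < 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(units = as.integer(units), epochs = as.integer(epochs),
                 n_layers = as.integer(n_layers),
                 dropout_rate = dropout_rate,
                 validation_fraction = validation_fraction,
                 learning_rate = learning_rate, batch_size = batch_size),
            class = "mtdl_config")
}

#' Hyperparameter grid for MTDL model selection
#'
#' The default grid is the full factorial design over units and epochs in
#' \{50, 60, 70, 80, 90, 100\} and 1--3 hidden layers, i.e. 6 x 6 x 3 =
#' 108 configurations.
#'
#' @param units,epochs,layers Vectors of candidate values.
#' @return A data.frame of class \code{mtdl_grid}, one row per
#'   configuration.
#' @export
mtdl_grid <- function(units = seq(50, 100, by = 10),
                      epochs = seq(50, 100, by = 10),
                      layers = 1:3) {
  stopifnot(length(units) > 0, length(epochs) > 0, length(layers) > 0,
            all(units >= 1), all(epochs >= 1), all(layers >= 1))
  g <- expand.grid(units = as.integer(units), epochs = as.integer(epochs),
                   n_layers = as.integer(layers),
                   KEEP.OUT.ATTRS = FALSE)
  class(g) <- c("mtdl_grid", "data.frame")
  g
}

#' Encode network input features for a dataset
#'
#' Builds the n x q feature matrix: I one-hot environment columns, J
#' genomic columns (row j of a square-root factor Lg of the GRM, with
#' Lg Lg' = Gg, so a linear network on this block is equivalent to
#' GBLUP), and -- when \code{gxe = TRUE} -- all I x J elementwise products
#' of environment indicators with genomic columns.
#'
#' @param ds An \code{\link{mtme_data}} object.
#' @param gxe Append the genotype-by-environment interaction block.
#' @param root Square-root factor of the GRM: symmetric eigen-root
#'   (default) or Cholesky.
#' @return A numeric matrix whose rows follow the dataset cell ordering,
#'   with a \code{"blocks"} attribute giving the column indices of the
#'   environment, genomic and interaction blocks.
#' @export
encode_features <- function(ds, gxe = FALSE,
                            root = c("eigen", "chol")) {
  stopifnot(inherits(ds, "mtme_data"))
  root <- match.arg(root)
  J <- length(ds$line_ids); I <- length(ds$env_ids); n <- n_cells(ds)
  G <- ds$grm
  Lg <- if (root == "chol") {
    t(tryCatch(chol(G), error = function(e)
      stop("GRM is not positive definite; use root = 'eigen'",
           call. = FALSE)))
  } else {
    e <- eigen(G, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values), 1))
      stop("GRM is not positive semi-definite", call. = FALSE)
    e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
  }
  env_idx <- match(ds$cells$Env, ds$env_ids)
  line_idx <- match(ds$cells$Line, ds$line_ids)
  Xe <- matrix(0, n, I, dimnames = list(NULL, paste0("env:", ds$env_ids)))
  Xe[cbind(seq_len(n), env_idx)] <- 1
  Xg <- Lg[line_idx, , drop = FALSE]
  colnames(Xg) <- paste0("g:", seq_len(J))
  blocks <- list(env = seq_len(I), genomic = I + seq_len(J))
  F <- cbind(Xe, Xg)
  if (gxe) {
    Xi <- matrix(0, n, I * J)
    for (i in seq_len(I)) {
      r <- env_idx == i
      Xi[r, ((i - 1) * J + 1):(i * J)] <- Xg[r, , drop = FALSE]
    }
    colnames(Xi) <- paste0("gxe:", rep(ds$env_ids, each = J), ":",
                           seq_len(J))
    blocks$interaction <- I + J + seq_len(I * J)
    F <- cbind(F, Xi)
  }
  rownames(F) <- NULL
  attr(F, "blocks") <- blocks
  F
}

# ---- network internals --------------------------------------------------

mlp_init <- function(q, units, n_layers, L) {
  dims <- c(q, rep(units, n_layers), L)
  W <- vector("list", length(dims) - 1)
  b <- vector("list", length(dims) - 1)
  for (k in seq_along(W)) {
    W[[k]] <- matrix(stats::rnorm(dims[k] * dims[k + 1],
                                  sd = sqrt(2 / dims[k])),
                     dims[k], dims[k + 1])
    b[[k]] <- rep(0, dims[k + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X, dropout_rate = 0, training = FALSE) {
  K <- length(par$W)
  A <- X
  acts <- vector("list", K)                 # post-activation inputs
  masks <- vector("list", K - 1)
  for (k in seq_len(K - 1)) {
    acts[[k]] <- A
    Z <- A %*% par$W[[k]]
    Z <- sweep(Z, 2, par$b[[k]], "+")
    A <- pmax(Z, 0)
    if (training && dropout_rate > 0) {
      m <- matrix(stats::runif(length(A)) >= dropout_rate, nrow(A),
                  ncol(A))
      A <- A * m / (1 - dropout_rate)
      masks[[k]] <- m
    }
  }
  acts[[K]] <- A
  out <- sweep(A %*% par$W[[K]], 2, par$b[[K]], "+")
  list(out = out, acts = acts, masks = masks)
}

mlp_backward <- function(par, fwd, Y, dropout_rate) {
  K <- length(par$W)
  n <- nrow(Y)
  gW <- vector("list", K); gb <- vector("list", K)
  delta <- 2 * (fwd$out - Y) / (n * ncol(Y))
  for (k in K:1) {
    gW[[k]] <- crossprod(fwd$acts[[k]], delta)
    gb[[k]] <- colSums(delta)
    if (k > 1) {
      delta <- delta %*% t(par$W[[k]])
      if (dropout_rate > 0 && !is.null(fwd$masks[[k - 1]]))
        delta <- delta * fwd$masks[[k - 1]] / (1 - dropout_rate)
      delta <- delta * (fwd$acts[[k]] > 0)
    }
  }
  list(W = gW, b = gb)
}

adam_init <- function(par) {
  zero <- function(x) lapply(x, function(p) p * 0)
  list(mW = zero(par$W), vW = zero(par$W),
       mb = zero(par$b), vb = zero(par$b), t = 0)
}

adam_update <- function(par, grad, opt, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  opt$t <- opt$t + 1
  c1 <- 1 - beta1^opt$t; c2 <- 1 - beta2^opt$t
  for (k in seq_along(par$W)) {
    opt$mW[[k]] <- beta1 * opt$mW[[k]] + (1 - beta1) * grad$W[[k]]
    opt$vW[[k]] <- beta2 * opt$vW[[k]] + (1 - beta2) * grad$W[[k]]^2
    par$W[[k]] <- par$W[[k]] -
      lr * (opt$mW[[k]] / c1) / (sqrt(opt$vW[[k]] / c2) + eps)
    opt$mb[[k]] <- beta1 * opt$mb[[k]] + (1 - beta1) * grad$b[[k]]
    opt$vb[[k]] <- beta2 * opt$vb[[k]] + (1 - beta2) * grad$b[[k]]^2
    par$b[[k]] <- par$b[[k]] -
      lr * (opt$mb[[k]] / c1) / (sqrt(opt$vb[[k]] / c2) + eps)
  }
  list(par = par, opt = opt)
}

#' Train the multi-trait network
#'
#' Standardises the responses (per-trait mean/SD fitted on the supplied
#' training rows), then trains the network for exactly
#' \code{config$epochs} passes of shuffled mini-batch Adam on the mean
#' squared error averaged over the L standardised outputs. Dropout is
#' applied after each hidden layer during training only.
#'
#' @param features Numeric n x q feature matrix (see
#'   \code{\link{encode_features}}).
#' @param Y Numeric n x L response matrix with no missing values.
#' @param config An \code{\link{mtdl_config}}.
#' @param seed Integer seed controlling initialisation, batch shuffling
#'   and dropout masks.
#' @return An object of class \code{mtdl_model} containing the layer
#'   weights, the fitted trait scaler, the configuration and the
#'   per-epoch mean training loss.
#' @export
train_mtdl <- function(features, Y, config, seed = NULL) {
  stopifnot(inherits(config, "mtdl_config"))
  X <- as.matrix(features); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  if (anyNA(Y))
    stop("training responses must not contain missing values",
         call. = FALSE)
  scaler <- fit_scaler(Y)
  Ys <- scale_traits(Y, scaler)
  n <- nrow(X)
  bs <- if (is.null(config$batch_size)) min(32L, n)
        else min(config$batch_size, n)
  with_seed(seed, {
    par <- mlp_init(ncol(X), config$units, config$n_layers, ncol(Y))
    opt <- adam_init(par)
    loss_hist <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        fwd <- mlp_forward(par, X[idx, , drop = FALSE],
                           config$dropout_rate, training = TRUE)
        loss <- mean((fwd$out - Ys[idx, , drop = FALSE])^2)
        if (!is.finite(loss))
          stop(sprintf("non-finite training loss at epoch %d", ep),
               call. = FALSE)
        losses <- c(losses, loss)
        grad <- mlp_backward(par, fwd, Ys[idx, , drop = FALSE],
                             config$dropout_rate)
        upd <- adam_update(par, grad, opt, config$learning_rate)
        par <- upd$par; opt <- upd$opt
      }
      loss_hist[ep] <- mean(losses)
    }
    structure(list(par = par, config = config, scaler = scaler,
                   loss_history = loss_hist, q = ncol(X),
                   trait_ids = colnames(Y)),
              class = "mtdl_model")
  })
}

#' Predict trait values with a trained network
#'
#' Deterministic forward pass with dropout disabled; outputs are mapped
#' back to the original trait scales with the scaler fitted at training.
#'
#' @param object An \code{mtdl_model}.
#' @param features Feature matrix with the same columns as at training.
#' @param ... Unused.
#' @return A numeric matrix, one row per input row, one column per trait.
#' @export
predict.mtdl_model <- function(object, features, ...) {
  X <- as.matrix(features)
  if (ncol(X) != object$q)
    stop(sprintf("feature dimension %d does not match training (%d)",
                 ncol(X), object$q), call. = FALSE)
  out <- mlp_forward(object$par, X, training = FALSE)$out
  out <- unscale_traits(out, object$scaler)
  colnames(out) <- object$trait_ids
  out
}

#' Select MTDL hyperparameters by an inner validation split
#'
#' Splits the training rows once into an inner-training part and an
#' inner-validation part (default 80/20), trains every configuration of
#' the grid on the inner-training rows, and returns the configuration
#' with the smallest inner-validation mean squared error (computed on the
#' standardised scale). Ties are broken by fewest layers, then fewest
#' units, then fewest epochs.
#'
#' @param features,Y Training feature matrix and responses.
#' @param grid An \code{\link{mtdl_grid}}.
#' @param validation_fraction Fraction of rows held out for validation.
#' @param dropout_rate Dropout rate used for every candidate.
#' @param seed Integer seed (drives the split and each training run).
#' @return A list with \code{config} (the winning
#'   \code{\link{mtdl_config}}) and \code{scores} (per-configuration
#'   validation losses).
#' @export
inner_cv_select <- function(features, Y, grid = mtdl_grid(),
                            validation_fraction = 0.2, dropout_rate = 0.3,
                            seed = NULL) {
  stopifnot(inherits(grid, "mtdl_grid"), nrow(grid) >= 1,
            validation_fraction > 0, validation_fraction < 1)
  X <- as.matrix(features); Y <- as.matrix(Y)
  n <- nrow(X)
  n_val <- max(1L, as.integer(round_half_up(validation_fraction * n)))
  if (n_val >= n)
    stop("training set too small for an inner validation split",
         call. = FALSE)
  val_idx <- with_seed(derive_seed(seed, 1), sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)

  ord <- order(grid$n_layers, grid$units, grid$epochs)
  scores <- rep(NA_real_, nrow(grid))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    cfg <- mtdl_config(g$units, g$epochs, g$n_layers,
                       dropout_rate = dropout_rate,
                       validation_fraction = validation_fraction)
    fit <- train_mtdl(X[tr_idx, , drop = FALSE],
                      Y[tr_idx, , drop = FALSE], cfg,
                      seed = derive_seed(seed, 100 + k))
    pred <- predict(fit, X[val_idx, , drop = FALSE])
    resid <- scale_traits(pred, fit$scaler) -
      scale_traits(Y[val_idx, , drop = FALSE], fit$scaler)
    scores[k] <- mean(resid^2)
  }
  best <- ord[which.min(scores[ord])]
  g <- grid[best, ]
  list(config = mtdl_config(g$units, g$epochs, g$n_layers,
                            dropout_rate = dropout_rate,
                            validation_fraction = validation_fraction),
       scores = cbind(as.data.frame(grid), val_loss = scores))
}

#' Tune and fit the multi-trait network
#'
#' Runs the inner validation split over the grid, then refits the winning
#' configuration on all supplied training rows.
#'
#' @inheritParams inner_cv_select
#' @return The refitted \code{mtdl_model}, with the selection results
#'   attached as attributes \code{"selection"}.
#' @export
mtdl_fit <- function(features, Y, grid = mtdl_grid(),
                     validation_fraction = 0.2, dropout_rate = 0.3,
                     seed = NULL) {
  sel <- inner_cv_select(features, Y, grid, validation_fraction,
                         dropout_rate, seed)
  model <- train_mtdl(features, Y, sel$config,
                      seed = derive_seed(seed, 999))
  attr(model, "selection") <- sel
  model
}
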