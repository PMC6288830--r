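## Cell-level (CV2) cross-validation and accuracy metrics.
##
## The CV2 scheme predicts tested lines in some tested environments from
## their records in other environments: a partition removes whole
## line-by-environment cells (all traits at once) rather than whole lines.

#' Random CV2 partitions of a dataset
#'
#' For each partition, \code{m = round(p_testing * N)} lines are drawn
#' (N = number of observed cells) -- with replacement if the number of
#' lines J is smaller than m, without replacement otherwise -- and one
#' environment is picked uniformly at random for each drawn line. The
#' distinct cells so selected form the test set; every other observed
#' cell is training. Partitions are drawn independently, so a cell can
#' appear in the test sets of several partitions, but never in both the
#' training and test set of the same partition.
#'
#' @param ds An \code{\link{mtme_data}} object.
#' @param p_testing Fraction of cells assigned to testing (default 0.2).
#' @param n_partitions Number of independent random partitions.
#' @param seed Integer seed.
#' @return A list of \code{cv_partition} objects, each with
#'   \code{partition_index}, \code{test_cells}, \code{train_cells} and
#'   the seed it was drawn under.
#' @export
cv2_partition <- function(ds, p_testing = 0.2, n_partitions = 10,
                          seed = NULL) {
  stopifnot(inherits(ds, "mtme_data"), p_testing > 0, p_testing < 1,
            n_partitions >= 1)
  obs <- ds$cells[observed_rows(ds), , drop = FALSE]
  N <- nrow(obs)
  if (N < 2) stop("need at least two observed cells", call. = FALSE)
  J <- length(ds$line_ids)
  m <- max(1L, as.integer(round_half_up(p_testing * N)))
  replace <- J < m
  obs_key <- paste(obs$Env, obs$Line, sep = "\r")

  with_seed(seed, lapply(seq_len(n_partitions), function(k) {
    lines <- sample(ds$line_ids, m, replace = replace)
    envs <- sample(ds$env_ids, m, replace = TRUE)
    key <- paste(envs, lines, sep = "\r")
    sel <- !duplicated(key) & key %in% obs_key
    test <- data.frame(Line = lines[sel], Env = envs[sel],
                       stringsAsFactors = FALSE)
    in_test <- obs_key %in% key[sel]
    train <- obs[!in_test, , drop = FALSE]
    rownames(train) <- NULL
    lost <- setdiff(ds$env_ids, train$Env)
    if (length(lost))
      warning("partition ", k, " removes every observed cell of ",
              "environment(s): ", paste(lost, collapse = ", "),
              call. = FALSE)
    structure(list(partition_index = k, test_cells = test,
                   train_cells = train, seed = seed),
              class = "cv_partition")
  }))
}

#' Pearson accuracy per trait-environment stratum
#'
#' Computes the Pearson correlation between predictions and observed
#' values separately for every (trait, environment) combination among the
#' supplied cells. Strata with fewer than two cells, or with zero
#' variance in either vector, are reported as missing (with a warning),
#' never as zero.
#'
#' @param predictions,truth Numeric matrices (cells x traits) with
#'   matching trait columns.
#' @param cells A data.frame with \code{Line} and \code{Env} for each
#'   row of the matrices.
#' @return A data.frame with columns \code{Trait}, \code{Env}, \code{r}
#'   and \code{n} (cells in the stratum).
#' @export
pearson_by_trait_env <- function(predictions, truth, cells) {
  predictions <- as.matrix(predictions); truth <- as.matrix(truth)
  stopifnot(nrow(predictions) == nrow(truth),
            nrow(predictions) == nrow(cells),
            ncol(predictions) == ncol(truth))
  traits <- colnames(truth)
  if (is.null(traits)) traits <- paste0("T", seq_len(ncol(truth)))
  envs <- unique(as.character(cells$Env))
  out <- expand.grid(Trait = traits, Env = envs, stringsAsFactors = FALSE)
  out$r <- NA_real_; out$n <- 0L
  for (k in seq_len(nrow(out))) {
    rows <- which(cells$Env == out$Env[k])
    l <- match(out$Trait[k], traits)
    x <- truth[rows, l]; y <- predictions[rows, l]
    ok <- is.finite(x) & is.finite(y)
    out$n[k] <- sum(ok)
    if (sum(ok) < 2) {
      warning(sprintf("stratum (%s, %s) has fewer than 2 cells",
                      out$Trait[k], out$Env[k]), call. = FALSE)
    } else if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning(sprintf("zero variance in stratum (%s, %s)",
                      out$Trait[k], out$Env[k]), call. = FALSE)
    } else {
      out$r[k] <- stats::cor(x[ok], y[ok])
    }
  }
  out
}

#' Divide Pearson accuracies by the square root of heritability
#'
#' Traits in different environments have different heritabilities; the
#' adjusted accuracy \code{r / sqrt(h2)} puts strata on a comparable
#' scale. Adjusted values may exceed 1 when h2 is small. Strata without a
#' supplied heritability keep their raw value and are flagged.
#'
#' @param table A data.frame with \code{Trait}, \code{Env} and \code{r}
#'   columns (e.g. from \code{\link{pearson_by_trait_env}}).
#' @param h2 A data.frame with \code{Trait}, \code{Env}, \code{h2}
#'   (each h2 in (0, 1]).
#' @return The table with columns \code{r_adj} and \code{adjusted}
#'   appended.
#' @export
adjust_by_heritability <- function(table, h2) {
  stopifnot(all(c("Trait", "Env", "r") %in% names(table)),
            all(c("Trait", "Env", "h2") %in% names(h2)))
  if (any(h2$h2 <= 0 | h2$h2 > 1))
    stop("heritabilities must lie in (0, 1]", call. = FALSE)
  idx <- match(paste(table$Trait, table$Env),
               paste(h2$Trait, h2$Env))
  table$r_adj <- table$r / sqrt(h2$h2[idx])
  table$adjusted <- !is.na(idx)
  table$r_adj[!table$adjusted] <- table$r[!table$adjusted]
  table
}

#' Summarise per-partition accuracies
#'
#' Averages the per-partition Pearson correlations within each stratum
#' (and grouping column, e.g. the engine variant) and reports the
#' standard error of the mean across partitions.
#'
#' @param scores A data.frame with columns \code{Trait}, \code{Env},
#'   \code{r} and optionally grouping columns named in \code{by}.
#' @param by Extra grouping column names.
#' @return A data.frame with mean accuracy, SE and partition count per
#'   group.
#' @export
summarize_accuracy <- function(scores, by = intersect("variant",
                                                      names(scores))) {
  keys <- c(by, "Trait", "Env")
  groups <- unique(scores[keys])
  rownames(groups) <- NULL
  groups$mean_r <- NA_real_; groups$se <- NA_real_
  groups$n_partitions <- 0L
  for (k in seq_len(nrow(groups))) {
    sel <- rep(TRUE, nrow(scores))
    for (col in keys) sel <- sel & scores[[col]] == groups[[col]][k]
    r <- scores$r[sel]
    r <- r[is.finite(r)]
    groups$n_partitions[k] <- length(r)
    if (length(r)) {
      groups$mean_r[k] <- mean(r)
      groups$se[k] <- if (length(r) > 1)
        stats::sd(r) / sqrt(length(r)) else 0
    }
  }
  groups
}

#' Compare the Bayesian and deep-learning engines under CV2
#'
#' For every random partition and every requested engine variant, fits
#' the model on the training cells (responses standardised per training
#' set and back-transformed afterwards), predicts the held-out cells,
#' and scores Pearson accuracy per trait-environment stratum. Engine
#' failures are recorded per partition rather than aborting the run.
#'
#' @param ds An \code{\link{mtme_data}} with fully observed cells.
#' @param engines Character subset of \code{c("bmtme", "mtdl")}.
#' @param gxe Logical vector: fit with and/or without the
#'   genotype-by-environment term.
#' @param p_testing,n_partitions CV2 settings.
#' @param bmtme_control List of chain settings for the Bayesian engine
#'   (\code{n_iter}, \code{burn_in}, \code{thin}, \code{priors}).
#' @param grid,dropout_rate MTDL hyperparameter grid and dropout rate.
#' @param h2 Optional per-stratum heritabilities for adjusted accuracy
#'   (data.frame with \code{Trait}, \code{Env}, \code{h2}).
#' @param seed Master seed; every partition and fit derives from it.
#' @param verbose Report progress.
#' @return A list with \code{scores} (per partition x variant x
#'   stratum), \code{summary} (per variant x stratum mean and SE),
#'   \code{overall} (cross-stratum mean per variant) and \code{errors}.
#' @export
run_comparison <- function(ds, engines = c("bmtme", "mtdl"),
                           gxe = c(TRUE, FALSE), p_testing = 0.2,
                           n_partitions = 10,
                           bmtme_control = list(), grid = mtdl_grid(),
                           dropout_rate = 0.3, h2 = NULL, seed = NULL,
                           verbose = FALSE) {
  engines <- match.arg(engines, several.ok = TRUE)
  ctl <- utils::modifyList(list(n_iter = 2000, burn_in = 1000, thin = 2,
                                priors = NULL), bmtme_control)
  parts <- cv2_partition(ds, p_testing, n_partitions,
                         seed = derive_seed(seed, 1))
  feats <- list()
  if ("mtdl" %in% engines)
    for (g in unique(gxe))
      feats[[as.character(g)]] <- encode_features(ds, gxe = g)

  variants <- expand.grid(engine = engines, gxe = unique(gxe),
                          stringsAsFactors = FALSE)
  variants$label <- paste0(variants$engine,
                           ifelse(variants$gxe, "_gxe", "_main"))
  scores <- list(); errors <- list()
  for (k in seq_len(n_partitions)) {
    part <- parts[[k]]
    train_ds <- mask_cells(ds, part)
    test_rows <- cell_rows(ds, part$test_cells)
    truth <- ds$Y[test_rows, , drop = FALSE]
    tr_rows <- observed_rows(train_ds)
    scaler <- fit_scaler(train_ds$Y[tr_rows, , drop = FALSE])

    for (v in seq_len(nrow(variants))) {
      lab <- variants$label[v]
      vseed <- derive_seed(seed, 1000 * v + k)
      if (verbose)
        message(sprintf("partition %d / %d: %s", k, n_partitions, lab))
      res <- tryCatch({
        if (variants$engine[v] == "bmtme") {
          sds <- train_ds
          sds$Y <- scale_traits(sds$Y, scaler)
          fit <- bmtme(sds, gxe = variants$gxe[v], n_iter = ctl$n_iter,
                       burn_in = ctl$burn_in, thin = ctl$thin,
                       priors = ctl$priors, seed = vseed,
                       keep_effects = FALSE)
          unscale_traits(predict(fit, part$test_cells), scaler)
        } else {
          F <- feats[[as.character(variants$gxe[v])]]
          model <- mtdl_fit(F[tr_rows, , drop = FALSE],
                            train_ds$Y[tr_rows, , drop = FALSE],
                            grid = grid, dropout_rate = dropout_rate,
                            seed = vseed)
          predict(model, F[test_rows, , drop = FALSE])
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1]] <-
          data.frame(partition = k, variant = lab,
                     message = conditionMessage(res))
        next
      }
      tab <- pearson_by_trait_env(res, truth, part$test_cells)
      tab$partition <- k; tab$variant <- lab
      scores[[length(scores) + 1]] <- tab
    }
  }
  scores <- do.call(rbind, scores)
  if (!is.null(h2)) scores <- adjust_by_heritability(scores, h2)
  summary <- summarize_accuracy(scores)
  overall <- stats::aggregate(mean_r ~ variant, data = summary, FUN = mean)
  names(overall)[2] <- "cross_stratum_mean"
  list(scores = scores, summary = summary, overall = overall,
       errors = if (length(errors)) do.call(rbind, errors) else NULL,
       partitions = parts, seed = seed)
}
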