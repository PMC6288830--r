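## Synthetic multi-trait multi-environment data, generated exactly from
## the mixed model's own generative process so that every other module is
## testable without external trial data.

#' Simulate a biallelic marker matrix
#'
#' Per-marker minor allele frequencies are drawn uniformly on
#' \code{maf_range} and genotypes are sampled under Hardy-Weinberg
#' proportions onto the -1/0/1 coding (minor homozygote, heterozygote,
#' major homozygote). Loci are independent -- no linkage disequilibrium is
#' simulated.
#'
#' @param J Number of lines.
#' @param p Number of markers.
#' @param maf_range Range of per-marker minor allele frequencies, a
#'   sub-interval of (0, 0.5].
#' @param missing_rate Fraction of calls masked as missing.
#' @param seed Integer seed (\code{NULL} uses the current RNG stream).
#' @return A J x p marker matrix with line/marker ids as dimnames.
#' @export
simulate_markers <- function(J, p, maf_range = c(0.05, 0.5),
                             missing_rate = 0, seed = NULL) {
  stopifnot(J >= 1, p >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            missing_rate >= 0, missing_rate < 1)
  with_seed(seed, {
    maf <- stats::runif(p, maf_range[1], maf_range[2])
    ## minor-allele dosage ~ Binomial(2, maf); code -1/0/1
    dosage <- matrix(stats::rbinom(J * p, 2, rep(maf, each = J)), J, p)
    W <- dosage - 1
    W <- -W                                   # dosage 2 (minor hom) -> -1
    if (missing_rate > 0)
      W[matrix(stats::runif(J * p) < missing_rate, J, p)] <- NA
    dimnames(W) <- list(sprintf("L%03d", seq_len(J)),
                        sprintf("M%04d", seq_len(p)))
    W
  })
}

#' Simulate a multi-trait multi-environment dataset from the mixed model
#'
#' Draws genotype-by-trait effects from MN(0, Gg, Sigma_t), optional
#' genotype-by-environment effects from MN(0, Sigma_E \%x\% Gg, Sigma_t)
#' and residuals from MN(0, I, Re), then assembles the phenotype matrix
#' as \code{X beta + Z1 b1 (+ Z2 b2) + E} in the package's frozen
#' environment-major cell ordering. The realized effects, residuals,
#' genetic values and per trait-environment signal fractions (realized
#' heritabilities) are retained.
#'
#' Defaults describe a mid-size breeding trial with moderately heritable,
#' genetically correlated traits: unit genetic variances with trait and
#' environment correlations of 0.5, and unit residual variances with a
#' residual trait correlation of 0.1. \code{beta} defaults to distinct
#' integers per environment-trait combination so fixed-effect recovery is
#' visually checkable.
#'
#' @param J,I,L,p Lines, environments, traits and markers.
#' @param beta I x L matrix of environment-by-trait means.
#' @param Sigma_t L x L genetic trait covariance.
#' @param Sigma_E I x I environment covariance of the interaction term.
#' @param Re L x L residual covariance.
#' @param gxe Include the genotype-by-environment term.
#' @param maf_range,missing_marker_rate Passed to
#'   \code{\link{simulate_markers}}; missing calls are mean-imputed
#'   before the GRM is formed.
#' @param markers Optional pre-made marker matrix (overrides \code{J},
#'   \code{p} and the marker simulation).
#' @param seed Integer seed.
#' @return A list of class \code{mtme_sim} with elements \code{data} (an
#'   \code{\link{mtme_data}}) and \code{truth} (realized \code{beta},
#'   \code{b1}, \code{b2}, \code{E}, genetic values, per-stratum
#'   heritabilities \code{h2} and the generator parameters).
#' @export
simulate_dataset <- function(J = 50, I = 3, L = 2, p = 200, beta = NULL,
                             Sigma_t = NULL, Sigma_E = NULL, Re = NULL,
                             gxe = TRUE, maf_range = c(0.05, 0.5),
                             missing_marker_rate = 0, markers = NULL,
                             seed = NULL) {
  if (is.null(Sigma_t)) Sigma_t <- 0.5 * diag(L) + 0.5
  if (is.null(Sigma_E)) Sigma_E <- 0.5 * diag(I) + 0.5
  if (is.null(Re)) Re <- 0.9 * diag(L) + 0.1
  check_pd(Sigma_t, "Sigma_t"); check_pd(Re, "Re")
  if (gxe) check_pd(Sigma_E, "Sigma_E")
  with_seed(seed, {
    W <- if (is.null(markers))
      simulate_markers(J, p, maf_range, missing_marker_rate, seed = NULL)
    else markers
    J <- nrow(W)
    if (anyNA(W)) W <- impute_markers(W)
    G <- validate_grm(compute_grm(W))
    if (is.null(beta)) beta <- matrix(seq_len(I * L), I, L)
    stopifnot(nrow(beta) == I, ncol(beta) == L)

    env_ids <- paste0("Env", seq_len(I))
    trait_ids <- paste0("T", seq_len(L))
    n <- J * I
    env_idx <- rep(seq_len(I), each = J)
    line_idx <- rep(seq_len(J), times = I)

    b1 <- rmatnorm(matrix(0, J, L), G, Sigma_t)
    b2 <- if (gxe)
      rmatnorm(matrix(0, I * J, L), kronecker(Sigma_E, G), Sigma_t)
    else matrix(0, I * J, L)
    E <- matrix(stats::rnorm(n * L), n, L) %*% t(psd_factor(Re))

    genetic <- b1[line_idx, , drop = FALSE]
    if (gxe) genetic <- genetic + b2[(env_idx - 1L) * J + line_idx, ,
                                     drop = FALSE]
    Y <- beta[env_idx, , drop = FALSE] + genetic + E

    pheno <- data.frame(Line = rownames(W)[line_idx],
                        Env = env_ids[env_idx],
                        stringsAsFactors = FALSE)
    pheno[trait_ids] <- as.data.frame(Y)
    ds <- mtme_data(pheno, G)

    h2 <- expand.grid(Trait = trait_ids, Env = env_ids,
                      stringsAsFactors = FALSE)
    h2$h2 <- mapply(function(tr, en) {
      r <- which(env_ids[env_idx] == en)
      l <- match(tr, trait_ids)
      stats::var(genetic[r, l]) / stats::var(Y[r, l])
    }, h2$Trait, h2$Env)

    structure(
      list(data = ds,
           truth = list(beta = beta, b1 = b1,
                        b2 = if (gxe) b2 else NULL, E = E,
                        genetic = genetic, h2 = h2, markers = W,
                        Sigma_t = Sigma_t,
                        Sigma_E = if (gxe) Sigma_E else NULL, Re = Re,
                        gxe = gxe)),
      class = "mtme_sim")
  })
}

#' Mask the test cells of a cross-validation partition
#'
#' Returns a copy of the dataset in which the trait values of every test
#' cell are set to missing, turning them into prediction targets; all
#' other cells are untouched.
#'
#' @param ds An \code{\link{mtme_data}} object.
#' @param partition A \code{cv_partition} from
#'   \code{\link{cv2_partition}} (or any data.frame with \code{Line} and
#'   \code{Env} columns in \code{$test_cells}).
#' @return The masked \code{mtme_data}.
#' @export
mask_cells <- function(ds, partition) {
  stopifnot(inherits(ds, "mtme_data"))
  test <- if (is.data.frame(partition)) partition else partition$test_cells
  rows <- cell_rows(ds, test)
  ds$Y[rows, ] <- NA_real_
  ds
}

## Row indices of the given (Line, Env) cells in the dataset ordering.
cell_rows <- function(ds, cells) {
  idx <- match(paste(cells$Env, cells$Line, sep = "\r"),
               paste(ds$cells$Env, ds$cells$Line, sep = "\r"))
  if (anyNA(idx))
    stop("cells not present in dataset: ",
         paste(head(paste(cells$Line, cells$Env, sep = "/")[is.na(idx)], 5),
               collapse = ", "), call. = FALSE)
  idx
}
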