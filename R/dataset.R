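## The multi-trait multi-environment dataset container.
##
## An `mtme_data` object aligns one row per line-by-environment cell with
## the L trait values observed in that cell and the genomic relationship
## matrix of the lines. The cell ordering is environment-major (all lines
## of the first environment, then the second, ...), with lines ordered by
## first appearance in the phenotype table; this ordering is frozen at
## construction because the Kronecker-compatible column order of the
## genotype-by-environment design matrix depends on it.

#' Construct a multi-trait multi-environment dataset
#'
#' Aligns a phenotype table (one row per line-by-environment cell) with a
#' genomic relationship matrix. Every line must appear in the GRM; cells
#' absent from the phenotype table (or with missing trait values) are kept
#' as missing -- they are legitimate prediction targets.
#'
#' @param pheno A data.frame with columns \code{Line}, \code{Env} and one
#'   numeric column per trait. Each (Line, Env) pair may appear at most
#'   once.
#' @param grm A J x J symmetric genomic relationship matrix whose dimnames
#'   cover every line in \code{pheno}.
#' @return An object of class \code{mtme_data} with components
#'   \code{cells} (data.frame of Line/Env in the frozen ordering),
#'   \code{Y} (n x L trait matrix, NA = unobserved), \code{line_ids},
#'   \code{env_ids}, \code{trait_ids} and \code{grm}.
#' @export
mtme_data <- function(pheno, grm) {
  stopifnot(is.data.frame(pheno))
  if (!all(c("Line", "Env") %in% names(pheno)))
    stop("phenotype table needs 'Line' and 'Env' columns", call. = FALSE)
  trait_ids <- setdiff(names(pheno), c("Line", "Env"))
  if (length(trait_ids) == 0)
    stop("phenotype table has no trait columns", call. = FALSE)
  pheno$Line <- as.character(pheno$Line)
  pheno$Env <- as.character(pheno$Env)
  if (anyDuplicated(pheno[c("Line", "Env")]))
    stop("duplicate (Line, Env) cells in phenotype table", call. = FALSE)

  line_ids <- unique(pheno$Line)             # order of first appearance
  env_ids <- unique(pheno$Env)
  missing_lines <- setdiff(line_ids, rownames(grm))
  extra_lines <- setdiff(rownames(grm), line_ids)
  if (length(missing_lines))
    stop("line ids in phenotypes but not in markers/GRM: ",
         paste(missing_lines, collapse = ", "),
         if (length(extra_lines))
           paste0("; in markers/GRM only: ",
                  paste(extra_lines, collapse = ", ")) else "",
         call. = FALSE)
  grm <- validate_grm(grm[line_ids, line_ids, drop = FALSE])

  J <- length(line_ids); I <- length(env_ids); L <- length(trait_ids)
  cells <- data.frame(
    Line = rep(line_ids, times = I),
    Env = rep(env_ids, each = J),
    stringsAsFactors = FALSE
  )
  Y <- matrix(NA_real_, nrow = J * I, ncol = L,
              dimnames = list(NULL, trait_ids))
  row_of <- match(paste(pheno$Env, pheno$Line, sep = "\r"),
                  paste(cells$Env, cells$Line, sep = "\r"))
  Y[row_of, ] <- as.matrix(pheno[trait_ids])

  structure(
    list(cells = cells, Y = Y, line_ids = line_ids, env_ids = env_ids,
         trait_ids = trait_ids, grm = grm),
    class = "mtme_data"
  )
}

#' @export
print.mtme_data <- function(x, ...) {
  cat(sprintf(
    "mtme_data: %d lines x %d environments (%d cells), %d trait(s)\n",
    length(x$line_ids), length(x$env_ids), nrow(x$cells),
    length(x$trait_ids)))
  cat(sprintf("  observed cells: %d of %d\n",
              sum(stats::complete.cases(x$Y)), nrow(x$Y)))
  cat("  traits:", paste(x$trait_ids, collapse = ", "), "\n")
  invisible(x)
}

n_cells <- function(ds) nrow(ds$cells)

## Rows of Y whose cell is fully observed (cell-level missingness: a cell
## with any missing trait is treated as unobserved).
observed_rows <- function(ds) which(stats::complete.cases(ds$Y))

#' Build the incidence (design) matrices of the mixed model
#'
#' Returns the environment incidence matrix X (n x I), the line incidence
#' matrix Z1 (n x J) and the line-within-environment incidence matrix Z2
#' (n x IJ). Z2's column for the cell of line j in environment i is
#' \code{(i - 1) * J + j}, so its column order is compatible with the
#' Kronecker row ordering (environment-major) of the
#' genotype-by-environment effect matrix.
#'
#' @param ds An \code{mtme_data} object.
#' @return A list with dense 0/1 matrices \code{X}, \code{Z1}, \code{Z2};
#'   every row of each matrix has exactly one 1.
#' @export
build_design <- function(ds) {
  stopifnot(inherits(ds, "mtme_data"))
  J <- length(ds$line_ids); I <- length(ds$env_ids); n <- n_cells(ds)
  env_idx <- match(ds$cells$Env, ds$env_ids)
  line_idx <- match(ds$cells$Line, ds$line_ids)
  X <- matrix(0, n, I, dimnames = list(NULL, ds$env_ids))
  X[cbind(seq_len(n), env_idx)] <- 1
  Z1 <- matrix(0, n, J, dimnames = list(NULL, ds$line_ids))
  Z1[cbind(seq_len(n), line_idx)] <- 1
  Z2 <- matrix(0, n, I * J)
  Z2[cbind(seq_len(n), (env_idx - 1L) * J + line_idx)] <- 1
  colnames(Z2) <- paste(rep(ds$env_ids, each = J),
                        rep(ds$line_ids, times = I), sep = ":")
  list(X = X, Z1 = Z1, Z2 = Z2)
}

#' Read a phenotype table from delimited text
#'
#' Header row with columns \code{Line}, \code{Env} and one column per
#' trait; empty fields are missing. Comma or tab separation is
#' auto-detected.
#'
#' @param path Path to the phenotype file.
#' @return A data.frame suitable for \code{\link{mtme_data}}.
#' @export
read_phenotypes <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#",
                          na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  if (!all(c("Line", "Env") %in% names(df)))
    stop("phenotype file must have 'Line' and 'Env' columns: ", path,
         call. = FALSE)
  df
}

# ---- trait standardisation ---------------------------------------------

#' Fit a per-trait standardiser on training responses
#'
#' Computes the per-trait mean and sample standard deviation (denominator
#' n - 1) over the non-missing training values. The scaler is meant to be
#' fitted on training cells only and then applied to both training and
#' test responses; predictions on the standardised scale are mapped back
#' with \code{\link{unscale_traits}}.
#'
#' @param Y Numeric matrix (rows = cells, columns = traits); NAs allowed.
#' @return An object of class \code{trait_scaler} with \code{means} and
#'   \code{sds}.
#' @export
fit_scaler <- function(Y) {
  Y <- as.matrix(Y)
  n_ok <- colSums(!is.na(Y))
  if (any(n_ok < 2))
    stop("each trait needs at least 2 non-missing training values",
         call. = FALSE)
  means <- colMeans(Y, na.rm = TRUE)
  sds <- apply(Y, 2, stats::sd, na.rm = TRUE)
  bad <- !is.finite(sds) | sds <= 0
  if (any(bad))
    stop("zero-variance trait(s): ",
         paste(colnames(Y)[bad], collapse = ", "), call. = FALSE)
  structure(list(means = means, sds = sds), class = "trait_scaler")
}

#' Standardise trait values with a fitted scaler
#' @param Y Numeric matrix of trait values.
#' @param scaler A \code{trait_scaler} from \code{\link{fit_scaler}}.
#' @return Matrix of the same shape on the standardised scale.
#' @export
scale_traits <- function(Y, scaler) {
  stopifnot(inherits(scaler, "trait_scaler"))
  sweep(sweep(as.matrix(Y), 2, scaler$means, "-"), 2, scaler$sds, "/")
}

#' Back-transform standardised trait values to the original scale
#' @inheritParams scale_traits
#' @return Matrix of the same shape on the original trait scales.
#' @export
unscale_traits <- function(Y, scaler) {
  stopifnot(inherits(scaler, "trait_scaler"))
  sweep(sweep(as.matrix(Y), 2, scaler$sds, "*"), 2, scaler$means, "+")
}
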