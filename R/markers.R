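## Marker quality control and the genomic relationship matrix.
##
## Markers are plain numeric matrices (lines in rows, markers in columns)
## coded -1/0/1 for the minor-allele homozygote, heterozygote and
## major-allele homozygote, with NA for missing calls. Row names are line
## identifiers, column names marker identifiers.

validate_markers <- function(W) {
  if (!is.matrix(W) || !is.numeric(W))
    stop("marker matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(W)) || anyDuplicated(rownames(W)))
    stop("marker matrix must have unique row names (line ids)", call. = FALSE)
  vals <- W[!is.na(W)]
  if (length(vals) && !all(vals %in% c(-1, 0, 1)))
    stop("marker codes must be -1, 0 or 1 (NA for missing)", call. = FALSE)
  invisible(W)
}

#' Filter markers by missing rate and minor allele frequency
#'
#' Removes markers whose fraction of missing calls exceeds
#' \code{max_missing_rate} and markers whose minor allele frequency (MAF)
#' fails the \code{min_maf} threshold. The MAF is computed from allele
#' dosages \code{(code + 1) / 2} over the non-missing lines, folded to the
#' minor allele. With \code{maf_inclusive = TRUE} (the default, matching the
#' common "lower than or equal to" rule) markers with MAF equal to the
#' threshold are removed as well; with \code{FALSE} only strictly smaller
#' MAFs are removed.
#'
#' @param W Numeric matrix of markers coded -1/0/1 with NA for missing,
#'   lines in rows.
#' @param max_missing_rate Maximum tolerated fraction of missing calls per
#'   marker, in \code{[0, 1]}.
#' @param min_maf Minor-allele-frequency threshold, in \code{[0, 0.5]}.
#' @param maf_inclusive If \code{TRUE}, remove markers with MAF \code{<=}
#'   \code{min_maf}; if \code{FALSE}, remove only MAF \code{<} threshold.
#' @return The filtered marker matrix (column order preserved).
#' @examples
#' W <- rbind(L1 = c(1, 1), L2 = c(1, -1), L3 = c(1, 0), L4 = c(1, NA))
#' colnames(W) <- c("mono", "seg")
#' filter_markers(W)  # monomorphic marker dropped
#' @export
filter_markers <- function(W, max_missing_rate = 0.8, min_maf = 0.05,
                           maf_inclusive = TRUE) {
  validate_markers(W)
  stopifnot(max_missing_rate >= 0, max_missing_rate <= 1,
            min_maf >= 0, min_maf <= 0.5)
  miss <- colMeans(is.na(W))
  dosage <- (W + 1) / 2                      # allele dosage in {0, 1/2, 1}
  freq <- colMeans(dosage, na.rm = TRUE)
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0                      # all-missing column
  ## tolerance keeps exact-boundary frequencies (e.g. 1/10) from being
  ## decided by floating-point rounding
  tol <- 1e-9
  keep <- miss <= max_missing_rate &
    (if (maf_inclusive) maf > min_maf + tol else maf >= min_maf - tol)
  if (!any(keep))
    stop("empty marker set: all markers removed by filtering", call. = FALSE)
  W[, keep, drop = FALSE]
}

#' Impute missing marker calls with the marker mean
#'
#' Each missing entry is replaced by the mean of the non-missing calls for
#' that marker (a real value, not rounded back to -1/0/1). Non-missing
#' entries are unchanged.
#'
#' @param W Numeric marker matrix with NA for missing calls.
#' @return A marker matrix with no missing entries.
#' @export
impute_markers <- function(W) {
  validate_markers(W)
  all_missing <- colSums(!is.na(W)) == 0
  if (any(all_missing))
    stop("cannot impute all-missing marker(s): ",
         paste(colnames(W)[all_missing], collapse = ", "), call. = FALSE)
  mu <- colMeans(W, na.rm = TRUE)
  idx <- which(is.na(W), arr.ind = TRUE)
  if (nrow(idx)) W[idx] <- mu[idx[, 2]]
  W
}

#' Compute the genomic relationship matrix
#'
#' Builds the J x J genomic relationship matrix (GRM) from the marker
#' matrix as \eqn{G_g = W W^T / p}, where \eqn{p} is the number of markers
#' (VanRaden-style, with the -1/0/1 codes used as given; no allele-frequency
#' centring is applied, and none is applied silently -- see the methods
#' vignette).
#'
#' @param W Numeric marker matrix with no missing entries.
#' @return A symmetric J x J matrix with the line ids as dimnames.
#' @export
compute_grm <- function(W) {
  if (anyNA(W))
    stop("marker matrix has missing entries; run impute_markers() first",
         call. = FALSE)
  if (ncol(W) < 1) stop("need at least one marker", call. = FALSE)
  G <- tcrossprod(W) / ncol(W)
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(W), rownames(W))
  G
}

## Validate a (possibly user-supplied) GRM: symmetry, PSD up to tolerance,
## and jitter the diagonal when the smallest eigenvalue is negative so that
## downstream factorisations are stable.
validate_grm <- function(G, jitter = TRUE) {
  if (!is.matrix(G) || nrow(G) != ncol(G))
    stop("GRM must be a square matrix", call. = FALSE)
  if (max(abs(G - t(G))) > 1e-6 * max(1, max(abs(G))))
    stop("GRM must be symmetric", call. = FALSE)
  G <- (G + t(G)) / 2
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(ev)
  if (min(ev) < -1e-8 * max(lmax, 1))
    stop(sprintf("GRM is not positive semi-definite (min eigenvalue %.3g)",
                 min(ev)), call. = FALSE)
  if (jitter && min(ev) < 0) {
    eps <- 1e-8 * sum(diag(G)) / nrow(G)
    G <- G + diag(eps, nrow(G))
  }
  G
}

#' Read a marker matrix from delimited text
#'
#' The file must have a header row whose first column is \code{Line}; the
#' remaining columns are markers coded -1/0/1 with empty fields for missing
#' calls. Comma or tab separation is auto-detected.
#'
#' @param path Path to the marker file.
#' @return A numeric marker matrix with line ids as row names.
#' @export
read_markers <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#",
                          na.strings = c("", "NA"))
  if (names(df)[1] != "Line")
    stop("marker file must start with a 'Line' column: ", path, call. = FALSE)
  W <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(W) <- "double"
  rownames(W) <- as.character(df$Line)
  validate_markers(W)
  W
}

#' Read a genomic relationship matrix from delimited text
#'
#' Square matrix with line ids in both the header row and the first column.
#'
#' @param path Path to the GRM file.
#' @return A symmetric numeric matrix with line ids as dimnames.
#' @export
read_grm <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#",
                          row.names = 1)
  G <- as.matrix(df)
  if (nrow(G) != ncol(G) || !setequal(rownames(G), colnames(G)))
    stop("GRM file must be square with matching row/column ids; mismatch: ",
         paste(union(setdiff(rownames(G), colnames(G)),
                     setdiff(colnames(G), rownames(G))), collapse = ", "),
         call. = FALSE)
  G <- G[, rownames(G), drop = FALSE]
  validate_grm(G)
}
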