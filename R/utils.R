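## Internal helpers shared across modules.

#' @importFrom stats rnorm rbinom runif sd cor rWishart var
#' @importFrom utils read.table write.table head
NULL

## round() in R rounds half to even; cross-validation sizing uses
## round-half-away-from-zero so that 0.2 * N behaves as breeders expect.
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state. A NULL seed leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

## Deterministically derive a child seed from a master seed, kept within
## 32-bit integer range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647L)
}

is_square_pd <- function(S, tol = 1e-8) {
  is.matrix(S) && nrow(S) == ncol(S) &&
    max(abs(S - t(S))) < tol * max(1, max(abs(S))) &&
    min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0
}

check_pd <- function(S, name) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("'%s' must be positive definite (min eigenvalue %.3g)",
                 name, min(ev)), call. = FALSE)
  invisible(TRUE)
}

## Detect the field separator of a delimited text file (tab or comma).
detect_sep <- function(path) {
  lines <- readLines(path, n = 10L)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", lines[1])) "\t" else ","
}

## Write a delimited table preceded by a provenance comment header.
write_output_table <- function(df, path, seed = NA) {
  header <- sprintf("# mtmegp %s seed=%s",
                    as.character(utils::packageVersion("mtmegp")),
                    as.character(seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
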