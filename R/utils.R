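#' @useDynLib cfcin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd setNames pchisq qnorm quantile rbinom rexp
#'   rlnorm rnbinom rnorm rpois runif uniroot fisher.test
#' @importFrom utils read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Run code with a private RNG stream
#'
#' Seeds the session RNG with `seed`, runs `expr`, and restores the caller's
#' RNG state afterwards, so simulation helpers are pure functions of their
#' configuration and never perturb user code.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Write a table atomically: tempfile in the target directory, then rename.
write_tsv_atomic <- function(df, path, col.names = TRUE) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
  file.rename(tmp, path)
  invisible(path)
}
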