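## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Evaluate an expression under a fixed RNG seed (restores RNG state after)
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

#' Atomic write: run `writer(tmp)` then rename tmp onto `path`
#' @noRd
write_atomic <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stopf("could not move temporary file onto '%s'", path)
  invisible(path)
}

#' Write a data.frame as a TSV (header, no quotes, no row names), atomically
#' @noRd
write_tsv_atomic <- function(df, path) {
  write_atomic(path, function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  })
}

#' @noRd
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
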