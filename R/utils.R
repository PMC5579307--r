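`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a fixed RNG seed, restoring global state afterwards
#'
#' All stochastic generators in the package route their randomness through
#' this helper so that they behave as pure functions of `(parameters, seed)`
#' and never clobber the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)  # force RNG initialisation so we have a state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Atomic file write
#'
#' Writes via a temporary file in the destination directory followed by
#' `file.rename()`, so that a crash never leaves a half-written output.
#'
#' @param path destination path.
#' @param writer function of one argument (a path) that performs the write.
#' @return `path`, invisibly.
#' @keywords internal
write_atomic <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

stop_domain <- function(...) {
  stop(structure(class = c("azeoblend_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
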