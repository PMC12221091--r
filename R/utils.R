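# internal helpers: typed conditions, named-stream RNG, small numerics

abort_sp <- function(msg, class = "settleprot_error", call. = FALSE) {
  cond <- structure(
    class = c(class, "settleprot_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

warn_sp <- function(msg, class = "settleprot_warning") {
  warning(structure(
    class = c(class, "settleprot_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Derive a deterministic per-stream seed from a base seed
#'
#' One base seed drives every stochastic stage of the pipeline; each named
#' stream gets its own derived seed, so adding a generator never perturbs the
#' draws of another.
#'
#' @param seed Integer base seed.
#' @param stream Character stream name.
#' @return An integer seed in \[0, 2^31 - 2\].
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1, keeps arithmetic exact in doubles
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% m
  as.integer(((seed %% m) * 48271 + h) %% m)
}

# evaluate `code` under the derived stream seed, restoring the caller's RNG
with_stream_seed <- function(seed, stream, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(stream_seed(seed, stream))
  code
}

row_vars <- function(x, na.rm = FALSE) {
  n <- if (na.rm) rowSums(is.finite(x)) else rep(ncol(x), nrow(x))
  mu <- rowMeans(x, na.rm = na.rm)
  ss <- rowSums((x - mu)^2, na.rm = na.rm)
  out <- ss / pmax(n - 1, 1)
  out[n < 2] <- NA_real_
  out
}

# deterministic TSV writer (fixed formatting, no quoting surprises)
write_tsv_sp <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
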