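# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the global
# RNG stream is restored afterwards so seeded package calls do not perturb
# the caller's stream.  seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and an index, staying within the
# 32-bit integer range R requires.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}

stop_instability <- function(step, where = "trajectory") {
  cond <- structure(
    class = c("splitkl_instability", "error", "condition"),
    list(message = sprintf(
           "non-finite or diverged state encountered at step %d (%s)",
           step, where),
         call = sys.call(-1), step = step, where = where))
  stop(cond)
}

#' Write a results table to CSV with exact numeric round-trip
#'
#' Doubles are formatted with 17 significant digits so that
#' [read_results_csv()] recovers them bit-identically.
#'
#' @param df data.frame of results.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a results table written by [write_results_csv()]
#'
#' @param path CSV file path.
#' @return data.frame with numeric columns restored.
#' @export
read_results_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
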