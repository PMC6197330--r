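# Internal helpers: deterministic child seed streams, argument checks, TSV I/O.

#' Derive a deterministic child seed for a named stage
#'
#' All randomness in the package flows from one top-level seed; each stage
#' (genome, counts, reads, metabolites, patients, ...) draws from its own child
#' stream so stages can be regenerated independently without disturbing each
#' other.
#'
#' @param seed Integer top-level seed.
#' @param stage Character stage name.
#' @return An integer seed in [0, 2^31 - 2], a deterministic function of
#'   `(seed, stage)`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded from (seed, stage),
# restoring the caller's RNG state afterwards.
with_child_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(child_seed(seed, stage))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("`%s` must be a single finite number in [%s, %s]", name,
          format(lower), format(upper))
  invisible(x)
}

#' Write a data frame as a plain TSV file
#'
#' Deterministic formatting (no quoting, no row names) so repeated runs with
#' identical inputs are byte-identical.
#' @param x A data frame.
#' @param path Output path.
#' @param comment Optional character vector of `#`-prefixed header lines.
#' @export
write_tsv <- function(x, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
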