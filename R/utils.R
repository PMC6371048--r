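# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
withSeed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Fast TSV writers/readers with fixed conventions (tab, no quoting, header).
writeTSV <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

readTSV <- function(path) {
  utils::read.table(path,
    sep = "\t", header = TRUE, quote = "",
    comment.char = "", stringsAsFactors = FALSE, check.names = FALSE
  )
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite scalar number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# population (divisor n) standard deviation
sdPop <- function(x) sqrt(mean((x - mean(x))^2))
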