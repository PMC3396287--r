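# Internal helpers shared across stages.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a deterministic sub-stream seed (< 2^31) from a base seed and a set
# of string/number labels, so that e.g. each (mark, replicate) array gets its
# own reproducible stream.
derive_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                         character(1)), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(labels)) h <- (h * 31 + ch) %% 1999999973
  as.integer((abs(as.numeric(seed)) %% 46340) * 46341 + h %% 46341) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_sorted_by_position <- function(df) {
  o <- order(df$chromosome, df$position, method = "radix")
  identical(o, seq_len(nrow(df)))
}

sort_by_position <- function(df) {
  df[order(df$chromosome, df$position, method = "radix"), , drop = FALSE]
}
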