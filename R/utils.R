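# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream. Seeds are kept below 2^31 - 1.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(expr)
}

# Natural (human) sort: "slice2.png" < "slice10.png".
natural_sort <- function(x) {
  if (length(x) == 0) return(x)
  toks <- regmatches(x, gregexpr("[0-9]+|[^0-9]+", x))
  nmax <- max(lengths(toks))
  keys <- lapply(seq_len(nmax), function(i) {
    piece <- vapply(toks, function(t) if (i <= length(t)) t[i] else "", "")
    num <- suppressWarnings(as.numeric(piece))
    if (all(!is.na(num) | piece == "")) {
      num[piece == ""] <- -Inf
      num
    } else piece
  })
  x[do.call(order, keys)]
}

# floor(x + 0.5): deterministic half-up rounding, invariant under integer
# translation (round() is not, because of round-half-to-even).
rnd_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
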