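## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
## stream is untouched. seed = NULL leaves the current stream in place.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed deterministically, kept inside 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + k * 1299709) %% 2147483647)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

assert_cols <- function(table, cols, where = "table") {
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop_config("%s lacks required column(s): %s", where,
                paste(miss, collapse = ", "))
  invisible(TRUE)
}

ARM_LEVELS <- c("LCPUFA", "HND", "UC")
ARM_PAIRS <- list(c("LCPUFA", "HND"), c("LCPUFA", "UC"), c("HND", "UC"))

pair_label <- function(pair) paste(pair[1], "vs", pair[2])
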