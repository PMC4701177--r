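#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible child seed for a named stage from a master seed.
# Keeps results below .Machine$integer.max so set.seed() always accepts them.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483629L)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores
# the caller's RNG stream afterwards. seed = NULL leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_msrs <- function(..., class) {
  stop(structure(class = c(class, "msrs_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x)
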