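#' @keywords internal
#' @useDynLib pfeeg, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and a stream label, staying < 2^31.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  # cheap deterministic hash of the key into [0, 2^31 - 2]
  bytes <- utf8ToInt(key)
  acc <- 0
  for (b in bytes) acc <- (acc * 131 + b) %% 2147483647
  as.integer(acc)
}

# run f(...) with the compiled fast path disabled (diagnostic re-runs)
withr_native_off <- function(f, ...) {
  old <- options(pfeeg.use_native = FALSE)
  on.exit(options(old), add = TRUE)
  f(...)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("non-finite values in %s", what)
  invisible(x)
}
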