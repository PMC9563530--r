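#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix %&%
#' @importFrom methods as is new
#' @importFrom stats rnorm runif rbinom pchisq quantile
#' @importFrom utils read.delim write.table head tail
NULL

# Internal validation helper: stop with a classed condition so callers (and
# the command-line wrappers) can distinguish user/validation errors from bugs.
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("gcnprio_validation", "error")))
}

stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("gcnprio_parse", "error")))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All randomness in the package flows
# through this helper so that a single configured seed determines every run.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_validation("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed from a master seed and a stream label, so
# independent components (fixture files, per-namespace model training, ...)
# consume independent substreams. Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(label)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_binary_matrix <- function(m) {
  if (inherits(m, "sparseMatrix")) {
    x <- if (methods::is(m, "nsparseMatrix")) numeric(0) else m@x
    all(x %in% c(0, 1))
  } else {
    all(m %in% c(0, 1))
  }
}
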