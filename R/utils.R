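# internal helpers

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All package randomness funnels through this
# so pipelines are reproducible without trashing the user's RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a stream of child seeds from one parent seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("ictalnet_validation_error", "error")))
}

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("ictalnet_format_error", "error")))
}

# Signal for metrics whose denominator is empty: warning + NA, never silent 0.
undefined_metric <- function(what) {
  warning(warningCondition(
    sprintf("%s is undefined (empty denominator)", what),
    class = "ictalnet_undefined_metric"))
  NA_real_
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# content hash of a serialized object, for run manifests
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
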