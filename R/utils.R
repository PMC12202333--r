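# Shared internal helpers.

# Deterministic substream derivation: fold arbitrary keys (integers or short
# strings) into a 31-bit seed with a polynomial hash, so per-(subject, state)
# or per-fold streams are reproducible regardless of generation order.
derive_seed <- function(seed, ...) {
  keys <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in keys) {
    if (is.character(k)) k <- utf8ToInt(k)
    for (v in as.numeric(k)) {
      h <- (h * 1000003 + (v %% 2147483647) + 12345) %% 2147483647
    }
  }
  as.integer(h)
}

# Run code with a local RNG state so callers' streams are untouched.
with_local_seed <- function(seed, code) {
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
  })
  set.seed(seed)
  force(code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

# Columns of a feature table that hold features (everything but metadata).
feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "state", "epoch", "label"))
}

state_to_label <- function(state) {
  as.integer(state == "fatigue")
}
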