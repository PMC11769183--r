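# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generator functions are pure in their (args, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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
  force(code)
}

# Derive a reproducible child seed (< 2^31) from a base seed and string/integer
# salts, so independent random streams do not collide across subjects/stages.
derive_seed <- function(seed, ...) {
  salts <- list(...)
  h <- as.double(seed %% 2147483647L)
  for (s in salts) {
    v <- if (is.character(s)) sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) else as.double(s)
    h <- (h * 69069 + v * 12345 + 1) %% 2147483647
  }
  as.integer(h %% 2147483587 + 1)
}

assert_that <- function(ok, msg, class = "fatiguecg_error") {
  if (!isTRUE(ok)) abort(msg, class = c(class, "fatiguecg_error"))
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
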