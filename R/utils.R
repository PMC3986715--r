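#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package go
# through this so that a user-level seed fully determines every result.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
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
  set.seed(seed)
  force(code)
}

# Derive the i-th stage seed from a global seed, staying within the 32-bit
# integer range R requires of set.seed().
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %%
    2147483647L)
}

# round-half-up, used for the data-split arithmetic where round()'s
# round-half-even rule would be surprising (0.67 * 10 = 6.7 -> 7)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
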