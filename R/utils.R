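# Small shared helpers.

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so library calls never perturb a user's random stream.
with_preserved_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer mixing used to give each variety/sample its own
#' reproducible random stream. The result always fits in a 32-bit integer.
#'
#' @param master integer master seed.
#' @param k integer stream index (>= 0).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, k) {
  stopifnot(is.numeric(master), is.numeric(k), length(master) == 1L,
            length(k) == 1L)
  as.integer(((abs(master) %% 1048576) * 1000003 + abs(k) * 7919 + 17) %%
               2147483646)
}

softmax_rows <- function(b) {
  m <- apply(b, 1L, max)
  e <- exp(b - m)
  e / rowSums(e)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
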