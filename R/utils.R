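# Deterministic expansion of one master seed into n independent sub-seeds.
# Restores the caller's RNG state so derivation itself has no side effects.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Default replicate seeds for a seed battery
#'
#' Expands one master seed into the requested number of replicate seeds
#' (five by default, one per random weight initialization).
#'
#' @param seed integer master seed.
#' @param n number of replicates.
#' @return integer vector of length \code{n}.
#' @export
default_seeds <- function(seed = 1L, n = 5L) derive_seeds(seed, n)

# centered moving average with symmetrically truncated edges
moving_average <- function(x, window = 13L) {
  n <- length(x)
  half <- window %/% 2L
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}
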