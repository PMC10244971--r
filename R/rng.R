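# Counter-based random streams.
#
# Every stochastic decision in the simulator (polarization sampling, division
# plane choice, node jitter, replicate seeding) draws from a stateless hash of
# (base seed, owner id, purpose, counter). There is no global random state:
# results do not depend on the order in which cells are visited, and a stream
# can be advanced for one cell without touching any other cell's draws.

# (a * b) mod 2^31, exact in doubles via 16-bit limb split.
.mul31 <- function(a, b) {
  lo <- a %% 65536
  hi <- (a - lo) / 65536
  (((hi * b) %% 32768) * 65536 + lo * b) %% 2147483648
}

# murmur3-style avalanche finaliser reduced to 31 bits
.fmix31 <- function(x) {
  x <- x %% 2147483648
  x <- bitwXor(as.integer(x), as.integer(x %/% 65536))
  x <- .mul31(x, 1597334677)
  x <- bitwXor(as.integer(x), as.integer(x %/% 8192))
  x <- .mul31(x, 851723965)
  x <- bitwXor(as.integer(x), as.integer(x %/% 65536))
  as.double(x)
}

#' Stateless uniform deviate from a counter-based stream
#'
#' Hashes `(seed, id, purpose, counter)` to a deviate in (0, 1). Identical
#' arguments always give the identical deviate; distinct purposes give
#' independent streams for the same owner.
#'
#' @param seed integer base seed of the run.
#' @param id integer owner identifier (typically a cell id).
#' @param purpose integer stream label; see [rng_purpose].
#' @param counter non-negative integer draw index within the stream.
#' @return a double in (0, 1).
#' @export
stream_uniform <- function(seed, id, purpose, counter) {
  h <- .fmix31(seed %% 2147483648)
  h <- .fmix31(bitwXor(as.integer(h), as.integer(id %% 2147483648)))
  h <- .fmix31(bitwXor(as.integer(h), as.integer(purpose %% 2147483648)))
  h <- .fmix31(bitwXor(as.integer(h), as.integer(counter %% 2147483648)))
  (h + 0.5) / 2147483648
}

#' Stream purpose labels
#'
#' Fixed integer labels separating the independent random streams each cell
#' owns: out-of-plane polarization, in-plane orientation, division-plane
#' choice, cytoplasm-node jitter, initial cycle phase, replicate seeding.
#' @export
rng_purpose <- c(
  polarization = 1L,
  inplane      = 2L,
  plane        = 3L,
  jitter       = 4L,
  phase        = 5L,
  replicate    = 6L
)

# n deviates from consecutive counters, returning the advanced counter too
stream_uniform_n <- function(seed, id, purpose, counter, n) {
  vapply(seq_len(n), function(k) stream_uniform(seed, id, purpose, counter + k - 1),
         numeric(1))
}

#' Derive a replicate seed from a base seed
#'
#' @param base_seed integer experiment-level seed.
#' @param index replicate index (1-based).
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(base_seed, index) {
  as.integer(.fmix31(bitwXor(as.integer(.fmix31(base_seed %% 2147483648)),
                             as.integer(index %% 2147483648))) %% 2147483647) + 1L
}
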