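#' Derive a replicate-level seed from a master seed
#'
#' Seeds are split hierarchically: a master seed identifies the whole
#' replicate study and each replicate draws all of its randomness (individual
#' parameters, residual noise, composite slot allocation) from a single
#' stream seeded by `replicate_seed(master, r)`. The split keeps every
#' derived seed inside the 32-bit integer range.
#'
#' @param master_seed integer master seed for the study.
#' @param replicate replicate index (1-based).
#' @return An integer seed.
#' @export
replicate_seed <- function(master_seed, replicate) {
  stopifnot(is.numeric(master_seed), is.numeric(replicate))
  as.integer((abs(as.numeric(master_seed)) + 7919 * as.numeric(replicate)) %%
               2147483629L)
}

# run code under a temporary seed when one is supplied
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}
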