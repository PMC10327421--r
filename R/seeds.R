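#' Deterministic child seeds
#'
#' The generator and the replication runner fan a single master seed out to
#' independent child seeds, one per (study, purpose, replication) triple, so
#' that studies are simulated independently yet every run is reproducible
#' bit for bit.  The scheme is a fixed integer hash: starting from the
#' master seed, each index is folded in with multiplications by fixed primes
#' modulo \eqn{2^{31} - 19} (a prime), keeping all intermediate values exact
#' in double precision and the result a valid 32-bit seed.
#'
#' @param seed master seed (integer).
#' @param ... non-negative integer indices identifying the purpose, e.g.
#'   \code{derive_seed(seed, m, 3L)} for study \code{m}, purpose 3.
#' @return an integer in \eqn{[1, 2^{31} - 20]}.
#' @export
derive_seed <- function(seed, ...) {
  mod <- 2147483629  # 2^31 - 19, prime
  s <- as.numeric(seed) %% mod
  for (a in c(...)) {
    # 48271 * mod < 2^53: products are exact in doubles
    s <- (s * 48271 + (as.numeric(a) %% mod) * 16807 + 1) %% mod
    s <- (s * 69621) %% mod
  }
  as.integer(s %% (mod - 2) + 1)
}

with_seed <- function(seed, expr) {
  force(seed)  # evaluate any RNG-dependent seed before saving the state
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
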