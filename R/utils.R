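# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package routes through this so that one
# seeded generator backs one operation call.
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n, salt = 0L) {
  (as.double(seed) * 48271 + salt * 9973 + seq_len(n) * 2654435761) %% 2147483647
}

stop_protmap <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Haldane map function: cM distance -> recombination fraction per meiosis.
haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

# Per-meiosis recombination fraction -> observed recombination between
# fully inbred RIL genotypes (selfing series).
ril_R <- function(r) 2 * r / (1 + 2 * r)

genotype_codes <- c("A", "H", "B")

code_to_int <- function(g) {
  if (is.numeric(g)) return(g)
  m <- match(g, genotype_codes)
  dim(m) <- dim(g)
  dimnames(m) <- dimnames(g)
  m
}
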