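#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific child seed from a master seed
#'
#' A single run seed fans out to per-stage seeds by stable hashing of the
#' stage name, so that each stage is reproducible independently of the order
#' in which stages execute.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# Run code with a local RNG state: seeds deterministically, restores the
# caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# all permutations of 1..n as an (n! x n) integer matrix, row-major lexicographic
all_permutations <- function(n) {
  stopifnot(n >= 1L, n <= 9L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- seq_len(n)[-first]
    blk <- nrow(sub)
    out[row:(row + blk - 1L), 1L] <- first
    out[row:(row + blk - 1L), -1L] <- matrix(rest[sub], blk, n - 1L)
    row <- row + blk
  }
  out
}

stop_mm <- function(...) stop(..., call. = FALSE)
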