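# Internal helpers shared across modules.

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

adrMessage <- function(...) {
  if (isTRUE(getOption("adrgraph.quiet", FALSE))) return(invisible())
  message(...)
}

# pair key for set operations on (drug, effect) index matrices
pairKey <- function(mat) {
  if (nrow(mat) == 0L) return(character())
  paste(mat[, 1L], mat[, 2L], sep = ":")
}

emptyPairs <- function() matrix(integer(), ncol = 2L,
                                dimnames = list(NULL, c("drug", "effect")))

asPairMatrix <- function(p, q) {
  cbind(drug = as.integer(p), effect = as.integer(q))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# FNV-1a hash of a serialized R object, hex string; used to stamp artifact
# files with the producing configuration.
configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
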