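# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state, so seeded internals never
#' perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' Stable string hash of the stage name mixed with the run seed; keeps every
#' stage independently reproducible from one global seed. Result is always a
#' valid 32-bit integer seed.
#'
#' @param seed Integer global seed.
#' @param stage Character stage tag.
#' @return Integer seed.
#' @export
#' @examples
#' deriveSeed(1, "sequences")
deriveSeed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v)) %% 262139L
  as.integer((abs(as.numeric(seed)) + h * 7919) %% 2147483629)
}

# Random DNA string of length n (uniform over ACGT).
randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitution-only mutation. Each site is substituted with probability
# `divergence` to one of the three other bases. Returns the mutated string
# and the 1-based substituted positions (bookkeeping for truth tables).
mutateSequence <- function(seq, divergence) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < divergence)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    ch[hit] <- mapply(function(b, k) alt[[b]][k], ch[hit], pick)
  }
  list(seq = paste(ch, collapse = ""), positions = hit)
}

# Reverse complement for plain character strings.
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming matches between two equal-length strings (byte comparison).
hammingMatches <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra == rb)
}

# Blast-like bit score and E-value for an ungapped nucleotide alignment
# under blastn-style +2/-3 scoring (Karlin-Altschul, lambda = 0.625,
# K = 0.41). Only used to populate standard tabular-hit columns; linkage
# thresholds on >= 2.5 kb hits are insensitive to the constants.
kaStats <- function(matches, mismatches, lenA, lenB) {
  score <- 2 * matches - 3 * mismatches
  bits <- (0.625 * score - log(0.41)) / log(2)
  evalue <- as.numeric(lenA) * as.numeric(lenB) * 2^(-bits)
  list(bits = bits, evalue = evalue)
}
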