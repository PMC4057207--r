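# internal helpers shared across modules

# Run code with a temporary RNG state seeded from `seed`; restores the caller's
# stream afterwards so library simulation never perturbs user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a deterministic 32-bit sub-seed from a master seed and a stream index.
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 131071 + as.numeric(stream) * 7919 + 17) %%
               2147483647)
}

#' Reverse complement of character sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] returning
#' plain character vectors, the sequence representation used throughout the
#' simulator and mapper.
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "TTTA"))
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_chars <- function(x) chartr("ACGT", "TGCA", x)

stop_config <- function(...) stop(..., call. = FALSE)
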