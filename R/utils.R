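#' @importFrom rlang %||% abort warn inform
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# All stochastic operations in the package route through this so that a
# user-visible `seed` argument never clobbers the session RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

# Uniform random DNA string of length `n` (no N's).
random_dna <- function(n) {
  stringi::stri_join(DNA_BASES[sample.int(4L, n, replace = TRUE)], collapse = "")
}

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over the alphabet A/C/G/T/N (case-sensitive,
#' upper case).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse-complemented sequences.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAN"))
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

# Canonical group levels used throughout: bacteria-first ordering mirrors the
# dominant-to-rare composition of a fecal metagenome.
GROUP_LEVELS <- c("bacteria", "virus", "eukaryote")

check_groups <- function(groups, arg = "group") {
  bad <- setdiff(unique(groups), GROUP_LEVELS)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Unknown %s value(s): %s. Expected one of: %s.",
      arg, paste(bad, collapse = ", "), paste(GROUP_LEVELS, collapse = ", ")
    ))
  }
  invisible(groups)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == trunc(x)
}
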