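#' @importFrom stats rnbinom setNames
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package funnel through this so a seed argument fully determines output.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Random DNA sequences
#'
#' Draws `n` uniform random sequences over A/C/G/T.
#'
#' @param n number of sequences.
#' @param len length of each sequence (nt); recycled against `n`.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return character vector of length `n`.
#' @export
random_dna <- function(n, len, seed = NULL) {
  len <- rep_len(as.integer(len), n)
  with_seed(seed, {
    vapply(len, function(l) {
      paste(sample(DNA_BASES, l, replace = TRUE), collapse = "")
    }, character(1))
  })
}

assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T%s}: e.g. '%s'",
                 what, if (allow_n) ",N" else "", x[which(bad)[1]]),
         call. = FALSE)
  }
  invisible(x)
}

#' Hamming distance between equal-length strings
#'
#' Vectorised over `a` and `b` (recycled to a common length).
#'
#' @param a,b character vectors of equal-length strings.
#' @return integer vector of substitution counts.
#' @export
hamming <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    stop("hamming() requires equal-length strings", call. = FALSE)
  }
  mapply(function(x, y) {
    sum(utf8ToInt(x) != utf8ToInt(y))
  }, a, b, USE.NAMES = FALSE)
}

#' Reverse complement
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Apply iid substitution errors at rate `rate` to each sequence. The
# replacement base is drawn from the three non-identical bases.
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) {
      ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Substitute exactly `k` positions of `s` (chosen uniformly) with a
# different base; used to inject bounded-mismatch artifact patterns.
mutate_k <- function(s, k) {
  if (k == 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), k)
  for (i in pos) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
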