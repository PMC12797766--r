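# Barcoded-TSO design: Levenshtein-constrained barcode selection from a 10X
# whitelist and assembly of the full template-switching oligo.

#' TSO segment design
#'
#' Describes the segment structure of the barcoded, 10X-compatible TSO:
#' 5' block (biotin), read-1 PCR handle, 16-nt well-specific barcode,
#' 9-nt UMI, the 10X `TTTCTTATAT` spacer, and three riboguanines (stored as
#' `GGG` in the DNA alphabet; downstream sequence logic is base-identity
#' only).
#'
#' The 9-nt UMI (one base shorter than the stock 10X design) keeps the full
#' oligo at 60 nt, the standard synthesis limit; read-1 parsing treats the
#' 26th base as the first, constant spacer base.
#'
#' @param handle read-1 PCR handle sequence.
#' @param barcode_len well barcode length (nt).
#' @param umi_len UMI length (nt).
#' @param spacer constant spacer sequence.
#' @param tail riboguanine tail, DNA alphabet.
#' @param blocked_5p logical; record a 5' biotin block on assembled oligos.
#' @return object of class `tso_design`.
#' @examples
#' d <- tso_design()
#' assemble_tso("AAAGTAGTCAAGCCTA", d)
#' @export
tso_design <- function(handle = "CTACACGACGCTCTTCCGATCT",
                       barcode_len = 16L,
                       umi_len = 9L,
                       spacer = "TTTCTTATAT",
                       tail = "GGG",
                       blocked_5p = TRUE) {
  assert_dna(c(handle, spacer, tail), "TSO segment")
  stopifnot(barcode_len >= 1, umi_len >= 1, nchar(tail) >= 1)
  structure(list(handle = handle, barcode_len = as.integer(barcode_len),
                 umi_len = as.integer(umi_len), spacer = spacer, tail = tail,
                 blocked_5p = isTRUE(blocked_5p)),
            class = "tso_design")
}

#' @export
print.tso_design <- function(x, ...) {
  cat("TSO design:",
      if (x$blocked_5p) "[5'-biotin]" else "[unblocked]",
      sprintf("%s + barcode(%d) + UMI(%d) + %s + r(%s)",
              x$handle, x$barcode_len, x$umi_len, x$spacer, x$tail), "\n")
  invisible(x)
}

#' Levenshtein (edit) distance
#'
#' Standard unit-cost edit distance (substitution, insertion, deletion)
#' between two strings, by dynamic programming. Empty strings are allowed.
#'
#' @param a,b strings over A/C/G/T/N (any characters are in fact accepted;
#'   costs are identity-based).
#' @return integer edit distance.
#' @examples
#' levenshtein("ACGT", "ACGT")  # 0
#' levenshtein("ACGT", "")     # 4
#' @export
levenshtein <- function(a, b) {
  s <- utf8ToInt(a); t <- utf8ToInt(b)
  n <- length(s); m <- length(t)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    cost <- as.integer(s[i] != t)
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost[j])
    }
    prev <- cur
  }
  as.integer(prev[m + 1L])
}

#' Pairwise Levenshtein distance matrix
#'
#' @param x character vector of sequences.
#' @return symmetric integer matrix of pairwise edit distances.
#' @export
levenshtein_matrix <- function(x) {
  n <- length(x)
  d <- matrix(0L, n, n, dimnames = list(x, x))
  if (n < 2) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- levenshtein(x[i], x[j])
    }
  }
  d
}

is_compatible <- function(candidate, accepted, d_min) {
  all(vapply(accepted, function(b) levenshtein(candidate, b) >= d_min,
             logical(1)))
}

#' Select well-specific barcodes under a pairwise edit-distance constraint
#'
#' Picks `n` barcodes from a whitelist so that every pair differs by a
#' Levenshtein distance of at least `d_min` (the published design uses
#' n = 24, d_min = 5 against the 10X whitelist). The default `"greedy"`
#' policy scans the whitelist in order and accepts a candidate iff it is at
#' distance >= `d_min` from every barcode accepted so far: deterministic,
#' and it reproduces any already-valid published set when that set is given
#' as (the head of) the whitelist. The `"exhaustive"` policy enumerates
#' subsets (toy whitelists only, <= 16 entries) and returns the first
#' size-`n` subset in whitelist order satisfying the constraint.
#'
#' @param whitelist character vector of equal-length barcodes (no N).
#' @param n number of barcodes to select.
#' @param d_min minimum pairwise Levenshtein distance.
#' @param policy `"greedy"` (default) or `"exhaustive"`.
#' @return object of class `barcode_set`: list with `barcodes` and `d_min`.
#'   On infeasibility an error of class `pb10x_infeasible` is signalled whose
#'   `barcodes` field carries the largest set found.
#' @export
select_barcodes <- function(whitelist, n, d_min,
                            policy = c("greedy", "exhaustive")) {
  policy <- match.arg(policy)
  stopifnot(n >= 1, d_min >= 0)
  assert_dna(whitelist, "whitelist barcode", allow_n = FALSE)
  if (length(unique(nchar(whitelist))) != 1) {
    stop("whitelist barcodes must all have the same length", call. = FALSE)
  }
  whitelist <- whitelist[!duplicated(whitelist)]

  best <- character(0)
  if (policy == "greedy") {
    accepted <- character(0)
    for (w in whitelist) {
      if (is_compatible(w, accepted, d_min)) {
        accepted <- c(accepted, w)
        if (length(accepted) == n) break
      }
    }
    best <- accepted
  } else {
    if (length(whitelist) > 16) {
      stop("exhaustive policy is limited to whitelists of <= 16 barcodes",
           call. = FALSE)
    }
    for (k in seq(min(n, length(whitelist)), 1L)) {
      combs <- utils::combn(seq_along(whitelist), k)
      found <- FALSE
      for (ci in seq_len(ncol(combs))) {
        cand <- whitelist[combs[, ci]]
        d <- levenshtein_matrix(cand)
        if (all(d[upper.tri(d)] >= d_min)) {
          best <- cand; found <- TRUE; break
        }
      }
      if (found) break
    }
  }

  if (length(best) < n) {
    cond <- structure(
      class = c("pb10x_infeasible", "error", "condition"),
      list(message = sprintf(
             "no set of %d barcodes at pairwise Levenshtein >= %d found by %s policy; largest set found has %d",
             n, d_min, policy, length(best)),
           call = sys.call(-1), barcodes = best))
    stop(cond)
  }
  structure(list(barcodes = best, d_min = as.integer(d_min)),
            class = "barcode_set")
}

#' @export
print.barcode_set <- function(x, ...) {
  cat(sprintf("barcode_set: %d barcodes, pairwise Levenshtein >= %d\n",
              length(x$barcodes), x$d_min))
  invisible(x)
}

#' Assemble a barcoded TSO oligo
#'
#' Concatenates handle + barcode + N-run (UMI placeholder) + spacer +
#' riboguanine tail; for the default design this is the 60-nt oligo
#' ordered from synthesis, with the UMI positions left as N.
#'
#' @param barcode well barcode, length `design$barcode_len`.
#' @param design a [tso_design()].
#' @param name oligo name.
#' @return list of class `oligo` with `name`, `sequence`, `modifications`.
#' @export
assemble_tso <- function(barcode, design = tso_design(),
                         name = paste0("TSO_", barcode)) {
  assert_dna(barcode, "barcode")
  if (nchar(barcode) != design$barcode_len) {
    stop(sprintf("barcode must be %d nt, got %d", design$barcode_len,
                 nchar(barcode)), call. = FALSE)
  }
  seq <- paste0(design$handle, barcode, strrep("N", design$umi_len),
                design$spacer, design$tail)
  mods <- c(if (design$blocked_5p) "5' biotin",
            sprintf("3' riboguanines (r%s)",
                    paste(strsplit(design$tail, "")[[1]], collapse = "r")))
  structure(list(name = name, sequence = seq, modifications = mods),
            class = "oligo")
}

#' Write an oligo order sheet
#'
#' Writes a TSV (name, sequence, modifications) and a FASTA mirror with the
#' oligo name as record id.
#'
#' @param oligos list of `oligo` objects (from [assemble_tso()]).
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.fasta`.
#' @return named character vector of the two paths, invisibly.
#' @export
write_order_sheet <- function(oligos, prefix) {
  if (length(oligos) == 0) stop("no oligos to write", call. = FALSE)
  tab <- data.frame(
    name = vapply(oligos, `[[`, character(1), "name"),
    sequence = vapply(oligos, `[[`, character(1), "sequence"),
    modifications = vapply(oligos, function(o)
      paste(o$modifications, collapse = "; "), character(1)))
  tsv <- paste0(prefix, ".tsv")
  fa <- paste0(prefix, ".fasta")
  write_tsv(tab, tsv)
  ss <- Biostrings::DNAStringSet(tab$sequence)
  names(ss) <- tab$name
  Biostrings::writeXStringSet(ss, fa)
  invisible(c(tsv = tsv, fasta = fa))
}
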