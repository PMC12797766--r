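# Artifact QC: TSO-concatemer detection via junction literals, 5' UMI-read
# extraction, deduplication, and strand-invasion quantification by fuzzy
# matching of the UMI-spacer-GGG pattern against the upstream reference
# context.

CONCATEMER_LITERALS <- c("ATATGGGCTAC", "GTAGCCCATAT")
UMI_READ_LITERAL <- "ATTGCGCAATG"

#' Per-method strand-invasion configuration
#'
#' Presets for the three protocols compared: `ss3x` extracts a 10-nt UMI of
#' which the final two bases are reassigned as the variable WW spacer;
#' `pb10x` a 9-nt UMI with the constant `TTTCTTATAT` spacer; `tenx` a 10-nt
#' UMI with the same spacer. All share a 23-nt upstream window and up to 3
#' mismatches.
#'
#' @param name one of `"pb10x"`, `"ss3x"`, `"tenx"`.
#' @return object of class `method_config` with fields `name`, `umi_len`,
#'   `spacer` (`NA` for the variable SS3X WW spacer), `window`,
#'   `max_mismatch`.
#' @export
method_config <- function(name = c("pb10x", "ss3x", "tenx")) {
  name <- match.arg(name)
  cfg <- switch(name,
    pb10x = list(umi_len = 9L, spacer = "TTTCTTATAT"),
    ss3x  = list(umi_len = 10L, spacer = NA_character_),
    tenx  = list(umi_len = 10L, spacer = "TTTCTTATAT"))
  structure(c(list(name = name), cfg,
              list(window = 23L, max_mismatch = 3L, tail = "GGG")),
            class = "method_config")
}

#' Detect TSO concatemer reads via junction literals
#'
#' A read is flagged iff any literal occurs as an exact substring. No
#' reverse complementing is performed beyond the literals supplied (the
#' default lists the junction motif and its reverse complement explicitly,
#' mirroring a bbduk call with `rcomp=f` and both orientations given,
#' `k = 11`, no mismatches).
#'
#' @param reads character vector of R2 sequences.
#' @param literals junction k-mers to search for.
#' @param k literal length; every literal must have length `k`.
#' @return list with `flags` (logical per read) and `fraction`
#'   (flagged/total).
#' @export
detect_concatemers <- function(reads, literals = CONCATEMER_LITERALS,
                               k = 11L) {
  stopifnot(k >= 1)
  if (any(nchar(literals) != k)) {
    stop("every literal must have length k", call. = FALSE)
  }
  flags <- rep(FALSE, length(reads))
  for (lit in literals) {
    flags <- flags | grepl(lit, reads, fixed = TRUE)
  }
  list(flags = flags,
       fraction = if (length(reads)) mean(flags) else NA_real_)
}

#' Extract 5' UMI-reads by fuzzy literal match on read 1
#'
#' Keeps reads whose R1 contains a substring within Hamming distance
#' `hdist` of the literal (default: the SS3X 5' tag `ATTGCGCAATG` at
#' `hdist = 1`, as used to pull UMI-bearing reads out of mixed 5'/internal
#' libraries).
#'
#' @param r1 character vector of R1 sequences.
#' @param literal tag sequence to search for.
#' @param hdist maximum Hamming distance per window.
#' @return logical vector, `TRUE` for reads to keep.
#' @export
extract_5p_umi_reads <- function(r1, literal = UMI_READ_LITERAL, hdist = 1L) {
  stopifnot(hdist >= 0)
  p <- nchar(literal)
  pat <- utf8ToInt(literal)
  keep <- rep(FALSE, length(r1))
  lens <- nchar(r1)
  max_off <- max(lens) - p + 1L
  if (max_off < 1L) return(keep)
  for (off in seq_len(max_off)) {
    idx <- which(!keep & lens >= off + p - 1L)
    if (!length(idx)) next
    mism <- integer(length(idx))
    for (j in seq_len(p)) {
      mism <- mism + (substr(r1[idx], off + j - 1L, off + j - 1L) !=
                        intToUtf8(pat[j]))
    }
    keep[idx[mism <= hdist]] <- TRUE
  }
  keep
}

#' Deduplicate 5' UMI-reads
#'
#' One record is retained per (cell_id, umi, ref, start, strand) key; the
#' first occurrence wins.
#'
#' @param tags data.frame with columns `cell_id`, `umi`, `ref`, `start`,
#'   `strand`.
#' @return the deduplicated data.frame.
#' @export
dedup_5p_reads <- function(tags) {
  key <- paste(tags$cell_id, tags$umi, tags$ref, tags$start, tags$strand,
               sep = "\r")
  tags[!duplicated(key), , drop = FALSE]
}

#' Build the UMI-spacer-GGG query pattern for a record
#'
#' For constant-spacer methods the pattern is umi + spacer + GGG. For SS3X
#' the extracted 10-mer already contains the observed WW spacer: the first
#' 8 bases are the UMI proper and the final 2 the spacer, so the pattern is
#' simply the 10-mer + GGG.
#'
#' @param umi character vector of extracted UMIs (length `config$umi_len`).
#' @param config a [method_config()].
#' @return character vector of patterns.
#' @export
invasion_pattern <- function(umi, config) {
  if (any(nchar(umi) != config$umi_len)) {
    stop(sprintf("UMI length must be %d for method %s", config$umi_len,
                 config$name), call. = FALSE)
  }
  if (is.na(config$spacer)) {
    # SS3X: positional split 8 + 2 (WW), both already observed in the UMI
    paste0(substr(umi, 1, 8), substr(umi, 9, 10), config$tail)
  } else {
    paste0(umi, config$spacer, config$tail)
  }
}

#' Extract upstream reference context for aligned reads
#'
#' For plus-strand alignments the context is the `window` reference bases
#' immediately 5' of the (0-based) alignment start; for minus-strand
#' alignments, the bases immediately 3' of the alignment end,
#' reverse-complemented, so "upstream" is always in read orientation.
#' Contexts are truncated at contig boundaries.
#'
#' @param tags data.frame with `ref`, `start`, `end`, `strand`.
#' @param reference named character vector of contig sequences, a
#'   `toy_transcriptome`, or a FASTA path.
#' @param window context length (nt).
#' @return `tags` with an added `upstream` column.
#' @export
upstream_context <- function(tags, reference, window = 23L) {
  if (inherits(reference, "toy_transcriptome")) reference <- reference$seqs
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    ss <- Biostrings::readDNAStringSet(reference)
    reference <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  missing <- setdiff(unique(tags$ref), names(reference))
  if (length(missing)) {
    stop("reference is missing contigs: ", paste(head(missing, 3),
         collapse = ", "), call. = FALSE)
  }
  n <- nrow(tags)
  ctx <- character(n)
  for (i in seq_len(n)) {
    s <- reference[[tags$ref[i]]]
    if (tags$strand[i] == "-") {
      from <- tags$end[i] + 1L               # 1-based, right of the end
      to <- min(nchar(s), tags$end[i] + window)
      ctx[i] <- if (from > to) "" else revcomp(substr(s, from, to))
    } else {
      to <- tags$start[i]                    # 1-based position of last upstream base
      from <- max(1L, tags$start[i] - window + 1L)
      ctx[i] <- if (to < 1L) "" else substr(s, from, to)
    }
  }
  tags$upstream <- ctx
  tags
}

#' Flag strand-invasion reads by fuzzy pattern-in-window matching
#'
#' A record is flagged iff its UMI-spacer-GGG pattern occurs within the
#' upstream window with at most `config$max_mismatch` mismatches.
#' `mode = "hamming"` (default) tries every anchored offset at which the
#' full pattern fits in the window and counts substitutions only;
#' `mode = "edit"` takes the minimum Levenshtein distance of the pattern
#' against every window substring (agrep semantics, indels allowed).
#' Windows shorter than the pattern (contig edges) are never flagged but
#' stay in the denominator.
#'
#' @param umi character vector of UMIs.
#' @param upstream character vector of upstream windows (same length).
#' @param config a [method_config()].
#' @param mode `"hamming"` or `"edit"`.
#' @return data.frame with `flag` (logical) and `best_mismatches` (integer,
#'   `NA` when not flagged).
#' @export
flag_strand_invasion <- function(umi, upstream, config,
                                 mode = c("hamming", "edit")) {
  mode <- match.arg(mode)
  pattern <- invasion_pattern(umi, config)
  n <- length(pattern)
  stopifnot(length(upstream) == n)
  flag <- logical(n)
  best <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    b <- best_pattern_mismatches(pattern[i], upstream[i], mode)
    if (!is.na(b) && b <= config$max_mismatch) {
      flag[i] <- TRUE
      best[i] <- b
    }
  }
  data.frame(flag = flag, best_mismatches = best)
}

# Minimum mismatch load of `pattern` anywhere in `window`; NA when the
# window is shorter than the pattern (hamming mode) or empty.
best_pattern_mismatches <- function(pattern, window, mode = "hamming") {
  p <- nchar(pattern)
  w <- nchar(window)
  if (w == 0L) return(NA_integer_)
  if (mode == "hamming") {
    if (w < p) return(NA_integer_)
    vals <- vapply(0:(w - p), function(off) {
      hamming(pattern, substr(window, off + 1L, off + p))
    }, integer(1))
    min(vals)
  } else {
    # best edit distance of pattern against any substring of the window
    best <- Inf
    for (a in seq_len(w)) {
      for (b in a:w) {
        best <- min(best, levenshtein(pattern, substr(window, a, b)))
      }
    }
    as.integer(best)
  }
}

#' Strand-invasion report
#'
#' Deduplicates the records (per (cell, UMI, ref, start, strand)), extracts
#' upstream context when absent, scores every deduplicated read with
#' [flag_strand_invasion()], and reports the percentage flagged together
#' with the histogram of best mismatch counts (0..max_mismatch).
#'
#' @param tags aligned-read tag table (`cell_id`, `umi`, `ref`, `start`,
#'   `end`, `strand`, optionally `upstream`).
#' @param reference reference sequences (see [upstream_context()]); ignored
#'   when `tags` already has an `upstream` column.
#' @param config a [method_config()].
#' @param mode mismatch semantics, see [flag_strand_invasion()].
#' @return object of class `invasion_report`: list with `n_dedup_reads`,
#'   `n_flagged`, `percent_flagged`, `mismatch_histogram`.
#' @export
strand_invasion_report <- function(tags, reference = NULL,
                                   config = method_config("pb10x"),
                                   mode = c("hamming", "edit")) {
  mode <- match.arg(mode)
  if (nrow(tags) == 0) stop("no records to score", call. = FALSE)
  tags <- dedup_5p_reads(tags)
  if (is.null(tags$upstream)) {
    if (is.null(reference)) {
      stop("either an `upstream` column or a reference is required",
           call. = FALSE)
    }
    tags <- upstream_context(tags, reference, config$window)
  }
  res <- flag_strand_invasion(tags$umi, tags$upstream, config, mode)
  hist <- table(factor(res$best_mismatches[res$flag],
                       levels = 0:config$max_mismatch))
  structure(list(n_dedup_reads = nrow(tags),
                 n_flagged = sum(res$flag),
                 percent_flagged = 100 * sum(res$flag) / nrow(tags),
                 mismatch_histogram = setNames(as.integer(hist),
                                               names(hist)),
                 method = config$name, mode = mode),
            class = "invasion_report")
}

#' @export
print.invasion_report <- function(x, ...) {
  cat(sprintf(
    "strand invasion [%s, %s]: %d/%d deduplicated 5' UMI-reads flagged (%.2f%%)\n",
    x$method, x$mode, x$n_flagged, x$n_dedup_reads, x$percent_flagged))
  cat("  mismatch histogram:",
      paste(sprintf("%s:%d", names(x$mismatch_histogram),
                    x$mismatch_histogram), collapse = "  "), "\n")
  invisible(x)
}
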