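# Read-1 demultiplexing: positional parsing, Hamming-1 whitelist
# correction, pool assignment, and per-cell read counting.

#' Parse read 1 into barcode / UMI / spacer base
#'
#' R1 is sliced positionally: bases [1,16] barcode, [17,25] UMI, base 26 the
#' first (constant) spacer base. Cell Ranger reads that 26th base as part of
#' a 10-nt UMI; since it is constant this does not affect compatibility, and
#' here it is kept separate for validation.
#'
#' @param seq character vector of R1 sequences (>= 26 nt each).
#' @param design a [tso_design()].
#' @return data.frame with `barcode_raw`, `umi`, `spacer_base`.
#' @export
parse_read1 <- function(seq, design = tso_design()) {
  need <- design$barcode_len + design$umi_len + 1L
  if (any(nchar(seq) < need)) {
    stop(sprintf("read 1 shorter than %d nt", need), call. = FALSE)
  }
  b <- design$barcode_len
  u <- design$umi_len
  data.frame(barcode_raw = substr(seq, 1L, b),
             umi = substr(seq, b + 1L, b + u),
             spacer_base = substr(seq, b + u + 1L, b + u + 1L),
             stringsAsFactors = FALSE)
}

#' Correct barcodes against a whitelist
#'
#' Returns, per raw barcode, the unique whitelist barcode within Hamming
#' distance `max_mismatch`, or `NA` when there is none or the match is
#' ambiguous (two or more whitelist barcodes at the minimal distance within
#' the threshold). Exact matches always win. This mirrors standard 10X
#' unique-match-or-drop behaviour.
#'
#' @param raw character vector of observed barcodes.
#' @param whitelist character vector or `barcode_set`.
#' @param max_mismatch maximum Hamming distance (default 1).
#' @return character vector, corrected barcode or `NA` per input.
#' @export
correct_barcode <- function(raw, whitelist, max_mismatch = 1L) {
  if (inherits(whitelist, "barcode_set")) whitelist <- whitelist$barcodes
  stopifnot(max_mismatch >= 0)
  out <- rep(NA_character_, length(raw))
  exact <- match(raw, whitelist)
  out[!is.na(exact)] <- whitelist[exact[!is.na(exact)]]
  todo <- which(is.na(out))
  if (length(todo) && max_mismatch > 0) {
    d <- vapply(whitelist, function(w) hamming(raw[todo], w),
                integer(length(todo)))
    d <- matrix(d, nrow = length(todo))
    for (k in seq_along(todo)) {
      dk <- d[k, ]
      m <- min(dk)
      if (m <= max_mismatch && sum(dk == m) == 1L) {
        out[todo[k]] <- whitelist[which.min(dk)]
      }
    }
  }
  out
}

#' Group barcoded wells into pools
#'
#' Consecutive groups of `pool_size` wells share a pool; the pool count is
#' `ceiling(n / pool_size)` (96 wells at pool size 24 give 4 pools). A
#' barcode occurring twice within one pool is an error, since cells within a
#' pool are only distinguishable by barcode.
#'
#' @param wells data.frame with columns `well`, `cell_id`, `barcode`, in
#'   plate order.
#' @param pool_size wells per pool (>= 1).
#' @return object of class `plate_layout`: list with `wells` (plus
#'   `pool_id`), `pool_size`, and `pools` (pool_id -> well names).
#' @export
assign_pools <- function(wells, pool_size) {
  stopifnot(pool_size >= 1, nrow(wells) >= 1)
  pool_id <- sprintf("pool%d", ((seq_len(nrow(wells)) - 1L) %/% pool_size) + 1L)
  wells$pool_id <- pool_id
  dup <- unlist(lapply(split(wells$barcode, pool_id), duplicated))
  if (any(dup)) {
    stop("duplicate barcode within a pool", call. = FALSE)
  }
  structure(list(wells = wells, pool_size = as.integer(pool_size),
                 pools = split(wells$well, pool_id)),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("plate_layout: %d wells in %d pool(s) of size %d\n",
              nrow(x$wells), length(x$pools), x$pool_size))
  invisible(x)
}

#' Demultiplex R1 reads against a plate layout
#'
#' Parses R1, corrects barcodes against the layout's barcodes, and assigns
#' each read to the cell carrying the corrected barcode (single-pool
#' layouts; pools are sequenced as separate libraries). The 26th base is
#' validated against the constant first spacer base with a warn-only
#' policy: mismatches are counted and reported, reads are kept.
#'
#' @param r1 character vector of R1 sequences, or a data.frame from
#'   [read_fastq()].
#' @param layout a single-pool `plate_layout`.
#' @param design a [tso_design()].
#' @param max_mismatch barcode correction radius (default 1).
#' @param read_id optional read ids (default from `r1` or generated).
#' @return data.frame tag table: `read_id`, `cell_id`, `umi`, `pool_id`,
#'   `status` (`"assigned"`/`"unassigned"`), with the spacer-base mismatch
#'   count in attribute `spacer_mismatches`.
#' @export
demux_read1 <- function(r1, layout, design = tso_design(),
                        max_mismatch = 1L, read_id = NULL) {
  if (is.data.frame(r1)) {
    if (is.null(read_id)) read_id <- r1$read_id
    r1 <- r1$seq
  }
  if (is.null(read_id)) read_id <- sprintf("read%07d", seq_along(r1))
  wells <- layout$wells
  if (length(unique(wells$pool_id)) > 1) {
    stop("demux_read1() expects a single-pool layout", call. = FALSE)
  }
  parsed <- parse_read1(r1, design)
  corrected <- correct_barcode(parsed$barcode_raw, wells$barcode, max_mismatch)
  idx <- match(corrected, wells$barcode)
  n_spacer_bad <- sum(parsed$spacer_base != substr(design$spacer, 1, 1))
  if (n_spacer_bad > 0) {
    warning(sprintf("%d read(s) with unexpected 26th (spacer) base; kept",
                    n_spacer_bad), call. = FALSE)
  }
  out <- data.frame(read_id = read_id,
                    cell_id = ifelse(is.na(idx), NA, wells$cell_id[idx]),
                    umi = parsed$umi,
                    pool_id = ifelse(is.na(idx), NA, wells$pool_id[idx]),
                    status = ifelse(is.na(idx), "unassigned", "assigned"),
                    stringsAsFactors = FALSE)
  attr(out, "spacer_mismatches") <- n_spacer_bad
  out
}

#' Count reads per cell
#'
#' @param tags a demultiplexed tag table (from [demux_read1()]) with
#'   `cell_id` and `status` columns, or any table with a `cell_id` column
#'   (rows with `NA` cell are counted as unassigned).
#' @return list with `per_cell` (data.frame cell_id / reads, all cells with
#'   >= 1 assigned read) and `unassigned` (integer).
#' @export
reads_per_cell <- function(tags) {
  assigned <- !is.na(tags$cell_id)
  if ("status" %in% names(tags)) assigned <- assigned & tags$status == "assigned"
  counts <- table(tags$cell_id[assigned])
  list(per_cell = data.frame(cell_id = names(counts),
                             reads = as.integer(counts),
                             stringsAsFactors = FALSE),
       unassigned = sum(!assigned))
}
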