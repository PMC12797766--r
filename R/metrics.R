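# Benchmarking statistics: seeded subsampling, sequencing saturation and
# saturation curves, dropout ratios, per-cell QC, and paired-TCR recovery
# from AIRR tables.

#' Seeded subsampling without replacement
#'
#' Uniform sample of `n_target` elements, deterministic under `seed`.
#' Operates on read ids (or row indices) so paired files stay synchronized:
#' apply the returned subset to both mates.
#'
#' @param ids vector of read ids (or any elements).
#' @param n_target sample size, `0 <= n_target <= length(ids)`.
#' @param seed integer seed.
#' @return vector of sampled elements (original order not preserved).
#' @export
subsample_reads <- function(ids, n_target, seed = 100) {
  if (n_target > length(ids)) {
    stop("n_target exceeds the number of reads", call. = FALSE)
  }
  if (n_target == length(ids)) return(ids)
  if (n_target == 0) return(ids[0])
  with_seed(seed, sample(ids, n_target))
}

#' Sequencing saturation
#'
#' 1 minus the ratio of unique counts to total reads. "Unique counts" are
#' distinct (cell, gene, UMI) triples among gene-assigned reads.
#'
#' @param total_reads total read count (> 0).
#' @param unique_counts number of unique molecules (0..total_reads).
#' @return saturation in [0, 1].
#' @export
saturation <- function(total_reads, unique_counts) {
  if (total_reads <= 0) stop("total_reads must be positive", call. = FALSE)
  if (unique_counts < 0 || unique_counts > total_reads) {
    stop("unique_counts must lie in [0, total_reads]", call. = FALSE)
  }
  1 - unique_counts / total_reads
}

#' Saturation curve over a depth grid
#'
#' For each target depth (reads per cell), subsamples the tagged reads
#' globally to `depth * n_cells` reads (matching per-cell targets
#' multiplied by the number of observed cells), deduplicates by
#' (cell, gene, UMI), and reports mean genes/cell, mean UMIs/cell, and
#' saturation. Depths exceeding the available reads are dropped with a
#' warning. Each grid point is an independent draw under the same seed, as
#' with repeated `seqtk sample -s`.
#'
#' @param tags data.frame of gene-assigned reads with columns `cell_id`,
#'   `gene` (or `ref`), `umi`.
#' @param depth_grid ascending integer vector of target reads/cell.
#' @param seed integer seed.
#' @return data.frame with `depth`, `mean_genes`, `mean_umis`,
#'   `saturation`.
#' @export
saturation_curve <- function(tags, depth_grid, seed = 100) {
  if (is.null(tags$gene)) tags$gene <- tags$ref
  stopifnot(!is.null(tags$cell_id), !is.null(tags$umi))
  if (is.unsorted(depth_grid)) {
    stop("depth_grid must be sorted ascending", call. = FALSE)
  }
  n_cells <- length(unique(tags$cell_id))
  n_avail <- nrow(tags)
  keep <- depth_grid * n_cells <= n_avail
  if (!all(keep)) {
    warning(sprintf("dropping %d depth(s) exceeding the %d available reads",
                    sum(!keep), n_avail), call. = FALSE)
    depth_grid <- depth_grid[keep]
  }
  rows <- lapply(depth_grid, function(d) {
    n <- d * n_cells
    idx <- subsample_reads(seq_len(n_avail), n, seed)
    sub <- tags[idx, c("cell_id", "gene", "umi")]
    triple <- unique(sub)
    pair <- unique(triple[, c("cell_id", "gene")])
    data.frame(depth = d,
               mean_genes = nrow(pair) / n_cells,
               mean_umis = nrow(triple) / n_cells,
               saturation = saturation(n, nrow(triple)))
  })
  do.call(rbind, rows)
}

#' Per-gene dropout ratio
#'
#' Fraction of cells with zero counts for each gene; 1 means the gene was
#' detected in no cell.
#'
#' @param mat genes x cells count matrix (>= 1 cell).
#' @return data.frame with `gene_id` and `dropout`.
#' @export
dropout_ratio <- function(mat) {
  if (is.null(dim(mat)) || ncol(mat) < 1 || nrow(mat) < 1) {
    stop("need a genes x cells matrix with >= 1 cell", call. = FALSE)
  }
  data.frame(gene_id = rownames(mat),
             dropout = rowMeans(mat == 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-cell QC summary
#'
#' Genes detected (count > 0), total UMIs, and percent mitochondrial per
#' cell; percent mito is `NA` for all-zero cells.
#'
#' @param mat genes x cells count matrix.
#' @param is_mito logical per gene; defaults to the matrix's `is_mito`
#'   attribute, else an `MT` prefix on the rownames.
#' @return data.frame with `cell_id`, `genes_detected`, `total_umis`,
#'   `percent_mito`.
#' @export
per_cell_qc <- function(mat, is_mito = NULL) {
  if (is.null(is_mito)) is_mito <- attr(mat, "is_mito")
  if (is.null(is_mito)) is_mito <- grepl("^MT", rownames(mat))
  stopifnot(length(is_mito) == nrow(mat))
  total <- colSums(mat)
  mito <- colSums(mat[is_mito, , drop = FALSE])
  data.frame(cell_id = colnames(mat),
             genes_detected = as.integer(colSums(mat > 0)),
             total_umis = total,
             percent_mito = ifelse(total > 0, 100 * mito / total, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read an AIRR rearrangement table
#'
#' Tolerant reader for AIRR-format contig tables: boolean-ish columns
#' (`productive`, `complete_vdj`, `full_length`) accept `T`/`TRUE`/`True`
#' and logical values; `has_v`/`has_j`/`has_cdr3` are derived from
#' non-empty `v_call`/`j_call`/`junction_aa` when absent.
#'
#' @param path TSV path, or a data.frame to normalise in place.
#' @return data.frame with at least `cell_id`, `locus`, `productive`,
#'   `has_v`, `has_j`, `has_cdr3`.
#' @export
read_airr <- function(path) {
  tab <- if (is.data.frame(path)) path else read_tsv(path)
  as_bool <- function(x) {
    if (is.logical(x)) return(x)
    toupper(trimws(as.character(x))) %in% c("T", "TRUE")
  }
  for (col in c("productive", "complete_vdj", "full_length")) {
    if (col %in% names(tab)) tab[[col]] <- as_bool(tab[[col]])
  }
  nonempty <- function(x) !is.na(x) & nzchar(trimws(as.character(x)))
  if (is.null(tab$has_v)) {
    tab$has_v <- if (!is.null(tab$v_call)) nonempty(tab$v_call) else FALSE
  }
  if (is.null(tab$has_j)) {
    tab$has_j <- if (!is.null(tab$j_call)) nonempty(tab$j_call) else FALSE
  }
  if (is.null(tab$has_cdr3)) {
    tab$has_cdr3 <- if (!is.null(tab$junction_aa)) nonempty(tab$junction_aa)
                    else FALSE
  }
  tab
}

#' Paired-TCR recovery statistic
#'
#' A chain qualifies iff it is productive (no stop codon) with identified V
#' and J segments and a fully identified CDR3. Percentages are over the
#' full cell universe (cells without contigs count in the denominator);
#' cells with several qualifying chains of one locus count once. Values are
#' rounded half-up to 2 decimals.
#'
#' @param airr AIRR table (path or data.frame; see [read_airr()]).
#' @param cells character vector of all assayed cell ids (non-empty).
#' @return list with `pct_TRA`, `pct_TRB`, `pct_paired`, `n_cells`.
#' @export
tcr_recovery <- function(airr, cells) {
  if (length(cells) == 0) stop("empty cell universe", call. = FALSE)
  tab <- read_airr(airr)
  ok <- tab$productive & tab$has_v & tab$has_j & tab$has_cdr3
  tra_cells <- unique(tab$cell_id[ok & tab$locus == "TRA"])
  trb_cells <- unique(tab$cell_id[ok & tab$locus == "TRB"])
  pct <- function(x) round_half_up(100 * mean(cells %in% x), 2)
  list(pct_TRA = pct(tra_cells),
       pct_TRB = pct(trb_cells),
       pct_paired = pct(intersect(tra_cells, trb_cells)),
       n_cells = length(cells))
}
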