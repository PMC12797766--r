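# Synthetic-data generators: toy transcriptome, plate layout, per-cell
# expression, and paired FASTQ reads with the protocol read geometry plus
# injectable TSO-concatemer and strand-invasion artifacts. All generators
# are deterministic under their seed argument.

#' Generate a toy transcriptome
#'
#' Random-sequence transcripts with unique gene ids. A configurable fraction
#' of genes is flagged mitochondrial, and a configurable fraction of those
#' is drawn short (< 200 nt), mimicking the short, largely tRNA-derived
#' mitochondrial transcript class of real libraries. The reference is
#' transcript-per-contig: each gene id is its own sequence.
#'
#' @param n_genes number of transcripts (>= 1).
#' @param mito_fraction fraction of genes flagged mitochondrial (ids get an
#'   `MT` prefix).
#' @param length_range nt length range for ordinary transcripts (min >= 120).
#' @param mito_short_fraction probability that a mitochondrial transcript is
#'   drawn short, uniform on 60-199 nt.
#' @param seed integer seed.
#' @param dir optional directory; when given, `ref.fa` (FASTA) and `ref.gtf`
#'   (1-based GTF, one gene/exon per transcript) are written there.
#' @return object of class `toy_transcriptome`: list with `genes`
#'   (data.frame gene_id / is_mito / length) and `seqs` (named character).
#' @export
make_transcriptome <- function(n_genes, mito_fraction = 0.2,
                               length_range = c(500, 2000),
                               mito_short_fraction = 0.8,
                               seed = 1, dir = NULL) {
  stopifnot(n_genes >= 1, mito_fraction >= 0, mito_fraction <= 1)
  length_range <- as.integer(length_range)
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] < 120) {
    stop("length_range must be an increasing interval with min >= 120 nt",
         call. = FALSE)
  }
  n_mito <- round(n_genes * mito_fraction)
  with_seed(seed, {
    is_mito <- seq_len(n_genes) <= n_mito
    gene_id <- ifelse(is_mito,
                      sprintf("MT%04d", seq_len(n_genes)),
                      sprintf("GENE%04d", seq_len(n_genes)))
    len <- sample(length_range[1]:length_range[2], n_genes, replace = TRUE)
    short <- is_mito & stats::runif(n_genes) < mito_short_fraction
    len[short] <- sample(60:199, sum(short), replace = TRUE)
    seqs <- setNames(random_dna(n_genes, len), gene_id)
    tx <- structure(list(
      genes = data.frame(gene_id = gene_id, is_mito = is_mito, length = len,
                         stringsAsFactors = FALSE),
      seqs = seqs), class = "toy_transcriptome")
    if (!is.null(dir)) write_transcriptome(tx, dir)
    tx
  })
}

#' Write a toy transcriptome to FASTA + GTF
#'
#' @param tx a [make_transcriptome()] object.
#' @param dir output directory (created if absent).
#' @return paths of the two files, invisibly.
#' @export
write_transcriptome <- function(tx, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "ref.fa")
  gtf <- file.path(dir, "ref.gtf")
  ss <- Biostrings::DNAStringSet(tx$seqs)
  Biostrings::writeXStringSet(ss, fa)
  g <- tx$genes
  # 1-based inclusive coordinates per the GTF standard
  rows <- data.frame(
    seqname = rep(g$gene_id, each = 2),
    source = "pb10x_toy",
    feature = rep(c("gene", "exon"), nrow(g)),
    start = 1L,
    end = rep(g$length, each = 2),
    score = ".", strand = "+", frame = ".",
    attribute = rep(sprintf("gene_id \"%s\"; gene_name \"%s\";",
                            g$gene_id, g$gene_id), each = 2))
  con <- file(gtf, "wb")
  write.table(rows, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(c(fasta = fa, gtf = gtf))
}

#' Build a plate layout
#'
#' Wells are filled in order; each well holds one cell and one barcoded TSO.
#' Barcodes are recycled across pools (the same TSO set serves every pool),
#' and [assign_pools()] groups consecutive wells into pools of `pool_size`.
#'
#' @param barcodes character vector of well barcodes (a `barcode_set` is
#'   also accepted).
#' @param n_wells number of occupied wells.
#' @param pool_size wells per pool; defaults to the number of barcodes.
#' @return a `plate_layout` (see [assign_pools()]).
#' @export
make_layout <- function(barcodes, n_wells, pool_size = NULL) {
  if (inherits(barcodes, "barcode_set")) barcodes <- barcodes$barcodes
  if (is.null(pool_size)) pool_size <- length(barcodes)
  if (pool_size > length(barcodes)) {
    stop("pool_size exceeds the number of distinct barcodes", call. = FALSE)
  }
  wells <- data.frame(
    well = sprintf("W%03d", seq_len(n_wells)),
    cell_id = sprintf("cell%03d", seq_len(n_wells)),
    barcode = barcodes[((seq_len(n_wells) - 1L) %% pool_size) + 1L],
    stringsAsFactors = FALSE)
  assign_pools(wells, pool_size)
}

#' Simulate per-cell expression counts
#'
#' Gene x cell counts drawn independently from a negative binomial with
#' mean `mean` and size (inverse-dispersion) `size`; `size = Inf` gives the
#' Poisson limit and `mean = 0` an all-zero matrix.
#'
#' @param layout a `plate_layout`.
#' @param tx a `toy_transcriptome`.
#' @param mean NB mean per gene per cell.
#' @param size NB size parameter (variance = mean + mean^2/size).
#' @param seed integer seed.
#' @return object of class `expression_truth`: list with integer `counts`
#'   (genes x cells) and the sampling `params`.
#' @export
simulate_expression <- function(layout, tx, mean = 5, size = 2, seed = 1) {
  stopifnot(mean >= 0, size > 0)
  g <- nrow(tx$genes); c <- nrow(layout$wells)
  counts <- with_seed(seed, {
    if (mean == 0) {
      matrix(0L, g, c)
    } else if (is.infinite(size)) {
      matrix(stats::rpois(g * c, lambda = mean), g, c)
    } else {
      matrix(rnbinom(g * c, mu = mean, size = size), g, c)
    }
  })
  dimnames(counts) <- list(tx$genes$gene_id, layout$wells$cell_id)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 params = list(mean = mean, size = size, seed = seed)),
            class = "expression_truth")
}

# Non-overlapping strand-invasion slots on a transcriptome: internal start
# positions (0-based) with >= pat_len upstream bases and >= read_len bases
# ahead, spaced so written patterns never collide.
invasion_slots <- function(tx, pat_len = 22L, read_len = 90L) {
  step <- pat_len + read_len
  out <- list()
  for (i in seq_len(nrow(tx$genes))) {
    L <- tx$genes$length[i]
    if (L - read_len < pat_len) next
    starts <- seq(pat_len, L - read_len, by = step)
    if (length(starts)) {
      out[[length(out) + 1L]] <- data.frame(gene_id = tx$genes$gene_id[i],
                                            start = as.integer(starts))
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_id = character(0), start = integer(0)))
  }
  do.call(rbind, out)
}

#' Simulate paired reads with protocol geometry and injectable artifacts
#'
#' For every read, R1 (26 nt) is barcode(16) + fresh UMI(9) + the first
#' spacer base. R2 (90 nt) depends on the artifact class drawn per read:
#' \describe{
#'   \item{normal}{the 5'-proximal 90 nt of a transcript sampled in
#'     proportion to the cell's expression counts (A-padded for transcripts
#'     shorter than 90 nt, emulating read-through into the poly-A tail).
#'     The count matrix defines each cell's molecule pool: a gene with
#'     count k contributes k molecules, each carrying one UMI drawn once
#'     and reused by all its sequenced duplicates, so deduplication and
#'     sequencing saturation behave as in a real library.}
#'   \item{concatemer}{a 90-nt window of a tandem TSO concatemer, always
#'     covering a TSO-TSO junction so the read carries the
#'     `ATATGGGCTAC` junction motif.}
#'   \item{strand_invasion}{starts at an internal transcript position whose
#'     upstream 22-nt reference context is overwritten with the read's
#'     UMI + spacer + GGG pattern, mutated at 0-3 uniformly drawn positions;
#'     ground truth is therefore exact by construction. Slots are
#'     non-overlapping; an error is raised when the transcriptome cannot
#'     host the requested number of invasion reads.}
#' }
#' Uniform substitution errors at `error_rate` are applied to both mates
#' afterwards (never to the reference). Quality strings are constant Q30.
#'
#' The aligned-read tag table (`tags`) reflects perfect alignment truth for
#' normal and strand-invasion reads (concatemers are unmapped, as in real
#' data). Only single-pool layouts are accepted: the protocol sequences each
#' pool as its own library, and barcodes recur across pools.
#'
#' @param truth an `expression_truth`.
#' @param layout a single-pool `plate_layout`.
#' @param tx the `toy_transcriptome` the counts refer to.
#' @param design a [tso_design()].
#' @param depth_per_cell reads per cell (>= 1).
#' @param concatemer_rate,invasion_rate per-read artifact probabilities
#'   (sum <= 1).
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @param dir optional output directory: writes `R1.fastq.gz`,
#'   `R2.fastq.gz`, `truth.tsv`, `tags.tsv`, and the (possibly
#'   invasion-modified) reference `ref.fa`/`ref.gtf`.
#' @return list with `reads` (read_id, r1_seq, r1_qual, r2_seq, r2_qual),
#'   `truth` (read_id, cell_id, gene_id, umi, artifact_class, start,
#'   strand), `tags` (cell_id, umi, ref, start, end, strand for mapped
#'   reads), and `tx` (reference after pattern injection).
#' @export
simulate_reads <- function(truth, layout, tx, design = tso_design(),
                           depth_per_cell = 100,
                           concatemer_rate = 0, invasion_rate = 0,
                           error_rate = 0, seed = 1, dir = NULL) {
  stopifnot(depth_per_cell >= 1,
            concatemer_rate >= 0, invasion_rate >= 0, error_rate >= 0,
            concatemer_rate + invasion_rate <= 1)
  wells <- layout$wells
  if (nrow(wells) == 0) stop("empty layout", call. = FALSE)
  if (length(unique(wells$pool_id)) > 1) {
    stop("simulate_reads() expects a single-pool layout; simulate pools separately",
         call. = FALSE)
  }
  read_len <- 90L
  spacer1 <- substr(design$spacer, 1, 1)
  pat_len <- design$umi_len + nchar(design$spacer) + nchar(design$tail)

  with_seed(seed, {
    n_total <- nrow(wells) * depth_per_cell
    cls_lvl <- c("normal", "concatemer", "strand_invasion")
    cls <- sample(cls_lvl, n_total, replace = TRUE,
                  prob = c(1 - concatemer_rate - invasion_rate,
                           concatemer_rate, invasion_rate))
    cell_idx <- rep(seq_len(nrow(wells)), each = depth_per_cell)

    # per-cell molecule pools: each molecule = (gene, UMI); sequencing a
    # molecule twice reuses its UMI
    mol_gene <- vector("list", nrow(wells))
    mol_umi <- vector("list", nrow(wells))
    for (ci in seq_len(nrow(wells))) {
      k <- truth$counts[, ci]
      mol_gene[[ci]] <- rep(rownames(truth$counts), k)
      mol_umi[[ci]] <- random_dna(length(mol_gene[[ci]]), design$umi_len)
    }
    umis <- character(n_total)

    # strand-invasion slot pool, shuffled once
    n_inv <- sum(cls == "strand_invasion")
    slots <- invasion_slots(tx, pat_len, read_len)
    if (n_inv > nrow(slots)) {
      stop(sprintf(
        "transcriptome capacity (%d non-overlapping invasion slots) < %d requested invasion reads; enlarge the transcriptome",
        nrow(slots), n_inv), call. = FALSE)
    }
    if (nrow(slots)) slots <- slots[sample(nrow(slots)), , drop = FALSE]
    inv_slot <- 0L

    seqs <- tx$seqs
    gene_id <- rep(NA_character_, n_total)
    start <- rep(NA_integer_, n_total)
    r2 <- character(n_total)

    for (i in seq_len(n_total)) {
      ci <- cell_idx[i]
      if (cls[i] == "normal") {
        if (length(mol_gene[[ci]]) > 0) {
          m <- sample.int(length(mol_gene[[ci]]), 1)  # uniform over molecules
          g <- mol_gene[[ci]][m]
          umis[i] <- mol_umi[[ci]][m]
        } else {
          g <- sample(rownames(truth$counts), 1)      # empty cell fallback
          umis[i] <- random_dna(1, design$umi_len)
        }
        gene_id[i] <- g
        start[i] <- 0L
        s <- substr(seqs[[g]], 1, read_len)
        if (nchar(s) < read_len) s <- paste0(s, strrep("A", read_len - nchar(s)))
        r2[i] <- s
      } else if (cls[i] == "strand_invasion") {
        umis[i] <- random_dna(1, design$umi_len)      # one fresh molecule
        inv_slot <- inv_slot + 1L
        g <- slots$gene_id[inv_slot]
        p0 <- slots$start[inv_slot]            # 0-based alignment start
        gene_id[i] <- g
        start[i] <- p0
        pattern <- paste0(umis[i], design$spacer, design$tail)
        pattern <- mutate_k(pattern, sample(0:3, 1))
        s <- seqs[[g]]
        substr(s, p0 - pat_len + 1L, p0) <- pattern   # 1-based write
        seqs[[g]] <- s
        r2[i] <- substr(s, p0 + 1L, p0 + read_len)
      } else {
        umis[i] <- random_dna(1, design$umi_len)
        # tandem TSO concatemer: three units, window forced over a junction
        units <- vapply(seq_len(3), function(k) {
          paste0(design$handle, wells$barcode[ci],
                 random_dna(1, design$umi_len), design$spacer, design$tail)
        }, character(1))
        template <- paste(units, collapse = "")
        unit_len <- nchar(units[1])
        off <- sample(max(1L, unit_len - 85L):(unit_len - 6L), 1)
        r2[i] <- substr(template, off, off + read_len - 1L)
      }
    }

    r1 <- paste0(wells$barcode[cell_idx], umis, spacer1)
    if (error_rate > 0) {
      r1 <- mutate_seqs(r1, error_rate)
      r2 <- mutate_seqs(r2, error_rate)
    }
    read_id <- sprintf("read%07d", seq_len(n_total))
    reads <- data.frame(read_id = read_id, r1_seq = r1,
                        r1_qual = strrep("?", 26L),
                        r2_seq = r2, r2_qual = strrep("?", read_len),
                        stringsAsFactors = FALSE)
    truth_tab <- data.frame(read_id = read_id,
                            cell_id = wells$cell_id[cell_idx],
                            gene_id = gene_id, umi = umis,
                            artifact_class = cls, start = start,
                            strand = "+", stringsAsFactors = FALSE)
    mapped <- cls != "concatemer"
    tags <- data.frame(cell_id = wells$cell_id[cell_idx][mapped],
                       umi = umis[mapped], ref = gene_id[mapped],
                       start = start[mapped],
                       end = start[mapped] + read_len,
                       strand = rep("+", sum(mapped)),
                       stringsAsFactors = FALSE)
    tx$seqs <- seqs
    out <- list(reads = reads, truth = truth_tab, tags = tags, tx = tx)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_fastq(data.frame(read_id = read_id, seq = r1,
                             qual = reads$r1_qual),
                  file.path(dir, "R1.fastq.gz"))
      write_fastq(data.frame(read_id = read_id, seq = r2,
                             qual = reads$r2_qual),
                  file.path(dir, "R2.fastq.gz"))
      write_tsv(truth_tab, file.path(dir, "truth.tsv"))
      write_tsv(tags, file.path(dir, "tags.tsv"))
      write_transcriptome(tx, dir)
    }
    out
  })
}

#' Simulate a toy AIRR contig table
#'
#' Assigns each cell one of five categories (paired, alpha-only, beta-only,
#' unproductive, none) with the given rates and emits AIRR-style contig rows
#' realising the category. Productive rows carry the Jurkat E6-1 reference
#' clonotype calls (TRAV8-4/TRAJ3, TRBV12-3/TRBJ1-2).
#'
#' @param layout a `plate_layout` (one cell per well).
#' @param pair_rate,alpha_only_rate,beta_only_rate,unproductive_rate
#'   per-cell category probabilities (sum <= 1; remainder = no contig).
#' @param seed integer seed.
#' @return list with `airr` (cell_id, locus, v_call, j_call, junction_aa,
#'   productive, complete_vdj) and `truth` (cell_id, category).
#' @export
simulate_airr <- function(layout, pair_rate = 0.8, alpha_only_rate = 0.05,
                          beta_only_rate = 0.1, unproductive_rate = 0.03,
                          seed = 1) {
  rates <- c(pair_rate, alpha_only_rate, beta_only_rate, unproductive_rate)
  stopifnot(all(rates >= 0), sum(rates) <= 1)
  cells <- layout$wells$cell_id
  tra <- list(locus = "TRA", v_call = "TRAV8-4", j_call = "TRAJ3",
              junction_aa = "CAVSDLEPNSSASKIIF")
  trb <- list(locus = "TRB", v_call = "TRBV12-3", j_call = "TRBJ1-2",
              junction_aa = "CASSFSTCSANYGYTF")
  row_for <- function(cell, chain, productive, complete = TRUE) {
    data.frame(cell_id = cell, locus = chain$locus,
               v_call = if (complete) chain$v_call else "",
               j_call = if (complete) chain$j_call else "",
               junction_aa = if (complete) chain$junction_aa else "",
               productive = productive, complete_vdj = complete,
               stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    cat_lvl <- c("paired", "alpha_only", "beta_only", "unproductive", "none")
    category <- sample(cat_lvl, length(cells), replace = TRUE,
                       prob = c(rates, 1 - sum(rates)))
    rows <- list()
    for (i in seq_along(cells)) {
      rows[[i]] <- switch(
        category[i],
        paired = rbind(row_for(cells[i], tra, TRUE),
                       row_for(cells[i], trb, TRUE)),
        alpha_only = row_for(cells[i], tra, TRUE),
        beta_only = row_for(cells[i], trb, TRUE),
        unproductive = rbind(row_for(cells[i], tra, FALSE),
                             row_for(cells[i], trb, FALSE)),
        none = NULL)
    }
    airr <- do.call(rbind, rows)
    if (is.null(airr)) {
      airr <- row_for("x", tra, TRUE)[0, ]
    }
    list(airr = airr,
         truth = data.frame(cell_id = cells, category = category,
                            stringsAsFactors = FALSE))
  })
}
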