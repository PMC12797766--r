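# Shared fixture builders. Everything is generated in code under fixed
# seeds; no binary fixtures.

toy_layout <- function(n_cells = 8, seed = 42) {
  bcs <- pb10x::random_dna(n_cells, 16, seed = seed)
  pb10x::make_layout(bcs, n_cells)
}

# Small end-to-end simulation reused across modules.
toy_simulation <- function(n_cells = 8, depth = 50, n_genes = 40,
                           concatemer_rate = 0, invasion_rate = 0,
                           error_rate = 0, seed = 7) {
  layout <- toy_layout(n_cells, seed = seed)
  tx <- pb10x::make_transcriptome(n_genes, seed = seed)
  truth <- pb10x::simulate_expression(layout, tx, seed = seed)
  sim <- pb10x::simulate_reads(truth, layout, tx,
                               depth_per_cell = depth,
                               concatemer_rate = concatemer_rate,
                               invasion_rate = invasion_rate,
                               error_rate = error_rate, seed = seed)
  c(sim, list(layout = layout, expr = truth))
}

# Independent brute-force oracle: minimum Hamming load of `pattern` over
# all anchored offsets in `window` (NA if it does not fit).
oracle_best_hamming <- function(pattern, window) {
  p <- nchar(pattern); w <- nchar(window)
  if (w < p || w == 0) return(NA_integer_)
  min(vapply(0:(w - p), function(off) {
    a <- strsplit(substr(window, off + 1, off + p), "")[[1]]
    b <- strsplit(pattern, "")[[1]]
    sum(a != b)
  }, integer(1)))
}

# Brute-force maximum clique size on the pairwise >= d_min graph,
# enumerating all subsets (toy sizes only).
oracle_max_clique <- function(barcodes, d_min) {
  n <- length(barcodes)
  d <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    as.integer(utils::adist(barcodes[i], barcodes[j]))
  }))
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    ok <- TRUE
    if (length(idx) > 1) {
      pr <- utils::combn(idx, 2)
      ok <- all(d[cbind(pr[1, ], pr[2, ])] >= d_min)
    }
    if (ok) best <- length(idx)
  }
  best
}
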