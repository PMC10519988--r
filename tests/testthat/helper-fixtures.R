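# Shared fixture builders. Everything is generated in code at test time.

# default model, built once per test run
default_model <- function(strand = "-") {
  make_gene_model(sim_config(strand = strand))
}

# small simulation config for fast single-nucleus tests
quick_config <- function(seed = 1L, ...) {
  sim_config(seed = seed,
             cells_per_type = c(tumour = 100L, mesangial = 60L, endothelial = 40L),
             ...)
}

# construct a nucleus_counts object from a dense count matrix and optional
# metadata (mirrors the generator's container)
make_nucleus <- function(counts, type = NULL, doublet_score = NULL,
                         sample = "S1", mito_genes = character(0)) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("C%04d", seq_len(ncol(counts)))
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("G%04d", seq_len(nrow(counts)))
  if (is.null(type)) type <- rep("tumour", ncol(counts))
  if (is.null(doublet_score)) doublet_score <- rep(0, ncol(counts))
  structure(list(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    cell_meta = data.frame(barcode = colnames(counts), sample = sample,
                           type = type, doublet_score = doublet_score,
                           stringsAsFactors = FALSE),
    gene_meta = data.frame(gene = rownames(counts),
                           mito = rownames(counts) %in% mito_genes,
                           stringsAsFactors = FALSE)
  ), class = "nucleus_counts")
}

# independent rank-sum oracle: exhaustive enumeration of group assignments,
# computing U by pair counting (greater counts 1, ties 0.5) -- a different
# route from the implementation's rank-sum formula
oracle_rank_sum_p <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x); n <- length(vals)
  gt <- outer(vals, vals, ">") + 0.5 * outer(vals, vals, "==")
  u_of <- function(idx) sum(gt[idx, setdiff(seq_len(n), idx), drop = FALSE])
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2, u_of)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# brute-force BH step-up rejection set at level alpha
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * alpha / m)
  rej <- rep(FALSE, m)
  if (length(ok) > 0) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}
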