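# Single-nucleus QC, doublet-cluster removal, log-normalisation, marker
# tables and the endothelial-normalised target/NRARP ratio statistic.

#' Quality-control filter for nuclei
#'
#' Keeps cells with `min_genes <= detected genes <= max_genes` and
#' mitochondrial fraction strictly below `max_mito`. Defaults encode the
#' standard gates: fewer than 1000 or more than 7500 detected genes, or a
#' mitochondrial proportion of 10% or greater, removes the cell.
#'
#' @param x A `nucleus_counts` object.
#' @param min_genes,max_genes Detected-gene bounds (inclusive).
#' @param max_mito Mitochondrial-fraction ceiling (exclusive).
#' @return list(`data` = filtered `nucleus_counts`, `report` = counts per
#'   removal reason and totals).
#' @export
qc_filter <- function(x, min_genes = 1000L, max_genes = 7500L, max_mito = 0.10) {
  stopifnot(inherits(x, "nucleus_counts"))
  detected <- Matrix::colSums(x$counts > 0)
  totals <- Matrix::colSums(x$counts)
  mito_genes <- x$gene_meta$gene[x$gene_meta$mito]
  if (length(mito_genes) == 0L) {
    warning("no mitochondrial-flagged genes: mito rule skipped")
    mito_frac <- rep(0, ncol(x$counts))
    mito_skipped <- TRUE
  } else {
    mito_frac <- Matrix::colSums(x$counts[mito_genes, , drop = FALSE]) /
      pmax(totals, 1)
    mito_skipped <- FALSE
  }
  low <- detected < min_genes
  high <- detected > max_genes
  mito_fail <- mito_frac >= max_mito
  keep <- !(low | high | mito_fail)
  x$cell_meta$detected_genes <- detected
  x$cell_meta$mito_fraction <- mito_frac
  list(
    data = subset_cells(x, which(keep)),
    report = list(n_in = length(keep), n_kept = sum(keep),
                  n_low_genes = sum(low), n_high_genes = sum(high),
                  n_high_mito = sum(mito_fail),
                  mito_rule_skipped = mito_skipped)
  )
}

#' Log-normalise counts to 10,000 per cell
#'
#' `value = ln(1 + 1e4 * count / cell_total)` (natural log). The normalised
#' vector of a cell is invariant to uniform scaling of its counts.
#'
#' @param x A `nucleus_counts` object.
#' @return `x` with a sparse `logcounts` element added.
#' @export
lognormalize <- function(x) {
  stopifnot(inherits(x, "nucleus_counts"))
  totals <- Matrix::colSums(x$counts)
  if (any(totals == 0)) {
    stop("zero-total cell(s) present: apply qc_filter first", call. = FALSE)
  }
  lc <- methods::as(x$counts, "CsparseMatrix") * 1.0
  lc@x <- log1p(1e4 * lc@x / rep.int(totals, diff(lc@p)))
  x$logcounts <- lc
  x
}

# ensure logcounts present
.logc <- function(x) {
  if (is.null(x$logcounts)) x <- lognormalize(x)
  x
}

#' Select nuclei co-expressing a gene set
#'
#' Cells with log-normalised expression strictly greater than zero for every
#' listed gene (the standard three-gene REN/NOTCH1/NRARP co-expression
#' gate). An empty gene list selects all cells.
#'
#' @param x A `nucleus_counts` object.
#' @param genes Character vector of gene names.
#' @return Character vector of selected barcodes.
#' @export
select_coexpressing <- function(x, genes = c("REN", "NOTCH1", "NRARP")) {
  x <- .logc(x)
  if (length(genes) == 0L) return(colnames(x$counts))
  absent <- setdiff(genes, rownames(x$counts))
  if (length(absent) > 0L) {
    stop("gene(s) absent from matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  sub <- x$logcounts[genes, , drop = FALSE]
  keep <- Matrix::colSums(sub > 0) == length(genes)
  colnames(x$counts)[keep]
}

# cells x pcs PCA scores of scaled variable-gene expression, with mito
# fraction and log totals regressed out (covariates only affect clustering)
.cluster_embedding <- function(x, n_var_genes = 2000L, n_pcs = 30L) {
  x <- .logc(x)
  lc <- x$logcounts
  v <- apply(lc, 1, stats::var)
  ng <- min(n_var_genes, sum(v > 0))
  top <- order(v, decreasing = TRUE)[seq_len(ng)]
  X <- t(as.matrix(lc[top, , drop = FALSE]))  # cells x genes
  totals <- Matrix::colSums(x$counts)
  mito_genes <- x$gene_meta$gene[x$gene_meta$mito]
  mito_frac <- if (length(mito_genes)) {
    Matrix::colSums(x$counts[mito_genes, , drop = FALSE]) / totals
  } else rep(0, ncol(x$counts))
  C <- cbind(1, mito_frac, log(totals))
  X <- X - C %*% solve(crossprod(C), crossprod(C, X))
  sds <- pmax(apply(X, 2, stats::sd), 1e-8)
  X <- sweep(X, 2, sds, "/")
  n_pcs <- min(n_pcs, ncol(X), nrow(X) - 1L)
  # PCA via eigen of the cell-cell Gram matrix (cells << genes)
  G <- tcrossprod(X)
  eg <- eigen(G, symmetric = TRUE)
  scores <- eg$vectors[, seq_len(n_pcs), drop = FALSE] *
    rep(sqrt(pmax(eg$values[seq_len(n_pcs)], 0)), each = nrow(X))
  scores
}

#' Remove doublet-enriched clusters and called doublets
#'
#' Over-clusters the data (built-in: k-means with `k = max(20, cells/50)` on
#' the top principal components of scaled variable-gene expression, standing
#' in for graph clustering at high resolution; or accepts externally
#' supplied cluster labels), removes every cluster whose mean doublet score
#' exceeds `mean_thresh` (strict inequality), then removes any remaining
#' individual cells whose doublet score exceeds `call_thresh` (doublet
#' calls).
#'
#' @param x A `nucleus_counts` object with `doublet_score` metadata.
#' @param labels Optional externally supplied cluster labels (length =
#'   cells); bypasses the built-in clustering.
#' @param k Number of k-means clusters; default `max(20, floor(cells/50))`,
#'   reduced (with a message) when there are fewer cells.
#' @param mean_thresh Cluster mean-score threshold (default 0.1, strict >).
#' @param call_thresh Per-cell doublet-call threshold (default 0.5, strict >).
#' @param seed Seed for k-means initialisation.
#' @return list(`data` = filtered object, `report` = removal counts and the
#'   removed cluster ids).
#' @export
remove_doublet_clusters <- function(x, labels = NULL, k = NULL,
                                    mean_thresh = 0.1, call_thresh = 0.5,
                                    seed = 1L) {
  stopifnot(inherits(x, "nucleus_counts"))
  if (!"doublet_score" %in% names(x$cell_meta)) {
    stop("doublet_score metadata required", call. = FALSE)
  }
  n <- ncol(x$counts)
  score <- x$cell_meta$doublet_score
  if (is.null(labels)) {
    if (is.null(k)) k <- max(20L, floor(n / 50))
    if (k >= n) {
      k <- max(1L, n - 1L)
      message("fewer cells than clusters requested: k reduced to ", k)
    }
    emb <- .cluster_embedding(x)
    labels <- with_seed(seed,
      stats::kmeans(emb, centers = k, nstart = 3L, iter.max = 50L)$cluster)
  } else {
    stopifnot(length(labels) == n)
  }
  cl_means <- tapply(score, labels, mean)
  bad_clusters <- names(cl_means)[cl_means > mean_thresh]
  in_bad <- as.character(labels) %in% bad_clusters
  called <- !in_bad & score > call_thresh
  keep <- !(in_bad | called)
  list(
    data = subset_cells(x, which(keep)),
    report = list(n_in = n, n_kept = sum(keep),
                  n_removed_cluster = sum(in_bad),
                  n_removed_call = sum(called),
                  # removed cells whose own score exceeds the call threshold:
                  # the score-supported doublet count (cluster-level removal
                  # additionally takes low-score bystanders, as wholesale
                  # cluster dropping does)
                  n_removed_scored = sum(!keep & score > call_thresh),
                  removed_clusters = bad_clusters,
                  cluster_means = cl_means)
  )
}

#' Per-cluster marker table
#'
#' For each cluster, tests each gene against all other cells with a
#' two-sided Wilcoxon rank-sum test on log-normalised values, and reports
#' genes detected in at least `min_pct` of the cluster, with
#' `|log2FC| >= logfc_thresh` and Bonferroni-adjusted p <= `alpha`
#' (Bonferroni over all genes in the matrix, per cluster). log2FC is
#' computed as `log2((expm1(mean_in) + 1) / (expm1(mean_out) + 1))` on
#' log-normalised values. Singleton clusters are skipped with a warning.
#'
#' @param x A `nucleus_counts` object.
#' @param labels Cluster label per cell.
#' @param min_pct Minimum in-cluster detection fraction (default 0.10).
#' @param logfc_thresh Minimum |log2FC| (default 0.2).
#' @param alpha Bonferroni-adjusted p cut-off (default 0.05).
#' @return data.frame: `cluster`, `gene`, `pct_in`, `pct_out`, `log2fc`,
#'   `p`, `p_adj`.
#' @export
marker_table <- function(x, labels, min_pct = 0.10, logfc_thresh = 0.2,
                         alpha = 0.05) {
  x <- .logc(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(x$counts))
  clusters <- unique(labels)
  if (length(clusters) < 2L) stop("need >= 2 clusters", call. = FALSE)
  m_genes <- nrow(x$counts)
  lc <- x$logcounts
  out <- list()
  for (cl in clusters) {
    in_cl <- labels == cl
    if (sum(in_cl) < 2L) {
      warning("singleton cluster '", cl, "' skipped")
      next
    }
    lin <- lc[, in_cl, drop = FALSE]
    lout <- lc[, !in_cl, drop = FALSE]
    pct_in <- Matrix::rowSums(lin > 0) / ncol(lin)
    pct_out <- Matrix::rowSums(lout > 0) / ncol(lout)
    mean_in <- Matrix::rowMeans(lin)
    mean_out <- Matrix::rowMeans(lout)
    log2fc <- log2((expm1(mean_in) + 1) / (expm1(mean_out) + 1))
    cand <- which(pct_in >= min_pct & abs(log2fc) >= logfc_thresh)
    for (gi in cand) {
      ts <- rank_sum_test(as.numeric(lin[gi, ]), as.numeric(lout[gi, ]))
      p_adj <- min(1, ts$p.value * m_genes)
      if (p_adj <= alpha) {
        out[[length(out) + 1L]] <- data.frame(
          cluster = cl, gene = rownames(lc)[gi],
          pct_in = pct_in[gi], pct_out = pct_out[gi],
          log2fc = log2fc[gi], p = ts$p.value, p_adj = p_adj,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(cluster = character(0), gene = character(0),
                      pct_in = numeric(0), pct_out = numeric(0),
                      log2fc = numeric(0), p = numeric(0), p_adj = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-nucleus target/NRARP expression ratios
#'
#' For each target gene, over nuclei with log-normalised target value > 0
#' and denominator value > 0, the ratio of the target's log-normalised
#' value to the denominator's. Targets absent from the matrix are dropped
#' with a message (only targets expressed in the dataset are ratioed).
#'
#' @param x A `nucleus_counts` object.
#' @param targets Target gene names (defaults to the canonical NOTCH1
#'   effectors).
#' @param denominator Denominator gene (default `"NRARP"`).
#' @return data.frame: `barcode`, `sample`, `type`, `target`, `ratio`, with
#'   attribute `n_excluded` (nuclei dropped per target for a zero value).
#' @export
target_ratio <- function(x, targets = TARGET_GENES, denominator = "NRARP") {
  x <- .logc(x)
  if (!denominator %in% rownames(x$counts)) {
    stop("denominator gene '", denominator, "' absent from matrix", call. = FALSE)
  }
  present <- intersect(targets, rownames(x$counts))
  if (length(present) < length(targets)) {
    message("dropping absent target(s): ",
            paste(setdiff(targets, present), collapse = ", "))
  }
  den <- as.numeric(x$logcounts[denominator, ])
  meta <- x$cell_meta
  out <- list()
  n_excluded <- integer(0)
  for (tg in present) {
    num <- as.numeric(x$logcounts[tg, ])
    ok <- num > 0 & den > 0
    n_excluded[tg] <- sum(!ok)
    if (!any(ok)) next
    out[[tg]] <- data.frame(
      barcode = meta$barcode[ok], sample = meta$sample[ok],
      type = if ("type" %in% names(meta)) meta$type[ok] else NA_character_,
      target = tg, ratio = num[ok] / den[ok], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Endothelial-median normalisation of ratio values
#'
#' Divides each nucleus's target/denominator ratio by the median ratio of
#' the endothelial nuclei of the same sample for the same target (the
#' per-sample technical-batch reference; endothelial cells are used because
#' their NOTCH-dependent signalling provides a stable baseline). A second
#' application divides again, by the recomputed reference median -- which is
#' exactly 1 after a first pass, since the median of values divided by their
#' median is itself 1.
#'
#' @param ratios data.frame from [target_ratio()].
#' @param endothelial_barcodes Barcodes of endothelial nuclei.
#' @return `ratios` with a `normalized` column appended.
#' @export
endothelial_normalize <- function(ratios, endothelial_barcodes) {
  stopifnot(all(c("barcode", "sample", "target", "ratio") %in% names(ratios)))
  is_endo <- ratios$barcode %in% endothelial_barcodes
  key <- interaction(ratios$sample, ratios$target, drop = TRUE)
  med <- tapply(ratios$ratio[is_endo], droplevels(key[is_endo]), stats::median)
  needed <- unique(as.character(key))
  missing <- setdiff(needed, names(med))
  if (length(missing) > 0L) {
    stop("no endothelial nucleus with a defined ratio for sample/target: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ratios$normalized <- ratios$ratio / as.numeric(med[as.character(key)])
  ratios
}

#' Pseudobulk aggregation
#'
#' Per-gene sum of raw counts within each group.
#'
#' @param x A `nucleus_counts` object.
#' @param group_key Metadata column name to aggregate by.
#' @return genes x groups matrix of summed counts.
#' @export
pseudobulk <- function(x, group_key = "type") {
  stopifnot(inherits(x, "nucleus_counts"))
  if (!group_key %in% names(x$cell_meta)) {
    stop("group key '", group_key, "' not in cell metadata", call. = FALSE)
  }
  g <- as.character(x$cell_meta[[group_key]])
  groups <- unique(g)
  out <- vapply(groups, function(gr) {
    Matrix::rowSums(x$counts[, g == gr, drop = FALSE])
  }, numeric(nrow(x$counts)))
  colnames(out) <- groups
  out
}

#' End-to-end single-nucleus ratio pipeline
#'
#' QC filter -> doublet-cluster removal -> log-normalisation -> per-nucleus
#' target/NRARP ratios -> endothelial-median normalisation -> group tests.
#' The test family comprises the per-target tumour-vs-reference rank-sum
#' tests on normalised ratios plus the REN expression test, all
#' Benjamini-Hochberg adjusted together.
#'
#' @param x A `nucleus_counts` object with `type` metadata (tumour /
#'   mesangial / endothelial labels; generator truth or external annotation).
#' @param targets,denominator As in [target_ratio()].
#' @param reference Reference population for the group tests (default
#'   `"mesangial"`).
#' @param cluster_labels Optional external over-clustering labels for the
#'   doublet step.
#' @param seed Seed for the built-in clustering.
#' @return list: `data` (filtered, normalised object), `qc_report`,
#'   `doublet_report`, `ratios` (with `normalized`), `tests` (per-target
#'   rows plus a `REN` row; columns `target`, `n_tumour`, `n_ref`, `p`,
#'   `p_adj`, `median_tumour`, `median_ref`), `median_normalized` (named
#'   per-target tumour medians).
#' @export
run_nucleus_pipeline <- function(x, targets = TARGET_GENES,
                                 denominator = "NRARP",
                                 reference = "mesangial",
                                 cluster_labels = NULL, seed = 1L) {
  qc <- qc_filter(x)
  db <- remove_doublet_clusters(qc$data, labels = cluster_labels, seed = seed)
  d <- lognormalize(db$data)
  ratios <- target_ratio(d, targets = targets, denominator = denominator)
  endo_bc <- d$cell_meta$barcode[d$cell_meta$type == "endothelial"]
  ratios <- endothelial_normalize(ratios, endo_bc)

  # per-target tumour vs reference on normalised ratios
  rows <- list()
  pvals <- numeric(0)
  for (tg in unique(ratios$target)) {
    rt <- ratios[ratios$target == tg, ]
    tum <- rt$normalized[rt$type == "tumour"]
    ref <- rt$normalized[rt$type == reference]
    if (length(tum) == 0L || length(ref) == 0L) {
      warning("comparison skipped for target ", tg, ": empty group")
      next
    }
    ts <- rank_sum_test(tum, ref)
    rows[[tg]] <- data.frame(
      target = tg, n_tumour = length(tum), n_ref = length(ref),
      p = ts$p.value, median_tumour = stats::median(tum),
      median_ref = stats::median(ref), stringsAsFactors = FALSE)
    pvals[tg] <- ts$p.value
  }
  # REN expression joins the same BH family
  ren_val <- as.numeric(d$logcounts["REN", ])
  ren_t <- ren_val[d$cell_meta$type == "tumour"]
  ren_r <- ren_val[d$cell_meta$type == reference]
  ren_ts <- rank_sum_test(ren_t, ren_r)
  rows[["REN"]] <- data.frame(
    target = "REN", n_tumour = length(ren_t), n_ref = length(ren_r),
    p = ren_ts$p.value, median_tumour = stats::median(ren_t),
    median_ref = stats::median(ren_r), stringsAsFactors = FALSE)
  pvals["REN"] <- ren_ts$p.value

  tests <- do.call(rbind, rows)
  tests$p_adj <- bh_adjust(tests$p)
  rownames(tests) <- NULL

  med_norm <- vapply(setdiff(tests$target, "REN"), function(tg) {
    stats::median(ratios$normalized[ratios$target == tg & ratios$type == "tumour"])
  }, numeric(1))

  list(data = d, qc_report = qc$report, doublet_report = db$report,
       ratios = ratios, tests = tests, median_normalized = med_norm)
}
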