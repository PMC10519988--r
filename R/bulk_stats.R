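# Bulk RNA normalisation and cross-cohort comparison: TMM scaling factors,
# log-CPM, per-gene cohort tests and cross-data-set DE intersection.

# weighted trimmed mean of M-values between one sample and the reference;
# mirrors the standard TMM recipe: genes with zero counts in either sample
# are excluded, 30% of M-values and 5% of A-values are trimmed from both
# tails, and the remaining M are averaged with inverse asymptotic-variance
# weights
.tmm_one <- function(obs, ref, lib_obs, lib_ref,
                     logratio_trim = 0.3, sum_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0L) return(1)
  m <- log2((obs / lib_obs) / (ref / lib_ref))
  a <- 0.5 * log2((obs / lib_obs) * (ref / lib_ref))
  # asymptotic variance of M per gene; weights are its inverse
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  fin <- is.finite(m) & is.finite(a) & is.finite(v)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  n <- length(m)
  if (n == 0L) return(1)
  if (max(abs(m)) < 1e-6) return(1)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(1)
  f <- sum(m[keep2] / v[keep2]) / sum(1 / v[keep2])
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM normalisation factors
#'
#' Trimmed-mean-of-M-values scaling factors, computed per sample against a
#' reference sample (by default the sample whose 75th-percentile CPM is
#' closest to the mean across samples). Gene-wise log2 ratios (M) are
#' trimmed 30% on both tails and average-abundance values (A) 5% on both
#' tails; the surviving M are combined with inverse asymptotic-variance
#' weights, and factors are centred so that their log-sum is zero. Factors
#' capture composition bias only: a library that is a uniformly scaled copy
#' of another has factor ~1 (depth is handled by CPM).
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @param reference Optional reference column (index or name).
#' @param logratio_trim,sum_trim Trim fractions for M and A.
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts, reference = NULL,
                        logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need >= 2 samples", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "), call. = FALSE)
  }
  if (is.null(reference)) {
    uq <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
    reference <- which.min(abs(uq - mean(uq)))
  } else if (is.character(reference)) {
    reference <- match(reference, colnames(counts))
    if (is.na(reference)) stop("reference sample not found", call. = FALSE)
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_one(counts[, j], counts[, reference], lib[j], lib[reference],
             logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))  # centre: log factors sum to zero
  names(f) <- colnames(counts)
  f
}

#' log-CPM transformation
#'
#' `log2((count + 0.5) / (library_size * factor + 1) * 1e6)`, the standard
#' continuity-corrected counts-per-million on TMM-effective library sizes.
#'
#' @param counts genes x samples count matrix.
#' @param factors Per-sample scaling factors (default [tmm_factors()]).
#' @param prior_count Numerator pseudocount (default 0.5).
#' @return Matrix of log-CPM values.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- tmm_factors(counts)
  if (any(factors <= 0)) stop("factors must be positive", call. = FALSE)
  lib <- colSums(counts)
  eff <- lib * factors + 1
  if (any(eff <= 0)) stop("nonpositive effective library size", call. = FALSE)
  t(log2(t(counts + prior_count) / eff * 1e6))
}

#' Compare one gene's expression across cohorts
#'
#' Two-sided Wilcoxon rank-sum test of the index cohort against each other
#' cohort on the gene's log-CPM values, Benjamini-Hochberg adjusted across
#' the comparisons.
#'
#' @param logcpm genes x samples log-CPM matrix.
#' @param gene Gene (row) name.
#' @param cohorts Cohort label per sample.
#' @param index_cohort The cohort compared against all others.
#' @return data.frame of comparisons (see [compare_ratio_groups()]; the
#'   `group` column names the contrasted cohort and the reference columns
#'   describe the index cohort).
#' @export
cohort_compare <- function(logcpm, gene, cohorts, index_cohort) {
  if (!gene %in% rownames(logcpm)) {
    stop("gene '", gene, "' absent from matrix", call. = FALSE)
  }
  cohorts <- as.character(cohorts)
  stopifnot(length(cohorts) == ncol(logcpm))
  if (!index_cohort %in% cohorts) {
    stop("missing cohort: ", index_cohort, call. = FALSE)
  }
  compare_ratio_groups(as.numeric(logcpm[gene, ]), cohorts,
                       reference = index_cohort)
}

# per-gene tumour-vs-normal rank test with BH, on TMM log-CPM
.de_one_set <- function(counts, design, alpha = 0.05) {
  stopifnot(length(design) == ncol(counts))
  design <- as.character(design)
  if (!all(design %in% c("tumour", "normal"))) {
    stop("design labels must be 'tumour' or 'normal'", call. = FALSE)
  }
  if (sum(design == "normal") == 0L) stop("set lacks normal samples", call. = FALSE)
  if (sum(design == "tumour") == 0L) stop("set lacks tumour samples", call. = FALSE)
  lc <- log_cpm(counts)
  tum <- design == "tumour"
  res <- t(apply(lc, 1, function(v) {
    ts <- rank_sum_test(v[tum], v[!tum])
    c(lfc = mean(v[tum]) - mean(v[!tum]), p = ts$p.value)
  }))
  out <- data.frame(gene = rownames(counts), lfc = res[, "lfc"], p = res[, "p"],
                    stringsAsFactors = FALSE)
  out$p_adj <- bh_adjust(out$p)
  out$direction <- ifelse(out$lfc >= 0, "up", "down")
  out$de <- out$p_adj <= alpha
  rownames(out) <- NULL
  out
}

#' Differential expression per data set and intersection of gene lists
#'
#' Runs, independently for each data set, a per-gene two-sided rank-sum
#' test of tumour vs normal samples on TMM-normalised log-CPM with
#' Benjamini-Hochberg adjustment, calls DE at adjusted p <= `alpha`, and
#' returns the intersection of the two DE gene sets. The empirical-Bayes
#' moderated linear-model machinery commonly used for this task is
#' deliberately replaced by the rank-based test (a documented
#' methodological substitution); results are validated against planted
#' truth, not against any published gene list.
#'
#' @param counts_a,counts_b genes x samples count matrices (shared gene
#'   universe by name).
#' @param design_a,design_b `"tumour"`/`"normal"` label per sample.
#' @param alpha BH-adjusted DE threshold (default 0.05).
#' @return list: `shared` (intersection gene vector), `set_a`, `set_b`
#'   (per-set DEResult tables).
#' @export
de_and_intersect <- function(counts_a, design_a, counts_b, design_b,
                             alpha = 0.05) {
  a <- .de_one_set(as.matrix(counts_a), design_a, alpha)
  b <- .de_one_set(as.matrix(counts_b), design_b, alpha)
  shared <- intersect(a$gene[a$de], b$gene[b$de])
  list(shared = shared, set_a = a, set_b = b)
}

#' Simulate bulk count matrices with planted differential expression
#'
#' Two independent tumour/normal data sets over a shared gene universe with
#' a configurable set of genes fold-changed in tumours of both sets (or of
#' one set only), for validating [de_and_intersect()] and
#' [cohort_compare()].
#'
#' @param n_genes Total genes.
#' @param n_tumour,n_normal Samples per condition per set.
#' @param de_both,de_a_only Gene counts planted DE in both sets / set A only.
#' @param fold Planted fold change.
#' @param base_mean Baseline NB mean.
#' @param size NB dispersion (size).
#' @param seed Integer seed.
#' @return list with `counts_a`, `design_a`, `counts_b`, `design_b`,
#'   `truth_both`, `truth_a_only`.
#' @export
simulate_bulk_sets <- function(n_genes = 200L, n_tumour = 8L, n_normal = 8L,
                               de_both = 20L, de_a_only = 10L, fold = 6,
                               base_mean = 100, size = 10, seed = 1L) {
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    both <- genes[seq_len(de_both)]
    a_only <- genes[de_both + seq_len(de_a_only)]
    gen_set <- function(up_genes) {
      mu <- matrix(base_mean, n_genes, n_tumour + n_normal,
                   dimnames = list(genes, NULL))
      mu[up_genes, seq_len(n_tumour)] <- base_mean * fold
      cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                    n_genes, ncol(mu), dimnames = dimnames(mu))
      colnames(cnt) <- sprintf("S%02d", seq_len(ncol(cnt)))
      list(counts = cnt,
           design = rep(c("tumour", "normal"), c(n_tumour, n_normal)))
    }
    a <- gen_set(c(both, a_only))
    b <- gen_set(both)
    list(counts_a = a$counts, design_a = a$design,
         counts_b = b$counts, design_b = b$design,
         truth_both = both, truth_a_only = a_only)
  })
}
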