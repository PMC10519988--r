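# Negative-binomial single-nucleus count simulator with planted effects.
#
# Populations: tumour, mesangial-like and endothelial nuclei over a panel of
# marker genes (REN, NOTCH1, NRARP, the canonical NOTCH1 effector targets
# HEYL/HEY1/HEY2/HES1/HES4/HES5, mitochondrial genes, endothelial and
# mesangial markers) plus a housekeeping background that sets realistic
# genes-per-cell. Planted effects: tumour REN excess (ren_fold, raw-count
# scale), tumour NOTCH1 excess (notch1_fold, raw-count scale) and a tumour
# excess of target genes relative to NRARP (target_ratio_fold, defined on
# the log-normalised expression scale the ratio statistic measures; the
# corresponding raw NB mean is obtained by inverting the log1p transform at
# the expected tumour library size). Doublets are sums of two random parent
# nuclei with a high-mean Beta doublet score; low-quality nuclei are
# count-thinned below the QC gene floor.

#' Canonical NOTCH1 effector target genes
#' @export
TARGET_GENES <- c("HEYL", "HEY1", "HEY2", "HES1", "HES4", "HES5")
MITO_GENES <- paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6",
                              "CO3", "ND3", "ND4L", "ND4", "ND5", "ND6", "CYB"))
ENDO_MARKERS <- c("PECAM1", "EMCN", "FLT1", "KDR", "CDH5")
MES_MARKERS <- c("PDGFRB", "GATA3", "ITGA8")

# per-type NB mean matrix for the full panel
.panel_means <- function(config) {
  n_hk <- 2400L
  hk <- sprintf("HK%04d", seq_len(n_hk))
  genes <- c("REN", "NOTCH1", "NRARP", TARGET_GENES, MITO_GENES,
             ENDO_MARKERS, MES_MARKERS, hk)
  mu <- matrix(0, nrow = length(genes), ncol = 3,
               dimnames = list(genes, c("tumour", "mesangial", "endothelial")))
  mu[hk, ] <- 1
  mu[MITO_GENES, ] <- 10
  mu["REN", ] <- c(20 * config$ren_fold, 20, 0.5)
  mu["NOTCH1", ] <- c(3 * config$notch1_fold, 3, 3)
  mu["NRARP", ] <- 0.5
  mu[TARGET_GENES, ] <- 0.8
  mu[ENDO_MARKERS, ] <- rep(c(0.05, 0.05, 15), each = length(ENDO_MARKERS))
  mu[MES_MARKERS, ] <- rep(c(10, 10, 0.2), each = length(MES_MARKERS))

  # plant the target/NRARP excess on the log-normalised scale: solve for the
  # raw mean whose log1p(1e4 * mu / library) equals fold * the one-count
  # baseline value, iterating the tumour library size to a fixed point
  f <- config$target_ratio_fold
  if (f > 1) {
    base_lib <- sum(mu[, "tumour"])
    lib <- base_lib
    mu_f <- 0.8
    for (it in 1:25) {
      s <- 1e4 / lib
      v1 <- log1p(s)                 # value of a single count
      mu_f <- (exp(f * v1) - 1) / s  # count level whose value is f * v1
      lib <- base_lib - length(TARGET_GENES) * 0.8 +
        length(TARGET_GENES) * mu_f
    }
    mu[TARGET_GENES, "tumour"] <- mu_f
  }
  mu
}

#' Simulate a single-nucleus count matrix with planted truth
#'
#' @param config A [sim_config()].
#' @return A `nucleus_counts` object: list with `counts` (sparse
#'   genes x cells integer matrix), `cell_meta` (barcode, sample, type,
#'   doublet_score) and `gene_meta` (gene, mito flag). Identical configs
#'   give byte-identical results.
#' @export
simulate_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$cells_per_type <= 0L)) {
    stop("cells_per_type must all be > 0", call. = FALSE)
  }
  mu <- .panel_means(config)
  genes <- rownames(mu)
  size <- config$nb_dispersion
  npt <- config$cells_per_type

  with_seed(config$seed, {
    types <- rep(names(npt), npt)
    n_sing <- length(types)
    counts <- matrix(0L, nrow = length(genes), ncol = n_sing)
    for (ty in names(npt)) {
      idx <- which(types == ty)
      counts[, idx] <- stats::rnbinom(length(genes) * length(idx),
                                      mu = mu[, ty], size = size)
    }

    n_extra <- n_sing
    n_dbl <- round(config$doublet_rate * n_extra)
    n_lowq <- round(config$lowq_rate * n_extra)

    dbl <- NULL
    if (n_dbl > 0) {
      p1 <- sample.int(n_sing, n_dbl, replace = TRUE)
      p2 <- sample.int(n_sing, n_dbl, replace = TRUE)
      dbl <- counts[, p1, drop = FALSE] + counts[, p2, drop = FALSE]
    }

    lowq <- NULL
    if (n_lowq > 0) {
      ty <- sample(names(npt), n_lowq, replace = TRUE, prob = npt / sum(npt))
      lowq <- matrix(0L, nrow = length(genes), ncol = n_lowq)
      for (j in seq_len(n_lowq)) {
        full <- stats::rnbinom(length(genes), mu = mu[, ty[j]], size = size)
        lowq[, j] <- stats::rbinom(length(genes), full, 0.08)
      }
    }

    all_counts <- cbind(counts, dbl, lowq)
    type_vec <- c(types, rep("doublet", n_dbl), rep("lowq", n_lowq))
    n_all <- ncol(all_counts)
    score <- numeric(n_all)
    is_dbl <- type_vec == "doublet"
    score[!is_dbl] <- stats::rbeta(sum(!is_dbl), 1.5, 40)
    score[is_dbl] <- stats::rbeta(sum(is_dbl), 16, 4)

    barcodes <- sprintf("BC%05d", seq_len(n_all))
    dimnames(all_counts) <- list(genes, barcodes)
    structure(list(
      counts = methods::as(Matrix::Matrix(all_counts, sparse = TRUE), "CsparseMatrix"),
      cell_meta = data.frame(barcode = barcodes, sample = "S1",
                             type = type_vec, doublet_score = score,
                             stringsAsFactors = FALSE),
      gene_meta = data.frame(gene = genes, mito = genes %in% MITO_GENES,
                             stringsAsFactors = FALSE)
    ), class = "nucleus_counts")
  })
}

#' @export
print.nucleus_counts <- function(x, ...) {
  cat("nucleus_counts:", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  print(table(x$cell_meta$type))
  invisible(x)
}

# subset a nucleus_counts object by cell index/barcode, keeping metadata
# aligned
subset_cells <- function(x, keep) {
  stopifnot(inherits(x, "nucleus_counts"))
  if (is.character(keep)) keep <- match(keep, colnames(x$counts))
  x$counts <- x$counts[, keep, drop = FALSE]
  x$cell_meta <- x$cell_meta[keep, , drop = FALSE]
  rownames(x$cell_meta) <- NULL
  if (!is.null(x$logcounts)) x$logcounts <- x$logcounts[, keep, drop = FALSE]
  x
}
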