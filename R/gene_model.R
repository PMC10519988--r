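# Toy-locus gene/domain model: a NOTCH1-like 34-exon gene with ECD/TM/ICD
# domain labels, an NRARP-like negative-regulator gene ~0.8 Mb beyond its
# transcript 5' end, a REN-like gene and two decoys on a single contig.
#
# Internal coordinates are 0-based half-open throughout; GFF3 I/O converts
# to 1-based inclusive at the boundary.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator and validates the
#' invariants: fractions in \\[0,1\\], fold changes >= 1, at least 30 exons so
#' that the ECD (exons 1-27) / TM (exon 28) / ICD (exons 29-34) domain
#' scheme fits.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param contig_length Toy contig length in bp.
#' @param exon_count Number of exons of the NOTCH1-like gene (>= 30).
#' @param strand Strand of the NOTCH1-like gene, `"-"` (default, matching
#'   the real locus) or `"+"`.
#' @param truncated_fraction Fraction of transcripts carrying the ECD-loss
#'   truncation in the coverage simulator.
#' @param depth Mean per-base coverage of the coverage simulator.
#' @param cells_per_type Named integer vector: nuclei per population
#'   (`tumour`, `mesangial`, `endothelial`).
#' @param ren_fold Planted tumour/mesangial fold excess of REN counts (>= 1).
#' @param notch1_fold Planted tumour fold excess of NOTCH1 counts (>= 1).
#' @param target_ratio_fold Planted tumour excess of NOTCH1 target genes
#'   relative to NRARP, defined on the log-normalised expression scale the
#'   ratio statistic measures (>= 1).
#' @param doublet_rate Fraction of extra barcodes that are doublets.
#' @param lowq_rate Fraction of extra barcodes that are low-quality cells.
#' @param nb_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param promoter_bp Promoter window, bp upstream of the TSS in transcript
#'   orientation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       contig_length = 3e6,
                       exon_count = 34L,
                       strand = "-",
                       truncated_fraction = 0.5,
                       depth = 100,
                       cells_per_type = c(tumour = 500L, mesangial = 300L, endothelial = 200L),
                       ren_fold = 3,
                       notch1_fold = 3,
                       target_ratio_fold = 4,
                       doublet_rate = 0.05,
                       lowq_rate = 0.05,
                       nb_dispersion = 2,
                       promoter_bp = 2000L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  strand <- match.arg(strand, c("-", "+"))
  exon_count <- as.integer(exon_count)
  if (exon_count < 30L) {
    stop("exon_count must be >= 30: the domain scheme needs exons 1-27 (ECD), ",
         "28 (TM) and 29-", exon_count, " (ICD)", call. = FALSE)
  }
  fracs <- c(truncated_fraction = truncated_fraction,
             doublet_rate = doublet_rate, lowq_rate = lowq_rate)
  bad <- fracs < 0 | fracs > 1
  if (any(bad)) {
    stop("fractions must lie in [0, 1]: ",
         paste(names(fracs)[bad], collapse = ", "), call. = FALSE)
  }
  folds <- c(ren_fold = ren_fold, notch1_fold = notch1_fold,
             target_ratio_fold = target_ratio_fold)
  if (any(folds < 1)) {
    stop("fold changes must be >= 1: ",
         paste(names(folds)[folds < 1], collapse = ", "), call. = FALSE)
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive", call. = FALSE)
  need <- c("tumour", "mesangial", "endothelial")
  if (!all(need %in% names(cells_per_type))) {
    stop("cells_per_type must name tumour, mesangial and endothelial", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), contig_length = contig_length,
    exon_count = exon_count, strand = strand,
    truncated_fraction = truncated_fraction, depth = depth,
    cells_per_type = vapply(cells_per_type[need], as.integer, integer(1)),
    ren_fold = ren_fold, notch1_fold = notch1_fold,
    target_ratio_fold = target_ratio_fold,
    doublet_rate = doublet_rate, lowq_rate = lowq_rate,
    nb_dispersion = nb_dispersion, promoter_bp = as.integer(promoter_bp)
  ), class = "sim_config")
}

# deterministic pseudo-varied exon/intron lengths (no RNG: the locus
# geometry is part of the stated world, not a random draw)
.exon_lengths <- function(n) {
  len <- 140L + (seq_len(n) * 37L) %% 160L
  len[n] <- 2000L  # terminal exon carries the 3' UTR
  len
}
.intron_lengths <- function(n) 600L + (seq_len(n) * 101L) %% 1200L

# lay out a gene from its TSS along transcript orientation; returns exon
# data.frame in transcript order, 0-based half-open genomic coords
.layout_gene <- function(gene, tss, strand, exon_len, intron_len, domain = NULL) {
  n <- length(exon_len)
  if (is.null(domain)) domain <- rep("none", n)
  starts <- integer(n)
  pos <- tss
  dir <- if (strand == "+") 1L else -1L
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (dir == 1L) {
      s <- pos; e <- pos + exon_len[i]
    } else {
      e <- pos; s <- pos - exon_len[i]
    }
    out[[i]] <- data.frame(gene = gene, exon_index = i, start = s, end = e,
                           domain = domain[i], stringsAsFactors = FALSE)
    pos <- if (dir == 1L) e + intron_len[min(i, length(intron_len))]
           else s - intron_len[min(i, length(intron_len))]
  }
  do.call(rbind, out)
}

#' Build the toy gene/domain model
#'
#' Constructs a single-contig model with (i) a NOTCH1-like gene of
#' `exon_count` exons numbered in transcript order, domain labels ECD on
#' exons 1-27, TM on exon 28 only, ICD on exons 29 and beyond; (ii) an
#' NRARP-like two-exon gene placed ~0.8 Mb beyond the NOTCH1-like
#' transcript 5' end (the higher-coordinate side on the default minus
#' strand, mirroring the 9q locus); (iii) a REN-like gene and two decoy
#' genes elsewhere on the contig. Every gene carries a promoter window of
#' `promoter_bp` upstream of its TSS in transcript orientation.
#'
#' @param config A [sim_config()].
#' @return A `gene_model` object: list with `contig`, `contig_length`,
#'   `genes` (footprints, strands, promoters) and `exons` (transcript-ordered
#'   exon table with domain labels), all 0-based half-open.
#' @export
make_gene_model <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$exon_count
  strand <- config$strand
  prom <- config$promoter_bp
  contig <- "toy9q"

  exl <- .exon_lengths(n)
  inl <- .intron_lengths(n - 1L)
  gene_span <- sum(exl) + sum(inl)
  spacer <- 8e5  # NRARP-like gene sits ~0.8 Mb beyond the transcript 5' end
  # fixed layout tops out at the DCY2 locus (~2.61 Mb) plus promoter margin
  needed <- 2.61e6 + prom + 1e4
  if (config$contig_length < needed) {
    stop(sprintf(
      "contig_length %.0f too small for the locus: need >= %.0f (deficit %.0f bp)",
      config$contig_length, needed, needed - config$contig_length), call. = FALSE)
  }

  domain <- c(rep("ECD", 27L), "TM", rep("ICD", n - 28L))
  if (strand == "-") {
    tss_notch <- 1.05e6
  } else {
    tss_notch <- 1.0e6
  }
  ex_notch <- .layout_gene("NOTCH1L", tss_notch, strand, exl, inl, domain)

  dirn <- if (strand == "+") 1L else -1L
  # NRARP-like gene: spacer bp beyond the 5' (transcript) end of NOTCH1L,
  # with its TSS (hence promoter) on the NOTCH1L-facing side so that a
  # deletion arriving from the NOTCH1L side can end inside the promoter
  # without consuming the gene body, while a deletion reaching ~3 kb further
  # encompasses the whole gene
  strand_nrarp <- if (strand == "-") "+" else "-"
  tss_nrarp <- tss_notch - dirn * spacer
  ex_nrarp <- .layout_gene("NRARPL", tss_nrarp, strand_nrarp,
                           c(300L, 700L), 1100L)

  ex_ren <- .layout_gene("RENL", 2.3e6, "+", rep(250L, 10L), rep(900L, 9L))
  ex_d1 <- .layout_gene("DCY1", 2.45e6, "+", rep(200L, 6L), rep(700L, 5L))
  ex_d2 <- .layout_gene("DCY2", 2.6e6, "-", rep(200L, 6L), rep(700L, 5L))

  exons <- rbind(ex_notch, ex_nrarp, ex_ren, ex_d1, ex_d2)
  if (any(exons$start < 0 | exons$end > config$contig_length)) {
    stop("internal layout error: exon outside contig", call. = FALSE)
  }

  strands <- c(NOTCH1L = strand, NRARPL = strand_nrarp, RENL = "+",
               DCY1 = "+", DCY2 = "-")
  classes <- c(NOTCH1L = "notch1_like", NRARPL = "regulator",
               RENL = "ren_like", DCY1 = "decoy", DCY2 = "decoy")
  genes <- do.call(rbind, lapply(names(strands), function(g) {
    ex <- exons[exons$gene == g, ]
    s <- min(ex$start); e <- max(ex$end)
    if (strands[[g]] == "+") {
      ps <- s - prom; pe <- s
    } else {
      ps <- e; pe <- e + prom
    }
    data.frame(gene = g, strand = strands[[g]], start = s, end = e,
               promoter_start = ps, promoter_end = pe,
               class = classes[[g]], stringsAsFactors = FALSE)
  }))
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(contig = contig, contig_length = config$contig_length,
                 genes = genes, exons = exons, promoter_bp = prom),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model on", x$contig, sprintf("(%.1f Mb)\n", x$contig_length / 1e6))
  for (i in seq_len(nrow(x$genes))) {
    g <- x$genes[i, ]
    nex <- sum(x$exons$gene == g$gene)
    cat(sprintf("  %-8s %s [%d, %d) %d exons (%s)\n", g$gene, g$strand,
                g$start, g$end, nex, g$class))
  }
  invisible(x)
}

# transcript-ordered exon table for one gene
model_exons <- function(model, gene) {
  ex <- model$exons[model$exons$gene == gene, ]
  if (nrow(ex) == 0L) stop("gene '", gene, "' absent from model", call. = FALSE)
  ex[order(ex$exon_index), ]
}

# gene row, erroring if absent
model_gene <- function(model, gene) {
  g <- model$genes[model$genes$gene == gene, ]
  if (nrow(g) == 0L) stop("gene '", gene, "' absent from model", call. = FALSE)
  g
}

# the single gene of a class (notch1_like / regulator / ren_like)
model_gene_of_class <- function(model, class) {
  g <- model$genes$gene[model$genes$class == class]
  if (length(g) == 0L) stop("no gene of class '", class, "' in model", call. = FALSE)
  g[1L]
}

#' Locate genomic positions in the model
#'
#' Maps each position to its locus context: containing gene (if any), exon
#' index or intron index in transcript order (intron k lies between exons k
#' and k+1), domain label, and whether the position falls in a promoter
#' window. Interval lookup uses [IRanges::findOverlaps()]; every position
#' maps to exactly one context (intergenic is a valid answer).
#'
#' @param model A `gene_model`.
#' @param pos Integer vector of 0-based positions.
#' @param contig Contig name; must match the model's contig.
#' @return data.frame with columns `pos`, `gene`, `exon`, `intron`,
#'   `domain`, `in_promoter`.
#' @export
locate_breakpoint <- function(model, pos, contig = model$contig) {
  stopifnot(inherits(model, "gene_model"))
  if (!all(contig == model$contig)) {
    stop("breakend on unmodelled contig: ", paste(unique(setdiff(contig, model$contig)), collapse = ", "),
         call. = FALSE)
  }
  pos <- as.numeric(pos)
  q <- IRanges::IRanges(start = pos + 1L, width = 1L)  # to 1-based
  out <- data.frame(pos = pos, gene = NA_character_, exon = NA_integer_,
                    intron = NA_integer_, domain = NA_character_,
                    in_promoter = FALSE, stringsAsFactors = FALSE)

  # gene footprints
  gr <- IRanges::IRanges(start = model$genes$start + 1L, end = model$genes$end)
  hit <- IRanges::findOverlaps(q, gr, select = "first")
  out$gene <- model$genes$gene[hit]

  # exons
  er <- IRanges::IRanges(start = model$exons$start + 1L, end = model$exons$end)
  ehit <- IRanges::findOverlaps(q, er, select = "first")
  in_exon <- !is.na(ehit)
  out$exon[in_exon] <- model$exons$exon_index[ehit[in_exon]]
  out$domain[in_exon] <- model$exons$domain[ehit[in_exon]]
  out$gene[in_exon] <- model$exons$gene[ehit[in_exon]]

  # introns: inside a gene but not in an exon -> between transcript-ordered
  # exons k and k+1; intron index = number of exons on the TSS side
  intronic <- which(!is.na(out$gene) & !in_exon)
  for (i in intronic) {
    g <- out$gene[i]
    ex <- model_exons(model, g)
    strand <- model_gene(model, g)$strand
    p <- out$pos[i]
    if (strand == "+") {
      k <- sum(ex$end <= p)         # exons fully on the 5' side
    } else {
      k <- sum(ex$start >= p + 1L)  # on - strand 5' side is higher coords
    }
    out$intron[i] <- k
    out$domain[i] <- "none"
  }

  # promoter windows (may overlap gene bodies of neighbours; flag only)
  pr <- IRanges::IRanges(start = model$genes$promoter_start + 1L,
                         end = model$genes$promoter_end)
  phit <- IRanges::findOverlaps(q, pr, select = "first")
  out$in_promoter <- !is.na(phit)
  prom_gene <- model$genes$gene[phit]
  out$promoter_gene <- prom_gene
  out
}
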