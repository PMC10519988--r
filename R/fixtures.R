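# Fixture serialisation: GFF3 for the gene model (1-based inclusive at the
# boundary; internal coordinates are 0-based half-open), 10-column BEDPE for
# SVs (0-based half-open), TSVs for variant tables / coverage / CN segments,
# MatrixMarket + barcodes/features TSVs for counts, JSON for truth and the
# manifest.

#' Write a gene model to GFF3
#'
#' Emits gene, exon and promoter features; exon attributes carry
#' `exon_index` and `domain` (`ECD|TM|ICD|none`). Internal 0-based
#' half-open coordinates are converted to GFF3 1-based inclusive.
#'
#' @param model A `gene_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model_gff3 <- function(model, path) {
  stopifnot(inherits(model, "gene_model"))
  g <- model$genes
  ex <- model$exons
  gr_genes <- GenomicRanges::GRanges(
    seqnames = model$contig,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand, type = "gene", ID = g$gene,
    gene_class = g$class)
  gr_prom <- GenomicRanges::GRanges(
    seqnames = model$contig,
    ranges = IRanges::IRanges(start = g$promoter_start + 1L, end = g$promoter_end),
    strand = g$strand, type = "promoter", ID = paste0(g$gene, "_promoter"),
    Parent = g$gene)
  strand_of <- g$strand[match(ex$gene, g$gene)]
  gr_ex <- GenomicRanges::GRanges(
    seqnames = model$contig,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = strand_of, type = "exon",
    ID = sprintf("%s_exon%d", ex$gene, ex$exon_index),
    Parent = ex$gene, exon_index = ex$exon_index, domain = ex$domain)
  all <- suppressWarnings(c(gr_genes, gr_prom, gr_ex))
  S4Vectors::metadata(all) <- list(contig_length = model$contig_length)
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Read a gene model from GFF3
#'
#' Inverse of [write_gene_model_gff3()]; converts back to internal 0-based
#' half-open coordinates.
#'
#' @param path GFF3 path.
#' @param contig_length Contig length (bp); recorded in the model.
#' @return A `gene_model`.
#' @export
read_gene_model_gff3 <- function(path, contig_length = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes_df <- df[df$type == "gene", ]
  prom_df <- df[df$type == "promoter", ]
  ex_df <- df[df$type == "exon", ]
  parent_chr <- function(p) vapply(p, function(v) as.character(v)[1], character(1))
  prom_parent <- parent_chr(prom_df$Parent)
  genes <- data.frame(
    gene = genes_df$ID, strand = as.character(genes_df$strand),
    start = genes_df$start - 1L, end = genes_df$end,
    promoter_start = prom_df$start[match(genes_df$ID, prom_parent)] - 1L,
    promoter_end = prom_df$end[match(genes_df$ID, prom_parent)],
    class = genes_df$gene_class, stringsAsFactors = FALSE)
  exons <- data.frame(
    gene = parent_chr(ex_df$Parent),
    exon_index = as.integer(ex_df$exon_index),
    start = ex_df$start - 1L, end = ex_df$end,
    domain = ex_df$domain, stringsAsFactors = FALSE)
  exons <- exons[order(match(exons$gene, genes$gene), exons$exon_index), ]
  rownames(exons) <- rownames(genes) <- NULL
  contig <- as.character(df$seqnames[1])
  if (is.null(contig_length)) contig_length <- max(genes$promoter_end, genes$end) + 1e5
  prom_bp <- unique(genes$promoter_end - genes$promoter_start)[1]
  structure(list(contig = contig, contig_length = contig_length,
                 genes = genes, exons = exons, promoter_bp = prom_bp),
            class = "gene_model")
}

#' Write rearrangement records to 10-column BEDPE
#'
#' Standard BEDPE: 0-based half-open breakend intervals, strands in columns
#' 9-10; extra columns carry `sv_class`, `cluster`, `assembly_score`,
#' `reads`, `sample_type`, `truth`.
#'
#' @param sv data.frame of rearrangement records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(sv, path) {
  sv <- sv[sv$class == "rearrangement", , drop = FALSE]
  bed <- data.frame(
    chrom1 = sv$contig, start1 = format(sv$pos, scientific = FALSE, trim = TRUE),
    end1 = format(sv$pos + 1, scientific = FALSE, trim = TRUE),
    chrom2 = sv$contig2, start2 = format(sv$pos2, scientific = FALSE, trim = TRUE),
    end2 = format(sv$pos2 + 1, scientific = FALSE, trim = TRUE),
    name = sv$id, score = 0L, strand1 = sv$strand1, strand2 = sv$strand2,
    sv_class = sv$sv_class, cluster = sv$cluster,
    assembly_score = sv$assembly_score, reads = sv$supporting_reads,
    sample_type = sv$sample_type,
    truth = if ("truth" %in% names(sv)) sv$truth else NA,
    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read rearrangement records from BEDPE
#'
#' @param path BEDPE path written by [write_bedpe()].
#' @return data.frame of rearrangement records (internal representation).
#' @export
read_bedpe <- function(path) {
  bed <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(
    id = bed$name, class = "rearrangement", sv_class = bed$sv_class,
    contig = bed$chrom1, pos = bed$start1, contig2 = bed$chrom2,
    pos2 = bed$start2, strand1 = bed$strand1, strand2 = bed$strand2,
    cluster = bed$cluster, asmd = NA_real_, clpm = NA_real_,
    quality = NA_real_, assembly_score = bed$assembly_score,
    supporting_reads = bed$reads, sample_type = bed$sample_type,
    truth = if ("truth" %in% names(bed)) bed$truth else NA_character_,
    stringsAsFactors = FALSE)
}

#' Write a nucleus count matrix as MatrixMarket + TSVs
#'
#' Writes `counts.mtx`, `features.tsv` (gene, mito flag), `barcodes.tsv`
#' and `cell_metadata.tsv` into `dir`.
#'
#' @param x A `nucleus_counts` object.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "nucleus_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.mtx", "features.tsv", "barcodes.tsv",
                            "cell_metadata.tsv"))
  Matrix::writeMM(x$counts, paths[1])
  utils::write.table(x$gene_meta, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(colnames(x$counts), paths[3])
  utils::write.table(x$cell_meta, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a nucleus count matrix written by [write_counts_mtx()]
#'
#' @param dir Directory containing the four files.
#' @return A `nucleus_counts` object.
#' @export
read_counts_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")), "CsparseMatrix")
  gene_meta <- utils::read.delim(file.path(dir, "features.tsv"),
                                 stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  cell_meta <- utils::read.delim(file.path(dir, "cell_metadata.tsv"),
                                 stringsAsFactors = FALSE)
  dimnames(m) <- list(gene_meta$gene, barcodes)
  structure(list(counts = m, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "nucleus_counts")
}

#' Write the complete fixture set for a configuration
#'
#' Generates and serialises every pipeline input: gene model (GFF3), SV
#' callsets per scenario (BEDPE), small-variant table (TSV), CN segments
#' (TSV), exon coverage (TSV), single-nucleus counts (MTX + TSVs), truth
#' JSON and a manifest listing files and the seed.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param scenarios SV scenarios to emit.
#' @return The manifest (list), invisibly. Also written as `manifest.json`.
#' @export
write_fixtures <- function(config, dir,
                           scenarios = c("case1", "case2", "decoys", "artifacts")) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  }
  model <- make_gene_model(config)
  files <- character(0)
  wr <- function(name) { files <<- c(files, name); file.path(dir, name) }

  write_gene_model_gff3(model, wr("model.gff3"))

  truth <- list(seed = config$seed, scenarios = list())
  small <- list()
  for (sc in scenarios) {
    sv <- simulate_sv_callset(model, sc, seed = config$seed)
    rearr <- sv[sv$class == "rearrangement", , drop = FALSE]
    if (nrow(rearr) > 0L) write_bedpe(rearr, wr(sprintf("sv_%s.bedpe", sc)))
    sm <- sv[sv$class != "rearrangement", , drop = FALSE]
    if (nrow(sm) > 0L) small[[sc]] <- sm
    truth$scenarios[[sc]] <- unique(sv$truth)
  }
  if (length(small) > 0L) {
    utils::write.table(do.call(rbind, small), wr("small_variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cn <- simulate_cn_segments(model, "case1", seed = config$seed)
  utils::write.table(cn, wr("cn_segments.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cov <- simulate_exon_coverage(model, config$truncated_fraction,
                                config$depth, seed = config$seed)
  utils::write.table(cov, wr("exon_coverage.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth$truncated_fraction <- config$truncated_fraction

  counts <- simulate_counts(config)
  write_counts_mtx(counts, file.path(dir, "snrna"))
  files <- c(files, file.path("snrna", c("counts.mtx", "features.tsv",
                                         "barcodes.tsv", "cell_metadata.tsv")))
  truth$cells_per_type <- as.list(config$cells_per_type)
  truth$n_doublet <- sum(counts$cell_meta$type == "doublet")
  truth$n_lowq <- sum(counts$cell_meta$type == "lowq")
  truth$folds <- list(ren = config$ren_fold, notch1 = config$notch1_fold,
                      target_ratio = config$target_ratio_fold)

  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, "truth.json")

  manifest <- list(seed = config$seed, files = files,
                   created = "notchtrunc fixtures")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
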