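# Per-exon coverage normalisation and the intracellular/extracellular
# domain expression ratio.
#
# The coverage model: a fraction p of transcripts carry the ECD-loss
# truncation (single-deletion geometry) and so contribute reads only to the
# TM and ICD exons; wildtype transcripts cover all exons. Per-exon read-base
# counts are Poisson with mean depth * length (full exons) or
# depth * length * (1 - p) (ECD exons).

#' Simulate an exon coverage track
#'
#' @param model A `gene_model`.
#' @param truncated_fraction Fraction p of transcripts truncated (ECD lost).
#' @param depth Mean wildtype per-base coverage.
#' @param seed Integer seed.
#' @param gene Gene to simulate; defaults to the NOTCH1-class gene.
#' @param sample,group Identifiers recorded in the track.
#' @return data.frame (`exon_coverage` track): `gene`, `exon_index`,
#'   `count` (read-bases), `length`, `library_size`, `sample`, `group`.
#' @export
simulate_exon_coverage <- function(model, truncated_fraction, depth, seed = 1L,
                                   gene = NULL, sample = "S1", group = "tumour") {
  stopifnot(inherits(model, "gene_model"))
  p <- truncated_fraction
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("truncated_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(gene)) gene <- model_gene_of_class(model, "notch1_like")
  ex <- model_exons(model, gene)
  len <- ex$end - ex$start
  frac <- ifelse(ex$domain == "ECD", 1 - p, 1)
  counts <- with_seed(seed, stats::rpois(nrow(ex), depth * len * frac))
  # library size: read-base total of the gene plus a fixed background
  # representing the rest of the transcriptome (ratio is invariant to it)
  lib <- 1e6 + round(sum(counts) / 100)
  data.frame(gene = gene, exon_index = ex$exon_index, count = counts,
             length = len, library_size = lib, sample = sample,
             group = group, stringsAsFactors = FALSE)
}

#' Normalise per-exon coverage
#'
#' `value_e = (count_e / length_e) / (library_size / 1e6)`: per-base depth
#' per million mapped reads, per exon.
#'
#' @param track An exon coverage track (see [simulate_exon_coverage()]).
#' @return The track with a `normalized` column appended.
#' @export
normalize_exon_coverage <- function(track) {
  req <- c("exon_index", "count", "length", "library_size")
  if (!all(req %in% names(track))) {
    stop("coverage track needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(track$library_size <= 0)) stop("library size must be > 0", call. = FALSE)
  if (any(track$length <= 0)) stop("exon lengths must be > 0", call. = FALSE)
  track$normalized <- (track$count / track$length) / (track$library_size / 1e6)
  track
}

#' Intracellular/extracellular domain expression ratio
#'
#' Ratio of mean per-base normalised coverage over the ICD exons to the
#' same over the ECD exons. The default `mode = "mean"` averages the
#' per-exon normalised values unweighted (matching per-exon plotting);
#' `mode = "pooled"` pools read-bases and bases across each domain before
#' dividing.
#'
#' @param track An exon coverage track.
#' @param icd_exons,ecd_exons Exon index sets (defaults 29-34 and 1-27).
#' @param mode `"mean"` (default) or `"pooled"`.
#' @return The ratio (dimensionless). Zero ECD coverage returns `Inf` with
#'   attribute `zero_denominator = TRUE` and a warning, never a silent
#'   division.
#' @export
domain_ratio <- function(track, icd_exons = 29:34, ecd_exons = 1:27,
                         mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  if (length(intersect(icd_exons, ecd_exons)) > 0L) {
    stop("ICD and ECD exon sets must be disjoint", call. = FALSE)
  }
  missing_ex <- setdiff(c(icd_exons, ecd_exons), track$exon_index)
  if (length(missing_ex) > 0L) {
    stop("exons absent from track: ", paste(missing_ex, collapse = ", "), call. = FALSE)
  }
  track <- normalize_exon_coverage(track)
  icd <- track[track$exon_index %in% icd_exons, ]
  ecd <- track[track$exon_index %in% ecd_exons, ]
  if (mode == "mean") {
    num <- mean(icd$normalized)
    den <- mean(ecd$normalized)
  } else {
    num <- sum(icd$count) / sum(icd$length)
    den <- sum(ecd$count) / sum(ecd$length)
  }
  if (den == 0) {
    warning("zero ECD coverage: returning Inf ratio sentinel")
    return(structure(Inf, zero_denominator = TRUE))
  }
  num / den
}

#' Compare domain ratios between sample groups
#'
#' Two-sided Wilcoxon rank-sum test of each group against the reference
#' group, Benjamini-Hochberg adjusted across the comparisons. A thin wrapper
#' over [compare_ratio_groups()] for ratio tables.
#'
#' @param ratio_table data.frame with columns `ratio` and `group` (one row
#'   per sample).
#' @param reference Reference group label.
#' @return data.frame of test results (see [compare_ratio_groups()]).
#' @export
compare_domain_ratios <- function(ratio_table, reference) {
  stopifnot(all(c("ratio", "group") %in% names(ratio_table)))
  compare_ratio_groups(ratio_table$ratio, ratio_table$group, reference = reference)
}
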