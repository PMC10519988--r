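# Breakpoint-consequence annotation: NOTCH1-class activating truncations,
# negative-regulator disruption, and the rule-based driver annotation for
# small variants, copy number and rearrangements.

# all breakend positions of a cluster of rearrangement records
.cluster_breakends <- function(cluster) {
  c(cluster$pos, cluster$pos2)
}

# does interval [a, b) overlap [s, e)?
.ov <- function(a, b, s, e) a < e & b > s

#' Classify a rearrangement cluster against the NOTCH1-class gene
#'
#' A cluster is called `activating_truncation` when a deletion breakpoint in
#' transcript orientation falls within the extracellular (ECD) exons or
#' introns of the gene while every intracellular-domain (ICD) exon survives
#' on the retained allele. The transmembrane status is `spared` only when
#' the TM exon and both flanking introns are untouched by every cluster
#' member; an inversion breakend in either flanking intron (bracketing the
#' TM exon) makes it `unknown`, and a breakend inside or a deletion over the
#' TM exon makes it `involved`. `tm_status = "spared"` implies the lesion is
#' a gamma-secretase-inhibitor candidate; an activating truncation with TM
#' involved/unknown falls back to targeting the downstream transcription
#' activation complex.
#'
#' @param model A `gene_model`.
#' @param cluster data.frame of rearrangement records sharing a cluster id
#'   (columns `sv_class`, `pos`, `pos2`, `contig`).
#' @param gene NOTCH1-class gene name; defaults to the model's
#'   `notch1_like` gene.
#' @return A `consequence_call` list: `gene`, `category`,
#'   `retained_domains`, `tm_status`, `targetability`.
#' @export
classify_truncation <- function(model, cluster, gene = NULL) {
  stopifnot(inherits(model, "gene_model"), is.data.frame(cluster),
            nrow(cluster) > 0L)
  if (is.null(gene)) gene <- model_gene_of_class(model, "notch1_like")
  ex <- model_exons(model, gene)
  g <- model_gene(model, gene)
  n_ex <- nrow(ex)
  tm_idx <- which(ex$domain == "TM")
  if (length(tm_idx) != 1L) {
    stop("gene '", gene, "' must have exactly one TM exon", call. = FALSE)
  }
  # locating errors on unmodelled contigs
  ends <- .cluster_breakends(cluster)
  ctx <- locate_breakpoint(model, ends,
                           contig = c(cluster$contig, cluster$contig2))

  dels <- cluster[cluster$sv_class == "deletion", , drop = FALSE]
  invs <- cluster[cluster$sv_class == "inversion", , drop = FALSE]

  ecd_exons <- ex$exon_index[ex$domain == "ECD"]
  icd_exons <- ex[ex$domain == "ICD", , drop = FALSE]

  in_gene_ctx <- ctx[!is.na(ctx$gene) & ctx$gene == gene, , drop = FALSE]

  # activating truncation: a deletion breakend in ECD exons or introns
  # internal to the ECD run (introns 1..26) or the ECD/TM boundary intron,
  # with all ICD exons outside every deletion interval
  activating <- FALSE
  deleted_exons <- integer(0)
  if (nrow(dels) > 0L) {
    for (i in seq_len(nrow(dels))) {
      a <- dels$pos[i]; b <- dels$pos2[i]
      bctx <- locate_breakpoint(model, c(a, b))
      in_ecd <- !is.na(bctx$gene) & bctx$gene == gene &
        ((!is.na(bctx$exon) & bctx$exon %in% ecd_exons) |
           (!is.na(bctx$intron) & bctx$intron < tm_idx))
      icd_hit <- any(.ov(a, b, icd_exons$start, icd_exons$end))
      if (any(in_ecd) && !icd_hit) activating <- TRUE
      deleted_exons <- union(deleted_exons,
                             ex$exon_index[.ov(a, b, ex$start, ex$end)])
    }
  }

  retained <- ex[!ex$exon_index %in% deleted_exons, , drop = FALSE]
  retained_domains <- unique(retained$domain)

  # transmembrane status
  tm_ex <- ex[tm_idx, ]
  flank_introns <- c(tm_idx - 1L, tm_idx)  # introns bracketing the TM exon
  touch_tm <- !is.na(ctx$gene) & ctx$gene == gene &
    ((!is.na(ctx$exon) & ctx$exon == tm_idx) |
       (!is.na(ctx$intron) & ctx$intron %in% flank_introns))
  tm_deleted <- nrow(dels) > 0L &&
    any(.ov(dels$pos, dels$pos2, tm_ex$start, tm_ex$end))
  tm_exon_breakend <- any(!is.na(ctx$gene) & ctx$gene == gene &
                            !is.na(ctx$exon) & ctx$exon == tm_idx)
  tm_status <- if (tm_deleted || tm_exon_breakend) {
    "involved"
  } else if (any(touch_tm)) {
    "unknown"
  } else {
    "spared"
  }

  in_gene_any <- nrow(in_gene_ctx) > 0L
  category <- if (activating) {
    "activating_truncation"
  } else if (nrow(invs) > 0L && in_gene_any) {
    "intragenic_inversion"
  } else if (in_gene_any) {
    "other"
  } else {
    "intergenic"
  }

  targetability <- if (category == "activating_truncation") {
    if (tm_status == "spared") "gamma_secretase_candidate"
    else "transcription_complex_candidate"
  } else {
    "none"
  }

  structure(list(gene = gene, category = category,
                 retained_domains = retained_domains,
                 tm_status = tm_status, targetability = targetability),
            class = "consequence_call")
}

#' @export
print.consequence_call <- function(x, ...) {
  cat(sprintf("consequence_call: %s %s (tm %s, %s; retained: %s)\n",
              x$gene, x$category, x$tm_status, x$targetability,
              paste(x$retained_domains, collapse = ",")))
  invisible(x)
}

#' Annotate disruption of the negative-regulator gene
#'
#' Reports `regulator_whole_gene_deleted` when some deletion interval
#' contains the full gene footprint, otherwise `regulator_promoter_hit`
#' when any cluster breakend lies in the regulator's promoter window,
#' otherwise `regulator_intact`.
#'
#' @param model A `gene_model`.
#' @param cluster data.frame of rearrangement records.
#' @param regulator Regulator gene name; defaults to the model's
#'   `regulator`-class gene.
#' @return list with `gene` and `category`.
#' @export
annotate_regulator <- function(model, cluster, regulator = NULL) {
  stopifnot(inherits(model, "gene_model"), is.data.frame(cluster))
  if (is.null(regulator)) regulator <- model_gene_of_class(model, "regulator")
  g <- model_gene(model, regulator)
  dels <- cluster[cluster$sv_class == "deletion", , drop = FALSE]
  whole <- nrow(dels) > 0L &&
    any(dels$pos <= g$start & dels$pos2 >= g$end)
  if (whole) {
    return(list(gene = regulator, category = "regulator_whole_gene_deleted"))
  }
  ends <- .cluster_breakends(cluster)
  in_prom <- ends >= g$promoter_start & ends < g$promoter_end
  if (any(in_prom)) {
    return(list(gene = regulator, category = "regulator_promoter_hit"))
  }
  list(gene = regulator, category = "regulator_intact")
}

#' Annotate somatic driver events by rule
#'
#' Implements the rule set: (i) missense or in-frame indel at a canonical
#' oncogene hotspot (exact position match against the supplied table);
#' (ii) truncating small variant or rearrangement breakend disrupting the
#' footprint of a recessive cancer gene; (iii) focal (<1 Mb) homozygous
#' deletion (total copy number 0) over a recessive gene; (iv) focal
#' amplification with copy number >4 (diploid context) or >8 (tetraploid)
#' over an oncogene; (v) rearrangement generating a known oncogenic fusion.
#'
#' @param model A `gene_model` providing gene footprints.
#' @param variants data.frame of variant records; small variants may carry a
#'   `consequence` column (`missense`, `inframe_indel`, `truncating`) and
#'   rearrangements an optional `fusion` column (`"GENEA-GENEB"`).
#' @param cn_segments data.frame with `contig`, `start`, `end`, `total_cn`,
#'   `ploidy` (`diploid` or `tetraploid`).
#' @param gene_table data.frame with `gene`, `role` (`oncogene`/`recessive`)
#'   and optional `hotspots` (comma-separated 0-based positions).
#' @param known_fusions character vector of oncogenic fusion names.
#' @return data.frame of driver calls: `type`, `gene`, `detail`.
#' @export
call_drivers <- function(model, variants, cn_segments, gene_table,
                         known_fusions = character()) {
  stopifnot(is.data.frame(gene_table), all(c("gene", "role") %in% names(gene_table)))
  if (!all(gene_table$role %in% c("oncogene", "recessive"))) {
    stop("gene_table roles must be 'oncogene' or 'recessive'", call. = FALSE)
  }
  drivers <- list()
  add <- function(type, gene, detail) {
    drivers[[length(drivers) + 1L]] <<- data.frame(
      type = type, gene = gene, detail = detail, stringsAsFactors = FALSE)
  }
  foot <- function(gene) model_gene(model, gene)

  if (!is.null(variants) && nrow(variants) > 0L) {
    cons <- if ("consequence" %in% names(variants)) variants$consequence
            else rep(NA_character_, nrow(variants))
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      if (v$class %in% c("substitution", "indel")) {
        ctx <- locate_breakpoint(model, v$pos, v$contig)
        vg <- ctx$gene
        if (is.na(vg)) next
        entry <- gene_table[gene_table$gene == vg, , drop = FALSE]
        if (nrow(entry) == 0L) next
        cq <- cons[i]
        if (!is.na(cq) && cq %in% c("missense", "inframe_indel") &&
            entry$role == "oncogene" && "hotspots" %in% names(entry) &&
            !is.na(entry$hotspots) && nzchar(entry$hotspots)) {
          hs <- as.numeric(strsplit(entry$hotspots, ",")[[1]])
          if (v$pos %in% hs) add("hotspot_variant", vg, v$id)
        }
        if (!is.na(cq) && cq == "truncating" && entry$role == "recessive") {
          add("recessive_truncating", vg, v$id)
        }
      } else if (v$class == "rearrangement") {
        if ("fusion" %in% names(v) && !is.na(v$fusion) &&
            v$fusion %in% known_fusions) {
          add("oncogenic_fusion", v$fusion, v$id)
          next
        }
        rec_genes <- gene_table$gene[gene_table$role == "recessive"]
        for (rg in rec_genes) {
          gf <- foot(rg)
          ends <- c(v$pos, v$pos2)
          if (any(ends > gf$start & ends < gf$end)) {
            add("recessive_breakend", rg, v$id)
          }
        }
      }
    }
  }

  if (!is.null(cn_segments) && nrow(cn_segments) > 0L) {
    if (!all(cn_segments$ploidy %in% c("diploid", "tetraploid"))) {
      bad <- setdiff(unique(cn_segments$ploidy), c("diploid", "tetraploid"))
      stop("unknown ploidy context: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    for (i in seq_len(nrow(cn_segments))) {
      seg <- cn_segments[i, ]
      focal <- (seg$end - seg$start) < 1e6
      if (!focal) next
      amp_thresh <- if (seg$ploidy == "diploid") 4 else 8
      for (j in seq_len(nrow(gene_table))) {
        gt <- gene_table[j, ]
        gf <- tryCatch(foot(gt$gene), error = function(e) NULL)
        if (is.null(gf)) next
        if (!.ov(seg$start, seg$end, gf$start, gf$end)) next
        if (gt$role == "recessive" && seg$total_cn == 0) {
          add("homozygous_deletion", gt$gene,
              sprintf("%.0f-%.0f", seg$start, seg$end))
        }
        if (gt$role == "oncogene" && seg$total_cn > amp_thresh) {
          add("amplification", gt$gene,
              sprintf("CN=%g (%s)", seg$total_cn, seg$ploidy))
        }
      }
    }
  }

  if (length(drivers) == 0L) {
    return(data.frame(type = character(0), gene = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, drivers))
}

#' Full consequence annotation of an SV callset
#'
#' Groups rearrangement records by cluster id and reports, per cluster, the
#' NOTCH1-class truncation call and the regulator disruption call.
#'
#' @param model A `gene_model`.
#' @param sv data.frame of rearrangement records with a `cluster` column.
#' @return data.frame: one row per cluster with `cluster`, `category`,
#'   `tm_status`, `targetability`, `regulator`, plus a `truth` column when
#'   present in the input.
#' @export
sv_consequence <- function(model, sv) {
  stopifnot(is.data.frame(sv), nrow(sv) > 0L)
  sv <- sv[sv$class == "rearrangement", , drop = FALSE]
  out <- lapply(unique(sv$cluster), function(cl) {
    cluster <- sv[sv$cluster == cl, , drop = FALSE]
    tc <- classify_truncation(model, cluster)
    rg <- annotate_regulator(model, cluster)
    data.frame(cluster = cl, gene = tc$gene, category = tc$category,
               tm_status = tc$tm_status, targetability = tc$targetability,
               retained_domains = paste(tc$retained_domains, collapse = ","),
               regulator = rg$category,
               truth = if ("truth" %in% names(cluster)) cluster$truth[1L] else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
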