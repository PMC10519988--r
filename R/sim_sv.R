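# Simulated somatic callsets: breakpoint configurations mimicking the two
# observed tumour genotypes (a single ~0.8 Mb deletion; an intragenic
# inversion bracketing the TM exon plus a regulator-encompassing deletion),
# decoy SVs, and quality-filter artifact records.

# midpoint of intron k (between transcript-ordered exons k and k+1),
# 0-based coordinate
.intron_mid <- function(model, gene, k) {
  ex <- model_exons(model, gene)
  if (k < 1L || k >= nrow(ex)) stop("no intron ", k, " in ", gene, call. = FALSE)
  g <- model_gene(model, gene)
  if (g$strand == "+") {
    lo <- ex$end[k]; hi <- ex$start[k + 1L]
  } else {
    lo <- ex$end[k + 1L]; hi <- ex$start[k]
  }
  as.integer(floor((lo + hi) / 2))
}

.sv_record <- function(id, sv_class, contig, pos1, pos2, cluster,
                       sample_type = "tumour", assembly_score = 95,
                       supporting_reads = 30L, truth = NA_character_) {
  p <- sort(c(pos1, pos2))
  data.frame(id = id, class = "rearrangement", sv_class = sv_class,
             contig = contig, pos = p[1L], contig2 = contig, pos2 = p[2L],
             strand1 = "+", strand2 = if (sv_class == "inversion") "+" else "-",
             cluster = cluster, asmd = NA_real_, clpm = NA_real_,
             quality = NA_real_, assembly_score = assembly_score,
             supporting_reads = supporting_reads, sample_type = sample_type,
             truth = truth, stringsAsFactors = FALSE)
}

.small_record <- function(id, class, contig, pos, asmd = 160, clpm = 0,
                          quality = 500, sample_type = "tumour",
                          truth = NA_character_) {
  data.frame(id = id, class = class, sv_class = NA_character_,
             contig = contig, pos = pos, contig2 = NA_character_,
             pos2 = NA_real_, strand1 = NA_character_, strand2 = NA_character_,
             cluster = NA_character_, asmd = asmd, clpm = clpm,
             quality = quality, assembly_score = NA_real_,
             supporting_reads = 40L, sample_type = sample_type,
             truth = truth, stringsAsFactors = FALSE)
}

#' Simulate a somatic SV callset with planted truth
#'
#' Scenarios:
#' \describe{
#'   \item{`case1`}{One deletion whose 5' (transcript-orientation) breakpoint
#'     lies in an ECD intron of the NOTCH1-like gene and whose 3' breakpoint
#'     lies inside the regulator's promoter window. Truth label
#'     `activating_truncation+regulator_promoter_hit`.}
#'   \item{`case2`}{An intragenic inversion with breakends in introns 27 and
#'     28 (bracketing the TM exon) plus a deletion from an ECD intron to just
#'     beyond the regulator gene, encompassing it entirely. Truth label
#'     `activating_truncation+regulator_whole_gene_deleted`.}
#'   \item{`decoys`}{Intergenic and decoy-gene SVs that pass the quality
#'     filters but have no NOTCH1-class consequence.}
#'   \item{`artifacts`}{One record per quality rule, each engineered to fail
#'     exactly that rule (ASMD, CLPM, indel quality, rearrangement read
#'     support).}
#' }
#'
#' @param model A `gene_model`.
#' @param scenario One of `"case1"`, `"case2"`, `"decoys"`, `"artifacts"`.
#' @param seed Integer seed (jitters breakpoint placement within introns).
#' @return data.frame of variant records with a `truth` column.
#' @export
simulate_sv_callset <- function(model, scenario, seed = 1L) {
  stopifnot(inherits(model, "gene_model"))
  scenario <- as.character(scenario)
  if (!scenario %in% c("case1", "case2", "decoys", "artifacts")) {
    stop("unknown scenario: ", scenario, call. = FALSE)
  }
  notch <- model_gene_of_class(model, "notch1_like")
  reg <- model_gene_of_class(model, "regulator")
  greg <- model_gene(model, reg)
  gnotch <- model_gene(model, notch)
  contig <- model$contig
  n_ex <- nrow(model_exons(model, notch))

  with_seed(seed, {
    if (scenario == "case1") {
      # 5' breakpoint inside an ECD intron (intron 3..8), 3' inside the
      # regulator promoter
      k <- sample(3:8, 1L)
      a <- .intron_mid(model, notch, k)
      prom_mid <- floor((greg$promoter_start + greg$promoter_end) / 2)
      b <- as.integer(prom_mid + sample(-300:300, 1L))
      rec <- .sv_record("sv_case1_del", "deletion", contig, a, b, "cl1",
                        truth = "activating_truncation+regulator_promoter_hit")
      return(rec)
    }
    if (scenario == "case2") {
      k <- sample(2:6, 1L)
      a <- .intron_mid(model, notch, k)
      # deletion reaches ~200 bp beyond the regulator's far (non-promoter)
      # end, encompassing the entire gene; ends ~3 kb past the case-1 end
      far <- if (gnotch$strand == "-") greg$end + 200L else greg$start - 200L
      del <- .sv_record("sv_case2_del", "deletion", contig, a, far, "cl2",
                        truth = "activating_truncation+regulator_whole_gene_deleted")
      inv <- .sv_record("sv_case2_inv", "inversion", contig,
                        .intron_mid(model, notch, 27L),
                        .intron_mid(model, notch, 28L), "cl2",
                        truth = "activating_truncation+regulator_whole_gene_deleted")
      return(rbind(del, inv))
    }
    if (scenario == "decoys") {
      d2 <- model_gene(model, "DCY2")
      inter <- c(5e4, 9e4)
      recs <- rbind(
        .sv_record("sv_decoy_intergenic", "deletion", contig,
                   inter[1L] + sample(0:5000, 1L), inter[2L] + sample(0:5000, 1L),
                   "dcl1", truth = "none"),
        .sv_record("sv_decoy_gene", "tandem-dup", contig,
                   d2$start + 100L, d2$end - 100L, "dcl2", truth = "none")
      )
      return(recs)
    }
    # artifacts: each record fails exactly one quality rule
    pos0 <- 1e4
    rbind(
      .small_record("art_sub_asmd", "substitution", contig, pos0 + 1,
                    asmd = 139.9, clpm = 0, truth = "fail:asmd"),
      .small_record("art_sub_clpm", "substitution", contig, pos0 + 2,
                    asmd = 200, clpm = 0.1, truth = "fail:clpm"),
      .small_record("art_indel_qual", "indel", contig, pos0 + 3,
                    quality = 299, truth = "fail:quality"),
      {
        r <- .sv_record("art_sv_support", "deletion", contig, 2e4, 3e4, "acl1",
                        sample_type = "tumour", assembly_score = NA_real_,
                        supporting_reads = 3L, truth = "fail:support")
        r
      }
    )
  })
}

#' Simulate copy-number segments consistent with an SV scenario
#'
#' Produces a diploid baseline with total copy number 1 over the deletion
#' interval for `case1`/`case2`; `decoys`/`artifacts` yield a flat diploid
#' profile.
#'
#' @param model A `gene_model`.
#' @param scenario Scenario name as in [simulate_sv_callset()].
#' @param seed Integer seed (forwarded to the SV simulator).
#' @return data.frame with `contig`, `start`, `end`, `total_cn`, `ploidy`.
#' @export
simulate_cn_segments <- function(model, scenario, seed = 1L) {
  base <- data.frame(contig = model$contig, start = 0,
                     end = model$contig_length, total_cn = 2,
                     ploidy = "diploid", stringsAsFactors = FALSE)
  if (!scenario %in% c("case1", "case2")) return(base)
  sv <- simulate_sv_callset(model, scenario, seed)
  del <- sv[sv$sv_class == "deletion", ][1L, ]
  data.frame(
    contig = model$contig,
    start = c(0, del$pos, del$pos2),
    end = c(del$pos, del$pos2, model$contig_length),
    total_cn = c(2, 1, 2),
    ploidy = "diploid", stringsAsFactors = FALSE
  )
}
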