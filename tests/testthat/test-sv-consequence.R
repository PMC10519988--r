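test_that("case-1 geometry: activating truncation sparing the TM exon", {
  for (strand in c("-", "+")) {
    m <- make_gene_model(sim_config(strand = strand))
    sv <- simulate_sv_callset(m, "case1", seed = 3)
    expect_equal(nrow(sv), 1)
    cc <- classify_truncation(m, sv)
    expect_identical(cc$category, "activating_truncation")
    expect_identical(cc$tm_status, "spared")
    expect_identical(cc$targetability, "gamma_secretase_candidate")
    expect_true(all(c("TM", "ICD") %in% cc$retained_domains))
    expect_identical(annotate_regulator(m, sv)$category,
                     "regulator_promoter_hit")
  }
})

test_that("case-2 geometry: inversion brackets TM, regulator deleted whole", {
  for (strand in c("-", "+")) {
    m <- make_gene_model(sim_config(strand = strand))
    sv <- simulate_sv_callset(m, "case2", seed = 3)
    inv <- sv[sv$sv_class == "inversion", ]
    ctx <- locate_breakpoint(m, c(inv$pos, inv$pos2))
    expect_setequal(ctx$intron, c(27, 28))
    cc <- classify_truncation(m, sv)
    expect_identical(cc$category, "activating_truncation")
    expect_identical(cc$tm_status, "unknown")
    expect_identical(cc$targetability, "transcription_complex_candidate")
    expect_identical(annotate_regulator(m, sv)$category,
                     "regulator_whole_gene_deleted")
  }
})

test_that("decoy and intergenic SVs are inert", {
  m <- default_model()
  sv <- simulate_sv_callset(m, "decoys", seed = 8)
  res <- sv_consequence(m, sv)
  expect_true(all(res$category == "intergenic"))
  expect_true(all(res$regulator == "regulator_intact"))
  expect_true(all(res$targetability == "none"))
})

test_that("strand mirroring leaves every consequence call unchanged", {
  calls <- lapply(c("-", "+"), function(strand) {
    m <- make_gene_model(sim_config(strand = strand))
    do.call(rbind, lapply(c("case1", "case2", "decoys"), function(sc) {
      sv_consequence(m, simulate_sv_callset(m, sc, seed = 13))
    }))
  })
  cols <- c("category", "tm_status", "targetability", "regulator")
  expect_identical(calls[[1]][, cols], calls[[2]][, cols])
})

test_that("TM exon direct involvement is reported as involved", {
  m <- default_model()
  ex <- m$exons[m$exons$gene == "NOTCH1L" & m$exons$exon_index == 28, ]
  ex1 <- m$exons[m$exons$gene == "NOTCH1L" & m$exons$exon_index == 1, ]
  # deletion from inside the TM exon through the gene 5' end
  del <- data.frame(id = "d", class = "rearrangement", sv_class = "deletion",
                    contig = m$contig, pos = floor((ex$start + ex$end) / 2),
                    contig2 = m$contig, pos2 = ex1$end + 100,
                    strand1 = "+", strand2 = "-", cluster = "c",
                    stringsAsFactors = FALSE)
  cc <- classify_truncation(m, del)
  expect_identical(cc$tm_status, "involved")
})

test_that("unknown scenario errors", {
  m <- default_model()
  expect_error(simulate_sv_callset(m, "case3", 1), "unknown scenario")
})

test_that("driver rules: hotspots, footprints, focality and ploidy thresholds", {
  m <- default_model()
  ren <- m$genes[m$genes$gene == "RENL", ]
  d1 <- m$genes[m$genes$gene == "DCY1", ]
  gene_table <- data.frame(
    gene = c("RENL", "DCY1"), role = c("oncogene", "recessive"),
    hotspots = c(as.character(ren$start + 50), NA), stringsAsFactors = FALSE)

  seg <- function(start, width, cn, ploidy) {
    data.frame(contig = m$contig, start = start, end = start + width,
               total_cn = cn, ploidy = ploidy, stringsAsFactors = FALSE)
  }
  # focal amplification over the oncogene: driver in diploid, not tetraploid
  amp_d <- call_drivers(m, NULL, seg(ren$start - 1e4, 5e5, 5, "diploid"), gene_table)
  expect_identical(amp_d$type, "amplification")
  amp_t <- call_drivers(m, NULL, seg(ren$start - 1e4, 5e5, 5, "tetraploid"), gene_table)
  expect_equal(nrow(amp_t), 0)
  expect_equal(nrow(call_drivers(m, NULL, seg(ren$start - 1e4, 5e5, 9, "tetraploid"),
                                 gene_table)), 1)
  # non-focal homozygous deletion is not a driver
  expect_equal(nrow(call_drivers(m, NULL, seg(d1$start - 1e5, 1.2e6, 0, "diploid"),
                                 gene_table)), 0)
  hom <- call_drivers(m, NULL, seg(d1$start - 1e4, 5e4, 0, "diploid"), gene_table)
  expect_identical(hom$type, "homozygous_deletion")
  expect_error(call_drivers(m, NULL, seg(1, 10, 2, "triploid"), gene_table),
               "unknown ploidy")

  # hotspot: exact position only, oncogene only
  v <- data.frame(id = "v1", class = "substitution", contig = m$contig,
                  pos = ren$start + 50, consequence = "missense",
                  stringsAsFactors = FALSE)
  expect_identical(call_drivers(m, v, NULL, gene_table)$type, "hotspot_variant")
  v$pos <- ren$start + 51
  expect_equal(nrow(call_drivers(m, v, NULL, gene_table)), 0)

  # truncating variant and breakend in recessive footprint
  tv <- data.frame(id = "v2", class = "indel", contig = m$contig,
                   pos = d1$start + 10, consequence = "truncating",
                   stringsAsFactors = FALSE)
  expect_identical(call_drivers(m, tv, NULL, gene_table)$type,
                   "recessive_truncating")
  bp <- data.frame(id = "v3", class = "rearrangement", contig = m$contig,
                   pos = d1$start + 10, pos2 = d1$start + 5e4,
                   stringsAsFactors = FALSE)
  expect_identical(call_drivers(m, bp, NULL, gene_table)$type,
                   "recessive_breakend")
  # known fusion
  bp$fusion <- "RENL-DCY2"
  expect_identical(call_drivers(m, bp, NULL, gene_table,
                                known_fusions = "RENL-DCY2")$type[1],
                   "oncogenic_fusion")
})
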