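test_that("GFF3 round trip preserves the model (1-based at the boundary)", {
  m <- default_model()
  path <- file.path(tempdir(), "model.gff3")
  write_gene_model_gff3(m, path)
  # GFF3 on disk is 1-based inclusive: exon width = end - start + 1
  lines <- readLines(path)
  ex_lines <- grep("\texon\t", lines, value = TRUE)
  f <- strsplit(ex_lines[1], "\t")[[1]]
  ex1 <- m$exons[m$exons$gene == "NOTCH1L", ][1, ]
  gff_start <- min(as.integer(sapply(strsplit(ex_lines, "\t"), `[`, 4)))
  expect_equal(gff_start, min(m$exons$start) + 1)
  m2 <- read_gene_model_gff3(path, contig_length = m$contig_length)
  o1 <- m$exons[order(m$exons$gene, m$exons$exon_index), ]
  o2 <- m2$exons[order(m2$exons$gene, m2$exons$exon_index), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2, ignore_attr = TRUE)
  expect_equal(m$genes[order(m$genes$gene), ], m2$genes[order(m2$genes$gene), ],
               ignore_attr = TRUE)
  # the round-tripped model annotates identically
  sv <- simulate_sv_callset(m, "case2", 5)
  expect_identical(sv_consequence(m2, sv)$category,
                   sv_consequence(m, sv)$category)
})

test_that("BEDPE round trip: 0-based half-open breakends", {
  m <- default_model()
  sv <- simulate_sv_callset(m, "case2", 9)
  path <- file.path(tempdir(), "sv.bedpe")
  write_bedpe(sv, path)
  bed <- read.delim(path)
  expect_equal(bed$end1 - bed$start1, c(1, 1))   # half-open single-base ends
  expect_equal(bed$start1, sv$pos)               # 0-based on disk and in memory
  sv2 <- read_bedpe(path)
  expect_equal(sv2[, c("pos", "pos2", "sv_class", "cluster")],
               sv[, c("pos", "pos2", "sv_class", "cluster")],
               ignore_attr = TRUE)
})

test_that("MTX round trip reproduces counts and metadata", {
  x <- simulate_counts(quick_config(seed = 21))
  d <- file.path(tempdir(), "mtx_rt")
  write_counts_mtx(x, d)
  x2 <- read_counts_mtx(d)
  expect_identical(as.matrix(x$counts), as.matrix(x2$counts))
  expect_equal(x$cell_meta$doublet_score, x2$cell_meta$doublet_score,
               tolerance = 1e-12)
  expect_identical(x$gene_meta$mito, x2$gene_meta$mito)
})

test_that("write_fixtures emits a manifest tied to the seed", {
  cfg <- quick_config(seed = 33)
  d <- file.path(tempdir(), "fix33")
  mf <- write_fixtures(cfg, d, scenarios = c("case1", "artifacts"))
  expect_equal(mf$seed, 33)
  expect_true(all(file.exists(file.path(d, c("model.gff3", "sv_case1.bedpe",
                                             "small_variants.tsv", "truth.json",
                                             "manifest.json")))))
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(truth$seed, 33)
  expect_match(unlist(truth$scenarios$case1), "activating_truncation")
  expect_error(write_fixtures(cfg, file.path(tempdir(), "no", "such", "deep",
                                             "root", "x", "y")),
               NA)  # nested dirs are created recursively
})

test_that("CLI subcommands run end to end", {
  d <- file.path(tempdir(), "clifix")
  expect_output(notchtrunc_cli(c("simulate", "--scenario", "case1",
                                 "--seed", "7", "--out", d)),
                "fixtures written")
  out <- file.path(tempdir(), "sv_out.tsv")
  notchtrunc_cli(c("sv-annotate", "--model", file.path(d, "model.gff3"),
                   "--sv", file.path(d, "sv_case1.bedpe"), "--out", out))
  res <- read.delim(out)
  expect_identical(res$category, "activating_truncation")
  expect_identical(res$regulator, "regulator_promoter_hit")
  # variant filtering from TSV
  m <- default_model()
  art <- simulate_sv_callset(m, "artifacts", 7)
  vin <- file.path(tempdir(), "var_in.tsv")
  write.table(art, vin, sep = "\t", quote = FALSE, row.names = FALSE)
  vrep <- file.path(tempdir(), "var_rep.tsv")
  expect_output(notchtrunc_cli(c("filter-variants", "--in", vin,
                                 "--report", vrep)), "0 pass")
  expect_true(all(!read.delim(vrep)$pass))
  expect_error(notchtrunc_cli(c("nonsense", "--a", "b")), "unknown command")
})
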