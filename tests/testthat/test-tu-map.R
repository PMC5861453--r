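# TU-map loading, TSS matching, refinement and promoter windows.

test_that("file loaders apply the coordinate conventions", {
  dir <- tempfile(); dir.create(dir)
  # BED is already 0-based half-open
  writeLines("chr1\t99\t199\ttu1\t0\t+", bed <- file.path(dir, "tus.bed"))
  tus <- load_tu_map(bed)
  expect_equal(tus$start, 99L)
  expect_equal(tus$end, 199L)
  # GFF3 1-based inclusive 100..200 -> internal (99, 200)
  genes <- data.frame(gene_id = "g1", replicon = "chr1", start = 99L,
                      end = 200L, strand = "+", stringsAsFactors = FALSE)
  write_genes_gff3(genes, gff <- file.path(dir, "genes.gff3"))
  reread <- load_genes(gff)
  expect_equal(reread$start, 99L)
  expect_equal(reread$end, 200L)
  # TSS TSV keeps 1-based positions
  write_tss_table(data.frame(replicon = "chr1", position = 150L,
                             strand = "-", gene_id = NA),
                  tss_path <- file.path(dir, "tss.tsv"))
  tss <- load_tss_table(tss_path)
  expect_equal(tss$position, 150L)
  unlink(dir, recursive = TRUE)
})

test_that("malformed inputs raise errors naming the file and line", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("replicon\tposition\tstrand\tgene_id",
               "chr1\t100\t+\tg1",
               "chr1\tabc\t+\tg2"), bad <- file.path(dir, "tss.tsv"))
  expect_error(load_tss_table(bad), "line 3.*non-numeric|non-numeric.*line 3")
  writeLines(c("replicon\tposition\tstrand\tgene_id",
               "chr1\t100\t*\tg1"), bad2 <- file.path(dir, "tss2.tsv"))
  expect_error(load_tss_table(bad2), "line 2")
  expect_error(load_tss_table(file.path(dir, "nope.tsv")), "no such file")
  writeLines(c("replicon\tposition\tstrand\tgene_id",
               "chrX\t100\t+\tg1"), bad3 <- file.path(dir, "tss3.tsv"))
  expect_error(load_tss_table(bad3, replicon_lengths = c(chr1 = 1000)),
               "unknown replicon")
  unlink(dir, recursive = TRUE)
})

test_that("TSSs match TUs by strand, distance and containment", {
  fx <- refine_fixture()
  # at the TU 5' end, same strand -> assigned at distance 0
  tss <- data.frame(replicon = "chr1", position = 91L, strand = "+",
                    gene_id = NA_character_, stringsAsFactors = FALSE)
  m <- match_tss_to_tu(tss, fx$tus, fx$genes)
  expect_equal(m$status, "assigned")
  expect_equal(m$tu_id, "tu1")
  expect_equal(m$distance_bp, 0L)
  # 30 bp upstream on + strand within the window
  m2 <- match_tss_to_tu(data.frame(replicon = "chr1", position = 61L,
                                   strand = "+", gene_id = NA),
                        fx$tus, fx$genes, max_distance_bp = 500L)
  expect_equal(m2$status, "assigned")
  expect_equal(m2$distance_bp, 30L)
  # beyond the window -> unassigned
  m3 <- match_tss_to_tu(data.frame(replicon = "chr1", position = 61L,
                                   strand = "+", gene_id = NA),
                        fx$tus, fx$genes, max_distance_bp = 20L)
  expect_equal(m3$status, "unassigned")
  # opposite strand at the TU 5' end -> unassigned
  m4 <- match_tss_to_tu(data.frame(replicon = "chr1", position = 91L,
                                   strand = "-", gene_id = NA),
                        fx$tus, fx$genes)
  expect_true(m4$status %in% c("unassigned"))
  # minus-strand TU: 5' end is the interval end; TSS there matches at 0
  m5 <- match_tss_to_tu(data.frame(replicon = "chr1", position = 820L,
                                   strand = "-", gene_id = NA),
                        fx$tus, fx$genes)
  expect_equal(m5$tu_id, "tu2")
  expect_equal(m5$distance_bp, 0L)
  # strictly downstream of the first cistron start -> internal
  m6 <- match_tss_to_tu(data.frame(replicon = "chr1", position = 221L,
                                   strand = "+", gene_id = "gB"),
                        fx$tus, fx$genes)
  expect_equal(m6$status, "internal")
})

test_that("refinement adjusts 5' ends and reports the ledger", {
  fx <- refine_fixture()
  # TSSs exactly at the annotated 5' ends -> nothing changes
  tss0 <- data.frame(replicon = "chr1", position = c(91L, 820L),
                     strand = c("+", "-"), gene_id = c("gA", "gM"),
                     stringsAsFactors = FALSE)
  r0 <- refine_tu_map(fx$tus, tss0, fx$genes)
  expect_equal(r0$report$n_tus_adjusted, 0L)
  expect_equal(r0$tus$start, fx$tus$start)
  expect_equal(r0$tus$end, fx$tus$end)

  # extension on +, contraction on -: 3' ends, strands, replicons untouched
  tss1 <- data.frame(replicon = "chr1", position = c(61L, 805L),
                     strand = c("+", "-"), gene_id = c("gA", "gM"),
                     stringsAsFactors = FALSE)
  r1 <- refine_tu_map(fx$tus, tss1, fx$genes)
  led <- r1$report$ledger
  expect_equal(r1$tus$start[r1$tus$tu_id == "tu1"], 60L)
  expect_equal(r1$tus$end[r1$tus$tu_id == "tu1"], 440L)
  expect_equal(r1$tus$end[r1$tus$tu_id == "tu2"], 805L)
  expect_equal(r1$tus$start[r1$tus$tu_id == "tu2"], 700L)
  expect_equal(led$adjustment_bp[led$tu_id == "tu1"], 30L)  # extension
  expect_equal(led$adjustment_bp[led$tu_id == "tu2"], -15L) # contraction
  expect_equal(r1$report$n_tus_adjusted, 2L)
  expect_equal(r1$report$median_abs_adjustment_bp, 22.5)
})

test_that("internal TSS shortens the TU to the TSS position", {
  fx <- refine_fixture()
  # internal primary TSS at cistron 2 (gB) of the 3-gene TU
  tss <- data.frame(replicon = "chr1", position = c(91L, 221L),
                    strand = "+", gene_id = c("gA", "gB"),
                    stringsAsFactors = FALSE)
  r <- refine_tu_map(fx$tus, tss, fx$genes)
  short <- r$tus[r$tus$tu_id == "tu1", ]
  expect_equal(short$start, 220L)
  expect_equal(short$end, 440L)
  members <- assign_genes_to_tus(r$tus, fx$genes)$members
  expect_setequal(members$tu1, c("gB", "gC"))  # cistrons 2-3
  expect_equal(r$report$n_internal_shortened, 1L)
  expect_equal(r$report$dropped_genes, "gA")

  # keep_upstream_remainder retains cistron 1 as a residual unit
  rk <- refine_tu_map(fx$tus, tss, fx$genes, keep_upstream_remainder = TRUE)
  expect_true("tu1_up" %in% rk$tus$tu_id)
  members_k <- assign_genes_to_tus(rk$tus, fx$genes)$members
  expect_equal(members_k$tu1_up, "gA")
  # gene conservation: every gene of the old map in exactly one new TU
  all_members <- unlist(members_k[c("tu1", "tu1_up", "tu2")])
  expect_setequal(all_members, c("gA", "gB", "gC", "gM"))
  expect_equal(anyDuplicated(all_members), 0L)
})

test_that("orphan genes with a TSS become new single-gene TUs", {
  fx <- refine_fixture()
  tss <- data.frame(replicon = "chr1", position = c(91L, 1180L),
                    strand = "+", gene_id = c("gA", "gOrf"),
                    stringsAsFactors = FALSE)
  r <- refine_tu_map(fx$tus, tss, fx$genes)
  expect_equal(r$report$n_orphan_added, 1L)
  orf <- r$tus[r$tus$tu_id == "TU_gOrf", ]
  expect_equal(orf$start, 1179L)   # from its TSS
  expect_equal(orf$end, 1300L)     # to the gene 3' end
  # a TSS downstream of the orphan gene end cannot form a unit
  tss_bad <- data.frame(replicon = "chr1", position = 1400L, strand = "+",
                        gene_id = "gOrf", stringsAsFactors = FALSE)
  r2 <- refine_tu_map(fx$tus, tss_bad, fx$genes)
  expect_equal(r2$report$n_orphan_added, 0L)
})

test_that("refinement is idempotent and conserves 3' ends on synthetic maps", {
  cfg <- small_config(seed = 14, n_internal_tss_tus = 0L)
  sim <- simulate_bundle(cfg)
  genes <- sim$bundle$genes
  r1 <- refine_tu_map(sim$tus, sim$tss, genes)
  # 3' coordinate, strand and replicon are never touched
  old <- sim$tus[match(sim$tus$tu_id, sim$tus$tu_id), ]
  new <- r1$tus[match(sim$tus$tu_id, r1$tus$tu_id), ]
  plus <- new$strand == "+"
  expect_equal(new$end[plus], old$end[plus])
  expect_equal(new$start[!plus], old$start[!plus])
  expect_equal(new$strand, old$strand)
  expect_equal(new$replicon, old$replicon)
  # refining the refined map again changes nothing
  r2 <- refine_tu_map(r1$tus, sim$tss, genes)
  expect_equal(r2$report$n_tus_adjusted, 0L)
  expect_equal(r2$report$n_orphan_added, 0L)
  expect_equal(r2$tus[order(r2$tus$tu_id), ],
               r1$tus[order(r1$tus$tu_id), ], ignore_attr = TRUE)
  # with internal TSSs, idempotence holds under keep_upstream_remainder
  cfg_i <- small_config(seed = 15, n_internal_tss_tus = 1L)
  sim_i <- simulate_bundle(cfg_i)
  ri1 <- refine_tu_map(sim_i$tus, sim_i$tss, sim_i$bundle$genes,
                       keep_upstream_remainder = TRUE)
  ri2 <- refine_tu_map(ri1$tus, sim_i$tss, sim_i$bundle$genes,
                       keep_upstream_remainder = TRUE)
  expect_equal(ri2$report$n_tus_adjusted, 0L)
  expect_equal(ri2$report$n_internal_shortened +
                 ri2$report$n_orphan_added, 0L)
})

test_that("promoter windows are 61 nt with correct boundary and strand handling", {
  seq100 <- paste(rep("ACGT", 25), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = seq100))
  # plus strand at position 51 on a 100 bp replicon -> bases 1..61
  pw <- extract_promoter_windows(
    data.frame(replicon = "chr1", position = 51L, strand = "+"), genome)
  expect_equal(unname(Biostrings::width(pw$windows)), 61L)
  expect_equal(as.character(pw$windows[[1]]), substr(seq100, 1, 61))
  expect_equal(names(pw$windows), "chr1:51:+")
  # minus strand on all-A sequence -> all T, 61 nt
  genome_a <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 100)))
  pw2 <- extract_promoter_windows(
    data.frame(replicon = "chr1", position = 50L, strand = "-"), genome_a)
  expect_equal(as.character(pw2$windows[[1]]), strrep("T", 61))
  # window would start before the replicon -> dropped and counted
  pw3 <- extract_promoter_windows(
    data.frame(replicon = "chr1", position = 10L, strand = "+"), genome)
  expect_equal(length(pw3$windows), 0L)
  expect_equal(nrow(pw3$skipped), 1L)
  expect_equal(pw3$skipped$reason, "clipped")
  # off-sequence TSS -> warning and skip
  expect_warning(
    pw4 <- extract_promoter_windows(
      data.frame(replicon = "chr1", position = 500L, strand = "+"), genome),
    "off sequence")
  expect_equal(pw4$skipped$reason, "off_sequence")
})

test_that("promoter FASTA wraps at 60 columns", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 50)))
  pw <- extract_promoter_windows(
    data.frame(replicon = "chr1", position = 100L, strand = "+"), genome)
  f <- tempfile(fileext = ".fa")
  write_promoter_fasta(pw$windows, f)
  lines <- readLines(f)
  expect_equal(nchar(lines[2]), 60L)
  expect_equal(nchar(lines[3]), 1L)
  unlink(f)
})
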