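# Direction classification and contingency analyses.

test_that("DE direction classification follows the padj/sign rule", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(1.2, -2.0, -0.5, 3.0),
                   padj = c(0.005, 0.5, 0.002, NA))
  expect_message(lab <- classify_de(de, alpha = 0.01), "missing padj")
  expect_equal(lab$direction, c("up", "ns", "down", "ns"))
  s <- de_direction_summary(lab)
  expect_equal(s$n_up + s$n_down + s$n_ns, s$n_total)
  expect_equal(s$n_misregulated, 2L)
  # partition is exhaustive and exclusive by construction
  expect_true(all(lab$direction %in% c("up", "down", "ns")))
})

test_that("alpha monotonicity: more genes called at a looser level", {
  set.seed(2)
  de <- data.frame(gene_id = sprintf("g%03d", 1:200),
                   log2fc = rnorm(200), padj = runif(200))
  s1 <- de_direction_summary(classify_de(de, alpha = 0.01))
  s5 <- de_direction_summary(classify_de(de, alpha = 0.05))
  expect_gte(s5$n_misregulated, s1$n_misregulated)
})

test_that("two-sided Fisher matches hand values, the oracle and fisher.test", {
  expect_equal(fisher_two_sided(matrix(c(5, 5, 5, 5), 2))$p_value, 1.0)
  expect_warning(res0 <- fisher_two_sided(matrix(c(0, 0, 3, 4), 2,
                                                 byrow = TRUE)),
                 "zero margin")
  expect_equal(res0$p_value, 1)
  expect_error(fisher_two_sided(matrix(c(-1, 2, 3, 4), 2)), "non-negative")

  # spec'd enumeration example
  tab <- matrix(c(2, 3, 4, 1), 2, byrow = TRUE)
  expect_equal(fisher_two_sided(tab)$p_value, fisher_oracle(tab),
               tolerance = 1e-12)
  # published replicon-count example: pHV1 decreased vs main chromosome
  phv1 <- matrix(c(35, 40, 534, 2406), 2, byrow = TRUE)
  expect_lt(fisher_two_sided(phv1)$p_value, 0.001)
  # random tables against both the oracle and stats::fisher.test
  set.seed(7)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(c(2, 8, 25), 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_two_sided(tab)$p_value
    expect_equal(p, fisher_oracle(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  # sample odds ratio, flagged as such
  res <- fisher_two_sided(matrix(c(6, 2, 3, 9), 2, byrow = TRUE))
  expect_equal(res$odds_ratio, (6 * 9) / (2 * 3))
  expect_equal(res$or_type, "sample")
})

test_that("replicon contrasts build both 2x2 constructions correctly", {
  counts <- hvo_tfeb_replicon_counts()
  res <- replicon_contrasts_counts(counts, "main_chromosome")
  expect_equal(nrow(res), 6L)  # 3 replicons x 2 directions
  phv1_dec <- res[res$replicon == "pHV1" & res$direction == "decreased", ]
  expect_equal(unname(unlist(
    phv1_dec[, c("n_replicon", "n_replicon_other",
                 "n_reference", "n_reference_other")])),
    c(35, 40, 534, 2406))
  res_b <- replicon_contrasts_counts(counts, "main_chromosome",
                                     construction = "vs_opposite")
  phv1_dec_b <- res_b[res_b$replicon == "pHV1" &
                        res_b$direction == "decreased", ]
  expect_equal(unname(unlist(
    phv1_dec_b[, c("n_replicon", "n_replicon_other",
                   "n_reference", "n_reference_other")])),
    c(35, 1, 534, 617))
  # the reference replicon cannot be contrasted with itself
  expect_error(replicon_contrasts_counts(counts[1, ], "main_chromosome"),
               "itself")
  expect_error(replicon_contrasts_counts(counts, "pHV9"), "not in counts")
})

test_that("replicon contrasts from labelled genes match the tally", {
  dirs <- c(rep("down", 12), rep("up", 3), rep("ns", 25),
            rep("down", 4), rep("up", 6), rep("ns", 50))
  lab <- labeled_de(dirs)
  rmap <- data.frame(gene_id = lab$gene_id,
                     replicon = rep(c("plasmid", "chr"), c(40, 60)))
  res <- replicon_contrasts(lab, rmap, reference = "chr")
  counts <- attr(res, "counts")
  expect_equal(counts$decreased[counts$replicon == "plasmid"], 12L)
  expect_equal(counts$increased[counts$replicon == "chr"], 6L)
  dec <- res[res$direction == "decreased", ]
  expect_equal(unname(unlist(dec[, c("n_replicon", "n_replicon_other",
                                     "n_reference", "n_reference_other")])),
               c(12, 28, 4, 56))
})

test_that("quartile contrast matches a hand tally on 8 genes", {
  # metric order: g1 < g2 < ... < g8; Q1 = {g1,g2}, Q4 = {g7,g8}
  lab <- labeled_de(c("ns", "down", "ns", "up", "ns", "ns", "down", "down"),
                    ids = sprintf("g%d", 1:8))
  metric <- data.frame(gene_id = sprintf("g%d", 1:8), value = (1:8) / 10)
  res <- quartile_contrast(metric, lab, direction = "down")
  expect_equal(unname(res$table), matrix(c(2, 0, 1, 1), 2, byrow = TRUE))
  expect_equal(dimnames(res$table), list(c("Q4", "Q1"), c("down", "not_down")))
  expect_equal(res$p_value, fisher_oracle(res$table), tolerance = 1e-12)
  # ties broken by gene id: equal metric values still give deterministic sets
  metric_tie <- data.frame(gene_id = sprintf("g%d", 1:8), value = 1)
  res_tie <- quartile_contrast(metric_tie, lab)
  q <- res_tie$quartiles
  expect_equal(sort(q$gene_id[q$quartile == "Q1"]), c("g1", "g2"))
  expect_equal(sort(q$gene_id[q$quartile == "Q4"]), c("g7", "g8"))
  expect_error(quartile_contrast(metric[1:3, ], lab), "fewer than 4")
})

test_that("category enrichment applies Bonferroni over categories x directions", {
  set.seed(5)
  dirs <- sample(c("up", "down", "ns"), 200, replace = TRUE)
  lab <- labeled_de(dirs)
  cmap <- data.frame(gene_id = lab$gene_id,
                     category = sample(sprintf("c%02d", 1:10), 200,
                                       replace = TRUE))
  res <- category_enrichment(lab, cmap)
  expect_equal(unique(res$m), 20L)  # 10 categories x 2 directions
  expect_equal(res$p_adjusted, pmin(1, res$m * res$p_value))
  # a raw p of 0.01 under m = 20 would adjust to 0.2
  expect_equal(min(1, 20 * 0.01), 0.2)
  # single category covering all genes: zero out-of-category margin -> p = 1
  # (one warning per tested direction)
  all_one <- data.frame(gene_id = lab$gene_id, category = "only")
  w <- testthat::capture_warnings(res1 <- category_enrichment(lab, all_one))
  expect_true(all(grepl("zero margin", w)))
  expect_true(all(res1$p_value == 1))
})

test_that("a planted down-shifted category is detected", {
  # margin established by oracle runs at the default -2.5 log2 shift
  # (30/30 detections at the default study size)
  hits <- vapply(1:20, function(s) {
    sim <- simulate_bundle(synthetic_config(seed = s + 100))
    lab <- classify_de(sim$de)
    cmap <- data.frame(gene_id = sim$bundle$genes$gene_id,
                       category = sim$bundle$genes$category)
    res <- category_enrichment(lab, cmap)
    row <- res[res$category == "prophage_like" & res$direction == "down", ]
    row$p_adjusted < 0.05 && row$effect == "enriched"
  }, logical(1))
  expect_gte(sum(hits), 17)
})

test_that("region summaries are plain conserved counts", {
  lab <- labeled_de(c("up", "down", "down", "ns", "ns"))
  r <- region_summary(lab, lab$gene_id[2:4])
  expect_equal(r, list(n_genes = 3L, n_up = 0L, n_down = 2L, n_ns = 1L))
  # empty region -> zeros
  expect_equal(region_summary(lab, character(0)),
               list(n_genes = 0L, n_up = 0L, n_down = 0L, n_ns = 0L))
  # whole genome equals the classification summary
  whole <- region_summary(lab, lab$gene_id)
  s <- de_direction_summary(lab)
  expect_equal(whole$n_up, s$n_up)
  expect_equal(whole$n_down, s$n_down)
  expect_error(region_summary(lab, "missing_gene"), "absent")
})

test_that("abundance contrast uses geometric means and detects a shift", {
  # planted shift: down-TUs one log2 unit more abundant (sd 1.5)
  set.seed(31)
  hits <- vapply(1:30, function(i) {
    n <- 200
    dirs <- rep(c("up", "down"), each = n)
    lab <- labeled_de(dirs, ids = sprintf("g%04d", seq_len(2 * n)))
    la <- c(rnorm(n, 8, 1.5), rnorm(n, 9, 1.5))
    tpm <- data.frame(tu_id = sprintf("tu%04d", seq_len(2 * n)),
                      tpm_rep1 = 2^(la + rnorm(2 * n, 0, 0.1)),
                      tpm_rep2 = 2^(la + rnorm(2 * n, 0, 0.1)))
    fc <- data.frame(tu_id = tpm$tu_id, gene_id = lab$gene_id)
    abundance_contrast(tpm, lab, fc)$p_value < 0.001
  }, logical(1))
  expect_gte(sum(hits), 27)

  # geometric mean: rep values (2, 8) -> 4, not 5
  lab2 <- labeled_de(c("up", "down"), ids = c("gu", "gd"))
  tpm2 <- data.frame(tu_id = c("t1", "t2"), tpm_rep1 = c(2, 3),
                     tpm_rep2 = c(8, 3))
  fc2 <- data.frame(tu_id = c("t1", "t2"), gene_id = c("gu", "gd"))
  res <- abundance_contrast(tpm2, lab2, fc2)
  expect_equal(res$median_up, 4)
  expect_equal(res$median_down, 3)
  # empty group -> error
  lab3 <- labeled_de(c("up", "up"), ids = c("gu", "gd"))
  expect_error(abundance_contrast(tpm2, lab3, fc2), "empty group")
  expect_error(abundance_contrast(data.frame(tu_id = "t1", tpm_rep1 = 0),
                                  lab2, fc2), "positive")
})

test_that("contrast p-values are super-uniform under permuted labels", {
  sim <- simulate_bundle(small_config(seed = 77))
  m <- composition_metrics(sim$bundle$genes, sim$bundle$sequences)$metrics
  lab <- classify_de(sim$de)
  metric <- data.frame(gene_id = m$gene_id, value = m$rare_codon_freq)
  set.seed(99)
  ps <- vapply(1:1000, function(i) {
    perm <- lab
    perm$direction <- sample(perm$direction)
    quartile_contrast(metric, perm, direction = "down")$p_value
  }, numeric(1))
  # P(p <= t) must not exceed t beyond binomial noise
  for (t in c(0.01, 0.05, 0.1, 0.25))
    expect_lte(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / 1000))
})
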