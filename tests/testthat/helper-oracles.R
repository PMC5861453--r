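# Independent brute-force oracle for the two-sided Fisher exact test:
# enumerate every table with the observed margins, computing hypergeometric
# probabilities from binomial coefficients (lchoose), and sum those not
# exceeding the observed table's probability (same relative-epsilon
# inclusion rule as mainstream implementations).
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  N <- a + b + c_ + d
  m1 <- a + b; c1 <- a + c_
  if (m1 == 0 || c1 == 0 || m1 == N || c1 == N) return(1)
  support <- max(0, c1 - (N - m1)):min(m1, c1)
  logp <- lchoose(c1, support) + lchoose(N - c1, m1 - support) -
    lchoose(N, m1)
  probs <- exp(logp)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Small fast configuration for property-style loops.
small_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed,
    replicons = list(
      list(name = "chrSyn", length_bp = 140000L, gene_count = 100L,
           origin = "native"),
      list(name = "pHVsyn1", length_bp = 25000L, gene_count = 15L,
           origin = "foreign")),
    n_internal_tss_tus = 1L, n_orphan_genes = 2L,
    prophage_region_size = 8L)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# Hand-built refinement fixture: one 3-gene plus-strand TU, one minus-strand
# monocistronic TU, and an orphan gene, on a single replicon.
refine_fixture <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC", "gM", "gOrf"),
    replicon = "chr1",
    start = c(100L, 220L, 340L, 700L, 1200L),
    end = c(200L, 320L, 440L, 800L, 1300L),
    strand = c("+", "+", "+", "-", "+"),
    stringsAsFactors = FALSE)
  tus <- data.frame(
    tu_id = c("tu1", "tu2"),
    replicon = "chr1",
    start = c(90L, 700L),
    end = c(440L, 820L),
    strand = c("+", "-"),
    stringsAsFactors = FALSE)
  list(genes = genes, tus = tus)
}

# Labeled DE fixture with hand-controlled directions.
labeled_de <- function(directions, ids = sprintf("g%03d", seq_along(directions))) {
  lfc <- ifelse(directions == "up", 2, ifelse(directions == "down", -2, 0.1))
  padj <- ifelse(directions == "ns", 0.5, 0.001)
  classify_de(data.frame(gene_id = ids, log2fc = lfc, padj = padj,
                         stringsAsFactors = FALSE), alpha = 0.01)
}
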