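# Genome-wide synonymous codon usage, rare-codon scoring and AT content.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' The 61 sense codons of the standard genetic code
#' @return Character vector of codons, named by the amino acid they encode.
#' @keywords internal
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  stats::setNames(codons, unname(gc[codons]))
}

# Count codons (frame 0, step 3) for a DNAStringSet; rows = genes, cols = the
# 64 ACGT trinucleotides.  Codons containing ambiguous bases are simply not
# counted, which is the behaviour required for both usage and AT metrics.
codon_count_matrix <- function(cds) {
  Biostrings::trinucleotideFrequency(cds, step = 3)
}

as_dna_set <- function(x, arg = "cds") {
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x)) return(Biostrings::DNAStringSet(x))
  stop(sprintf("`%s` must be a DNAStringSet or character vector", arg),
       call. = FALSE)
}

# Drop genes whose length is not a multiple of 3 (with a warning) and
# truncate genes at an internal stop codon (counting codons up to it).
# Returns list(counts = matrix over 64 codons, kept = logical).
clean_codon_counts <- function(cds) {
  w <- Biostrings::width(cds)
  bad_len <- w %% 3L != 0L
  if (any(bad_len)) {
    warning(sprintf("skipping %d CDS with length not divisible by 3: %s",
                    sum(bad_len),
                    paste(utils::head(names(cds)[bad_len], 5), collapse = ", ")),
            call. = FALSE)
    cds <- cds[!bad_len]
    w <- w[!bad_len]
  }
  if (length(cds) == 0L) {
    return(list(counts = matrix(0L, 0, 64), kept = !bad_len))
  }
  counts <- codon_count_matrix(cds)
  # Internal stop detection: more stop codons than the (optional) terminal one.
  last_codon <- as.character(Biostrings::subseq(cds, start = w - 2L, end = w))
  n_stops <- rowSums(counts[, STOP_CODONS, drop = FALSE])
  internal <- n_stops > as.integer(last_codon %in% STOP_CODONS)
  if (any(internal)) {
    warning(sprintf("%d CDS contain an internal stop codon; codons counted up to it",
                    sum(internal)), call. = FALSE)
    for (i in which(internal)) {
      s <- as.character(cds[[i]])
      cod <- substring(s, seq(1L, nchar(s) - 2L, by = 3L),
                       seq(3L, nchar(s), by = 3L))
      first_stop <- which(cod %in% STOP_CODONS)[1L]
      cod <- cod[seq_len(first_stop - 1L)]
      counts[i, ] <- 0L
      tab <- table(factor(cod, levels = colnames(counts)))
      counts[i, ] <- as.integer(tab)
    }
  }
  list(counts = counts, kept = !bad_len)
}

#' Genome-wide synonymous codon usage table
#'
#' Pools codon counts over all coding sequences ("genome-wide") and computes,
#' for each sense codon, its fraction of the total usage of its synonymous
#' family.  Stop codons and codons containing ambiguous bases are excluded;
#' coding sequences whose length is not a multiple of 3 are skipped with a
#' warning, and sequences with an internal stop are counted up to it.
#'
#' @param cds A `DNAStringSet` (or character vector) of coding sequences,
#'   ideally named by gene id.
#' @return An object of class `codon_usage_table`: a data.frame with one row
#'   per sense codon and columns `codon`, `aa`, `count`,
#'   `synonymous_fraction`, `family_size` and `family_observed` (FALSE for
#'   amino-acid families never observed; such codons carry fraction 0).
#' @examples
#' usage <- genome_codon_usage(c(g1 = "ATGGCTGCTTAA"))
#' subset(usage, aa == "A")
#' @export
genome_codon_usage <- function(cds) {
  cds <- as_dna_set(cds)
  if (length(cds) == 0L) stop("no coding sequences supplied", call. = FALSE)
  cc <- clean_codon_counts(cds)
  if (nrow(cc$counts) == 0L) stop("no usable coding sequences", call. = FALSE)
  totals <- colSums(cc$counts)
  sc <- sense_codons()
  tab <- data.frame(
    codon = unname(sc),
    aa = names(sc),
    count = as.numeric(totals[unname(sc)]),
    stringsAsFactors = FALSE
  )
  fam_tot <- tapply(tab$count, tab$aa, sum)
  tab$family_size <- as.integer(table(tab$aa)[tab$aa])
  tab$family_observed <- fam_tot[tab$aa] > 0
  tab$synonymous_fraction <- ifelse(tab$family_observed,
                                    tab$count / fam_tot[tab$aa], 0)
  rownames(tab) <- tab$codon
  class(tab) <- c("codon_usage_table", "data.frame")
  tab
}

#' Define the rare-codon set from a usage table
#'
#' A codon is rare when its genome-wide synonymous-family fraction is
#' strictly below `threshold` (default 10%).  Single-codon families (Met,
#' Trp) can never be rare since their fraction is 1; families never observed
#' in the input are excluded rather than treated as all-rare.
#'
#' @param usage A `codon_usage_table` from [genome_codon_usage()].
#' @param threshold Strict upper bound on the synonymous fraction (default 0.10).
#' @return An object of class `rare_codon_set`: list with elements `codons`
#'   (character vector) and `threshold`.
#' @export
rare_codon_set <- function(usage, threshold = 0.10) {
  stopifnot(inherits(usage, "codon_usage_table"),
            is.numeric(threshold), threshold > 0, threshold < 1)
  rare <- usage$codon[usage$family_observed &
                        usage$synonymous_fraction < threshold]
  structure(list(codons = rare, threshold = threshold),
            class = "rare_codon_set")
}

#' @export
print.rare_codon_set <- function(x, ...) {
  cat(sprintf("Rare-codon set: %d codons below synonymous fraction %.3g\n",
              length(x$codons), x$threshold))
  if (length(x$codons)) cat(" ", paste(sort(x$codons), collapse = " "), "\n")
  invisible(x)
}

#' Per-gene rare-codon frequency
#'
#' Fraction of a gene's sense codons that belong to the rare-codon set.
#' Genes with zero countable sense codons get `NA` (missing, not 0).
#'
#' @param cds `DNAStringSet` or character vector of coding sequences.
#' @param rare A `rare_codon_set` (or plain character vector of codons).
#' @return Numeric vector in \[0, 1\], named like `cds`.
#' @export
rare_codon_frequency <- function(cds, rare) {
  cds <- as_dna_set(cds)
  rare_codons <- if (inherits(rare, "rare_codon_set")) rare$codons else rare
  stopifnot(is.character(rare_codons))
  if (length(cds) == 0L) return(numeric(0))
  cc <- clean_codon_counts(cds)
  out <- rep(NA_real_, length(cc$kept))
  names(out) <- names(cds)
  if (nrow(cc$counts) > 0L) {
    sense <- setdiff(colnames(cc$counts), STOP_CODONS)
    n_sense <- rowSums(cc$counts[, sense, drop = FALSE])
    n_rare <- if (length(rare_codons))
      rowSums(cc$counts[, intersect(rare_codons, sense), drop = FALSE])
    else rep(0, length(n_sense))
    val <- ifelse(n_sense > 0, n_rare / n_sense, NA_real_)
    if (any(n_sense == 0))
      warning("gene(s) with zero sense codons: rare-codon frequency is NA",
              call. = FALSE)
    out[cc$kept] <- val
  }
  out
}

#' AT content of sequences
#'
#' (A + T) / (A + C + G + T); ambiguous bases are excluded from both
#' numerator and denominator.  Strand-symmetric by construction.
#'
#' @param seqs `DNAStringSet` or character vector.
#' @return Numeric vector in \[0, 1\].
#' @export
at_content <- function(seqs) {
  seqs <- as_dna_set(seqs, "seqs")
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence: AT content undefined", call. = FALSE)
  f <- Biostrings::letterFrequency(seqs, letters = c("A", "T", "G", "C"))
  denom <- rowSums(f)
  if (any(denom == 0))
    stop("sequence with no unambiguous bases: AT content undefined",
         call. = FALSE)
  stats::setNames((f[, "A"] + f[, "T"]) / denom, names(seqs))
}

#' Per-gene AT content over the annotated gene span
#'
#' Counts A/T over the gene interval on the reference strand (AT content is
#' strand-invariant, so no reverse complement is needed).
#'
#' @param genes Gene table (see [load_genes()]): columns `gene_id`,
#'   `replicon`, `start`, `end` (0-based half-open), `strand`.
#' @param genome Named `DNAStringSet` of replicon sequences.
#' @return Numeric vector named by gene id.
#' @export
gene_at_content <- function(genes, genome) {
  spans <- extract_gene_spans(genes, genome, reverse_complement = FALSE)
  at_content(spans)
}

# Extract gene intervals from the genome; optionally reverse-complement
# minus-strand genes (needed for CDS, not for AT content).
extract_gene_spans <- function(genes, genome, reverse_complement = TRUE) {
  check_gene_table(genes)
  missing_rep <- setdiff(unique(genes$replicon), names(genome))
  if (length(missing_rep))
    stop("unknown replicon(s) in gene table: ",
         paste(missing_rep, collapse = ", "), call. = FALSE)
  if (any(genes$start < 0) ||
      any(genes$end > Biostrings::width(genome)[match(genes$replicon,
                                                      names(genome))]))
    stop("gene interval outside replicon bounds", call. = FALSE)
  if (any(genes$end <= genes$start))
    stop("empty gene interval", call. = FALSE)
  out <- Biostrings::DNAStringSet(rep("", nrow(genes)))
  for (rep_name in unique(genes$replicon)) {
    i <- which(genes$replicon == rep_name)
    out[i] <- Biostrings::extractAt(
      genome[[rep_name]],
      IRanges::IRanges(start = genes$start[i] + 1L, end = genes$end[i]))
  }
  names(out) <- genes$gene_id
  if (reverse_complement) {
    neg <- genes$strand == "-"
    if (any(neg)) out[neg] <- Biostrings::reverseComplement(out[neg])
  }
  out
}

#' Extract coding sequences for a gene table
#'
#' @inheritParams gene_at_content
#' @return `DNAStringSet` of CDS (minus-strand genes reverse-complemented),
#'   named by gene id.
#' @export
extract_cds <- function(genes, genome) {
  extract_gene_spans(genes, genome, reverse_complement = TRUE)
}

#' Per-gene composition metrics
#'
#' One-stop computation of the two compositional "foreignness" metrics used
#' downstream: rare-codon frequency (against the genome-wide usage table
#' built from these same genes) and AT content of the gene span.
#'
#' @inheritParams gene_at_content
#' @param rare_threshold Strict synonymous-fraction threshold (default 0.10).
#' @return List with `metrics` (data.frame: gene_id, rare_codon_freq,
#'   at_content, replicon, category), `usage` (`codon_usage_table`) and
#'   `rare_set` (`rare_codon_set`).
#' @export
composition_metrics <- function(genes, genome, rare_threshold = 0.10) {
  spans <- extract_gene_spans(genes, genome, reverse_complement = FALSE)
  cds <- spans
  neg <- genes$strand == "-"
  if (any(neg)) cds[neg] <- Biostrings::reverseComplement(cds[neg])
  usage <- genome_codon_usage(cds)
  rare <- rare_codon_set(usage, threshold = rare_threshold)
  metrics <- data.frame(
    gene_id = genes$gene_id,
    rare_codon_freq = unname(rare_codon_frequency(cds, rare)[genes$gene_id]),
    at_content = unname(at_content(spans)[genes$gene_id]),
    replicon = genes$replicon,
    category = if ("category" %in% names(genes)) genes$category else NA_character_,
    stringsAsFactors = FALSE
  )
  list(metrics = metrics, usage = usage, rare_set = rare)
}

check_gene_table <- function(genes) {
  need <- c("gene_id", "replicon", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("gene table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene ids in gene table", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'", call. = FALSE)
  invisible(genes)
}
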