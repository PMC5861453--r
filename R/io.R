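# Readers and writers.  File conventions: GFF3 and TSS tables are 1-based
# inclusive, BED is 0-based half-open; everything is converted to the
# internal 0-based half-open representation at this boundary only.

#' Write/read replicon sequences
#' @param seqs Named `DNAStringSet`.
#' @param path FASTA file path.
#' @export
write_genome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  # keep only the first word of each FASTA header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a gene table as GFF3
#'
#' Genes are emitted as CDS features (1-based inclusive) carrying `ID`,
#' `category` and `origin` attributes.
#'
#' @param genes Gene table (0-based half-open internal coordinates).
#' @param path Output GFF3 path.
#' @export
write_genes_gff3 <- function(genes, path) {
  check_gene_table(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  if ("category" %in% names(genes))
    S4Vectors::mcols(gr)$category <- genes$category
  if ("origin" %in% names(genes))
    S4Vectors::mcols(gr)$origin <- genes$origin
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Load gene records from GFF3
#'
#' Keeps `CDS` (or, if none, `gene`) features; requires an `ID` attribute.
#'
#' @param path GFF3 file.
#' @param replicons Optional character vector of known replicon names;
#'   records on other replicons raise an error.
#' @return Gene table: gene_id, replicon, start, end (0-based half-open),
#'   strand, plus category/origin when present in the attributes.
#' @export
load_genes <- function(path, replicons = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop(sprintf("malformed GFF3 '%s': %s", path,
                                conditionMessage(e)), call. = FALSE))
  types <- as.character(S4Vectors::mcols(gr)$type)
  keep <- types == "CDS"
  if (!any(keep)) keep <- types == "gene"
  gr <- gr[keep]
  if (length(gr) == 0L) stop("no CDS/gene features in ", path, call. = FALSE)
  ids <- as.character(S4Vectors::mcols(gr)$ID)
  if (any(is.na(ids) | ids == ""))
    stop("GFF3 features without ID attribute in ", path, call. = FALSE)
  genes <- data.frame(
    gene_id = ids,
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  for (extra in c("category", "origin"))
    if (extra %in% names(S4Vectors::mcols(gr)))
      genes[[extra]] <- as.character(S4Vectors::mcols(gr)[[extra]])
  if (!all(genes$strand %in% c("+", "-")))
    stop("GFF3 gene without strand in ", path, call. = FALSE)
  if (!is.null(replicons)) {
    bad <- setdiff(unique(genes$replicon), replicons)
    if (length(bad))
      stop("unknown replicon(s) in ", path, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  check_gene_table(genes)
}

#' Write/load a transcription-unit map as BED6
#'
#' BED is natively 0-based half-open, matching the internal convention;
#' `name` carries the TU id, `score` is unused (0).
#'
#' @param tus TU table: tu_id, replicon, start, end, strand.
#' @param path BED file path.
#' @export
write_tu_bed <- function(tus, path) {
  stopifnot(all(c("tu_id", "replicon", "start", "end", "strand") %in%
                  names(tus)))
  df <- data.frame(chrom = tus$replicon, start = tus$start, end = tus$end,
                   name = tus$tu_id, score = 0L, strand = tus$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_tu_bed
#' @param replicons Optional known replicon names for validation.
#' @return `load_tu_map`: TU table (0-based half-open).
#' @export
load_tu_map <- function(path, replicons = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e)
                   stop(sprintf("malformed BED '%s': %s", path,
                                conditionMessage(e)), call. = FALSE))
  if (length(gr) == 0L) stop("empty TU map: ", path, call. = FALSE)
  tus <- data.frame(
    tu_id = as.character(S4Vectors::mcols(gr)$name),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  if (!all(tus$strand %in% c("+", "-")))
    stop("TU without strand in ", path, call. = FALSE)
  if (anyDuplicated(tus$tu_id))
    stop("duplicated TU ids in ", path, call. = FALSE)
  if (!is.null(replicons)) {
    bad <- setdiff(unique(tus$replicon), replicons)
    if (length(bad))
      stop("unknown replicon(s) in ", path, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  tus
}

# Strict TSV reader: checks required columns, reports offending data line
# numbers (header = line 1).
read_checked_tsv <- function(path, required, numeric_cols = character(0),
                             integer_cols = character(0)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop(sprintf("malformed TSV '%s': %s", path,
                                conditionMessage(e)), call. = FALSE))
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("'%s' lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  for (col in c(numeric_cols, integer_cols)) {
    suppressWarnings(v <- as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) &
                   !(df[[col]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("'%s' line %d: non-numeric value '%s' in column %s",
                   path, bad[1] + 1L, df[[col]][bad[1]], col), call. = FALSE)
    df[[col]] <- if (col %in% integer_cols) as.integer(v) else v
  }
  df
}

#' Write/load a primary-TSS table
#'
#' TSV with columns `replicon`, `position` (1-based first transcribed
#' base), `strand`, `gene_id` (optional association, NA allowed).
#'
#' @param tss TSS table.
#' @param path TSV path.
#' @export
write_tss_table <- function(tss, path) {
  stopifnot(all(c("replicon", "position", "strand") %in% names(tss)))
  if (!"gene_id" %in% names(tss)) tss$gene_id <- NA_character_
  utils::write.table(tss[, c("replicon", "position", "strand", "gene_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tss_table
#' @param replicon_lengths Optional named vector for position validation.
#' @return `load_tss_table`: TSS table (positions 1-based).
#' @export
load_tss_table <- function(path, replicon_lengths = NULL) {
  df <- read_checked_tsv(path, required = c("replicon", "position", "strand"),
                         integer_cols = "position")
  if (!"gene_id" %in% names(df)) df$gene_id <- NA_character_
  df$gene_id[df$gene_id %in% c("", "NA")] <- NA_character_
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("'%s' line %d: strand must be '+' or '-'", path,
                 bad[1] + 1L), call. = FALSE)
  bad <- which(is.na(df$position) | df$position < 1L)
  if (length(bad))
    stop(sprintf("'%s' line %d: TSS position must be a positive integer",
                 path, bad[1] + 1L), call. = FALSE)
  if (!is.null(replicon_lengths)) {
    unknown <- setdiff(unique(df$replicon), names(replicon_lengths))
    if (length(unknown))
      stop("unknown replicon(s) in ", path, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    over <- which(df$position > replicon_lengths[df$replicon])
    if (length(over))
      stop(sprintf("'%s' line %d: TSS position beyond replicon end", path,
                   over[1] + 1L), call. = FALSE)
  }
  df[, c("replicon", "position", "strand", "gene_id")]
}

#' Write/load a differential-expression table
#'
#' TSV with columns `gene_id`, `log2fc`, `padj` (NA allowed in `padj`).
#' @param de DE table.
#' @param path TSV path.
#' @export
write_de_table <- function(de, path) {
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(de)))
  utils::write.table(de[, c("gene_id", "log2fc", "padj")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
load_de_table <- function(path) {
  df <- read_checked_tsv(path, required = c("gene_id", "log2fc", "padj"),
                         numeric_cols = c("log2fc", "padj"))
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene ids in ", path, call. = FALSE)
  df
}

#' Write/load a per-TU TPM table
#'
#' TSV with `tu_id` plus one numeric column per replicate.
#' @param tpm TPM table.
#' @param path TSV path.
#' @export
write_tpm_table <- function(tpm, path) {
  stopifnot("tu_id" %in% names(tpm), ncol(tpm) >= 2L)
  utils::write.table(tpm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tpm_table
#' @export
load_tpm_table <- function(path) {
  df <- read_checked_tsv(path, required = "tu_id")
  rep_cols <- setdiff(names(df), "tu_id")
  if (!length(rep_cols))
    stop("TPM table needs at least one replicate column: ", path,
         call. = FALSE)
  for (col in rep_cols) {
    suppressWarnings(df[[col]] <- as.numeric(df[[col]]))
    if (anyNA(df[[col]]))
      stop("non-numeric TPM values in ", path, call. = FALSE)
  }
  df
}

#' Write per-gene composition metrics
#' @param metrics Metrics data.frame from [composition_metrics()].
#' @param path TSV path.
#' @export
write_metrics_table <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a codon usage table
#' @param usage A `codon_usage_table`.
#' @param path TSV path.
#' @export
write_codon_usage <- function(usage, path) {
  utils::write.table(as.data.frame(usage), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write promoter windows as FASTA (wrapped at 60 columns)
#' @param windows `DNAStringSet` from [extract_promoter_windows()].
#' @param path FASTA path.
#' @export
write_promoter_fasta <- function(windows, path) {
  Biostrings::writeXStringSet(windows, filepath = path, width = 60L)
  invisible(path)
}
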