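# Synthetic genome / TU / TSS / DE generator with recorded ground truth.
#
# Each stage derives its RNG stream from config$seed (seed, seed+1, seed+2)
# so a stage is deterministic regardless of what ran before it, and the
# caller's RNG state is left untouched.

AMINO_ACIDS <- sort(unique(names(sense_codons())))

#' Generate a synthetic multi-replicon genome with native/foreign codon regimes
#'
#' Each replicon carries non-overlapping protein-coding genes whose
#' synonymous codons are drawn from the profile matching the replicon origin
#' (native or foreign); intergenic sequence is sampled at the origin's
#' target AT fraction.  Every CDS is in frame: ATG start, no internal stop,
#' one stop codon.  Functional categories are assigned at random except for
#' one contiguous `prophage_like` block on the first replicon.
#'
#' @param config A [synthetic_config()].
#' @return List with `bundle` (class `genome_bundle`: `sequences` a named
#'   `DNAStringSet`, `genes` a gene table with 0-based half-open coords,
#'   `config`) and `truth` (per-gene origin/category table).
#' @export
generate_genome <- function(config) {
  validate_synthetic_config(config)
  with_seed(config$seed, {
    seqs <- list()
    gene_rows <- list()
    for (r in config$replicons) {
      g <- generate_replicon(r, config)
      seqs[[r$name]] <- g$sequence
      gene_rows[[r$name]] <- g$genes
    }
    gene_rows <- Filter(Negate(is.null), gene_rows)
    genes <- if (length(gene_rows))
      do.call(rbind, c(gene_rows, list(make.row.names = FALSE))) else NULL
    if (is.null(genes))
      genes <- data.frame(gene_id = character(), replicon = character(),
                          start = integer(), end = integer(),
                          strand = character(), origin = character(),
                          stringsAsFactors = FALSE)
    genes$category <- assign_categories(genes, config)
    bundle <- structure(list(
      sequences = Biostrings::DNAStringSet(unlist(seqs)),
      genes = genes,
      config = config), class = "genome_bundle")
    truth <- list(genes = genes[, c("gene_id", "replicon", "origin",
                                    "category")])
    list(bundle = bundle, truth = truth)
  })
}

# One replicon: place genes left-to-right with random intergenic gaps, draw
# CDS codons from the origin profile, splice into an AT-matched background.
generate_replicon <- function(r, config) {
  n <- r$gene_count
  at <- if (r$origin == "native") config$at_native else config$at_foreign
  base_prob <- c(A = at / 2, T = at / 2, G = (1 - at) / 2, C = (1 - at) / 2)
  profile <- if (r$origin == "native") config$native_codon_profile
             else config$foreign_codon_profile
  if (n == 0L) {
    seq <- paste(sample(names(base_prob), r$length_bp, replace = TRUE,
                        prob = base_prob), collapse = "")
    return(list(sequence = seq,
                genes = NULL))
  }
  body_codons <- sample(seq(config$gene_codon_range[1],
                            config$gene_codon_range[2]), n, replace = TRUE)
  lens <- 3L * (body_codons + 2L)  # + start + stop
  slack <- r$length_bp - sum(lens) - (n + 1L)
  if (slack < 0)
    stop(sprintf("replicon %s: %d genes (%d bp) cannot fit in %d bp",
                 r$name, n, sum(lens), r$length_bp), call. = FALSE)
  gaps <- as.integer(rmultinom(1, slack, rep(1, n + 1L))) + 1L
  # 0-based start of gene i = gaps[1..i] + CDS lengths of genes 1..i-1
  starts <- cumsum(gaps[seq_len(n)]) + cumsum(c(0L, lens[-n]))
  ends <- starts + lens
  strand <- sample(c("+", "-"), n, replace = TRUE)

  cds <- sample_cds(body_codons, profile)
  pieces <- character(2L * n + 1L)
  pieces[seq(1L, 2L * n + 1L, by = 2L)] <-
    split_random_string(gaps, base_prob)
  genomic_cds <- cds
  neg <- strand == "-"
  if (any(neg))
    genomic_cds[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(cds[neg])))
  pieces[seq(2L, 2L * n, by = 2L)] <- genomic_cds
  genes <- data.frame(
    gene_id = sprintf("%s_g%04d", r$name, seq_len(n)),
    replicon = r$name,
    start = starts, end = ends, strand = strand,
    origin = r$origin, stringsAsFactors = FALSE)
  list(sequence = paste(pieces, collapse = ""), genes = genes)
}

# Draw all body codons for a replicon at once (amino acids uniform, codons
# from the per-family profile), then assemble per-gene CDS strings.
sample_cds <- function(body_codons, profile) {
  sc <- sense_codons()
  total <- sum(body_codons)
  aa <- sample(AMINO_ACIDS, total, replace = TRUE)
  codon <- character(total)
  for (a in unique(aa)) {
    fam <- unname(sc[names(sc) == a])
    idx <- which(aa == a)
    codon[idx] <- sample(fam, length(idx), replace = TRUE,
                         prob = profile[fam])
  }
  gene_idx <- rep(seq_along(body_codons), body_codons)
  bodies <- vapply(split(codon, gene_idx), paste, character(1), collapse = "")
  stops <- sample(STOP_CODONS, length(body_codons), replace = TRUE)
  paste0("ATG", bodies, stops)
}

# Sample sum(lens) background bases in one call and split into segments.
split_random_string <- function(lens, base_prob) {
  letters_all <- sample(names(base_prob), sum(lens), replace = TRUE,
                        prob = base_prob)
  idx <- rep(seq_along(lens), lens)
  out <- vapply(split(letters_all, idx), paste, character(1), collapse = "")
  # zero-length segments vanish from split(); restore them
  res <- character(length(lens))
  res[as.integer(names(out))] <- out
  res
}

assign_categories <- function(genes, config) {
  n <- nrow(genes)
  if (n == 0L) return(character(0))
  cats <- c(sprintf("cat%02d", seq_len(max(config$n_categories - 1L, 1L))))
  category <- sample(cats, n, replace = TRUE)
  if (config$n_categories > 1L && config$prophage_region_size > 0L) {
    first_rep <- genes$replicon == config$replicons[[1]]$name
    idx <- which(first_rep)
    k <- min(config$prophage_region_size, length(idx))
    if (k > 0L) {
      start <- if (length(idx) > k) sample(length(idx) - k + 1L, 1L) else 1L
      category[idx[start:(start + k - 1L)]] <- "prophage_like"
    }
  }
  category
}

#' Generate the true and perturbed transcription-unit maps plus TSS table
#'
#' Groups genes into operon-like transcription units (consecutive same-strand
#' genes, random boundaries), places the true primary TSS a short UTR
#' upstream of the first cistron, then perturbs each TU's annotated 5' end
#' by a two-regime offset (zero / small geometric / > 100 bp tail; mostly
#' displacing the annotation downstream of the true TSS so that refinement
#' extends the unit).  A chosen number of multi-gene TUs receive an
#' additional internal primary TSS at a downstream cistron start, and a
#' chosen number of single-gene TUs are dropped from the map (orphan genes)
#' while keeping their TSS.
#'
#' @param bundle A `genome_bundle` from [generate_genome()].
#' @param config The same [synthetic_config()].
#' @return List with `tus` (the perturbed map: tu_id, replicon, start, end,
#'   strand; 0-based half-open), `tss` (replicon, position \[1-based\],
#'   strand, gene_id), and `truth` (true TU table with applied signed
#'   offsets, internal-TSS records, orphan gene ids).  Offsets are signed in
#'   the direction of transcription: positive means the annotated 5' end
#'   lies downstream of the true TSS (refinement extends the TU).
#' @export
generate_tu_and_tss <- function(bundle, config) {
  stopifnot(inherits(bundle, "genome_bundle"))
  genes <- bundle$genes
  rep_len <- stats::setNames(Biostrings::width(bundle$sequences),
                             names(bundle$sequences))
  with_seed(config$seed + 1L, {
    groups <- operon_groups(genes, config$operon_break_prob)
    n_tu <- length(groups)
    true_tus <- data.frame(
      tu_id = sprintf("TU%04d", seq_len(n_tu)),
      replicon = vapply(groups, function(g) g$replicon, ""),
      strand = vapply(groups, function(g) g$strand, ""),
      start = NA_integer_, end = NA_integer_,
      members = vapply(groups, function(g) paste(g$gene_ids, collapse = ","), ""),
      n_genes = vapply(groups, function(g) length(g$gene_ids), 0L),
      stringsAsFactors = FALSE)
    utr <- sample(seq(config$utr_range[1], config$utr_range[2]), n_tu,
                  replace = TRUE)
    for (i in seq_len(n_tu)) {
      g <- groups[[i]]
      if (g$strand == "+") {
        true_tus$start[i] <- max(0L, g$span_start - utr[i])
        true_tus$end[i] <- g$span_end
      } else {
        true_tus$start[i] <- g$span_start
        true_tus$end[i] <- min(rep_len[[g$replicon]], g$span_end + utr[i])
      }
    }
    # True primary TSS (1-based first transcribed base)
    true_tus$true_tss <- ifelse(true_tus$strand == "+",
                                true_tus$start + 1L, true_tus$end)

    # Perturb annotated 5' ends
    d <- config$tss_offset_distribution
    offs <- draw_offsets(n_tu, d)
    pert <- true_tus
    for (i in seq_len(n_tu)) {
      o <- offs[i]
      if (pert$strand[i] == "+") {
        new_start <- pert$start[i] + o
        new_start <- max(0L, min(new_start, pert$end[i] - 1L))
        offs[i] <- new_start - true_tus$start[i]
        pert$start[i] <- new_start
      } else {
        new_end <- pert$end[i] - o
        new_end <- min(rep_len[[pert$replicon[i]]],
                       max(new_end, pert$start[i] + 1L))
        offs[i] <- true_tus$end[i] - new_end
        pert$end[i] <- new_end
      }
    }
    true_tus$offset_bp <- as.integer(offs)

    # Internal TSSs at a downstream cistron start of multi-gene TUs
    multi <- which(true_tus$n_genes >= 2L)
    if (config$n_internal_tss_tus > length(multi))
      stop(sprintf("n_internal_tss_tus (%d) exceeds available multi-gene TUs (%d)",
                   config$n_internal_tss_tus, length(multi)), call. = FALSE)
    internal_idx <- if (config$n_internal_tss_tus > 0L)
      sort(sample(multi, config$n_internal_tss_tus)) else integer(0)
    internal <- lapply(internal_idx, function(i) {
      ids <- strsplit(true_tus$members[i], ",")[[1]]
      cistron <- if (length(ids) == 2L) 2L else sample(2:length(ids), 1L)
      gid <- ids[cistron]
      g <- genes[genes$gene_id == gid, ]
      pos <- if (g$strand == "+") g$start + 1L else g$end
      data.frame(tu_id = true_tus$tu_id[i], gene_id = gid,
                 position = pos, stringsAsFactors = FALSE)
    })
    internal <- if (length(internal)) do.call(rbind, internal) else
      data.frame(tu_id = character(), gene_id = character(),
                 position = integer(), stringsAsFactors = FALSE)
    true_tus$has_internal_tss <- true_tus$tu_id %in% internal$tu_id

    # Orphan genes: drop single-gene TUs from the perturbed map
    single <- setdiff(which(true_tus$n_genes == 1L), internal_idx)
    if (config$n_orphan_genes > length(single))
      stop(sprintf("n_orphan_genes (%d) exceeds available single-gene TUs (%d)",
                   config$n_orphan_genes, length(single)), call. = FALSE)
    orphan_idx <- if (config$n_orphan_genes > 0L)
      sort(sample(single, config$n_orphan_genes)) else integer(0)
    orphan_genes <- unlist(lapply(orphan_idx,
                                  function(i) true_tus$members[i]))
    orphan_genes <- as.character(orphan_genes %||% character(0))
    true_tus$is_orphan_tu <- seq_len(n_tu) %in% orphan_idx

    perturbed <- pert[!true_tus$is_orphan_tu,
                      c("tu_id", "replicon", "start", "end", "strand")]
    rownames(perturbed) <- NULL

    first_cistron <- vapply(groups, function(g) g$gene_ids[1], "")
    tss <- data.frame(
      replicon = true_tus$replicon,
      position = true_tus$true_tss,
      strand = true_tus$strand,
      gene_id = first_cistron,
      stringsAsFactors = FALSE)
    if (nrow(internal)) {
      g <- genes[match(internal$gene_id, genes$gene_id), ]
      tss <- rbind(tss, data.frame(
        replicon = g$replicon, position = internal$position,
        strand = g$strand, gene_id = internal$gene_id,
        stringsAsFactors = FALSE))
    }
    tss <- tss[order(tss$replicon, tss$position), ]
    rownames(tss) <- NULL

    list(tus = perturbed, tss = tss,
         truth = list(tus = true_tus, internal_tss = internal,
                      orphan_genes = orphan_genes))
  })
}

# Consecutive same-strand genes on a replicon, split into operons at random
# boundaries; genes ordered 5'->3' within each unit.
operon_groups <- function(genes, break_prob) {
  if (nrow(genes) == 0L) return(list())
  out <- list()
  for (rep_name in unique(genes$replicon)) {
    g <- genes[genes$replicon == rep_name, ]
    g <- g[order(g$start), ]
    if (nrow(g) == 0L) next
    new_block <- c(TRUE, g$strand[-1] != g$strand[-nrow(g)] |
                     runif(nrow(g) - 1L) < break_prob)
    block <- cumsum(new_block)
    for (b in split(seq_len(nrow(g)), block)) {
      gb <- g[b, ]
      ids <- if (gb$strand[1] == "+") gb$gene_id else rev(gb$gene_id)
      out[[length(out) + 1L]] <- list(
        replicon = rep_name, strand = gb$strand[1],
        span_start = min(gb$start), span_end = max(gb$end),
        gene_ids = ids)
    }
  }
  out
}

# Two-regime signed offsets: zero with p_zero; > 100 bp with p_large;
# otherwise 1 + geometric with mean geometric_mean_bp (median ~5 at the
# default).  Sign: + (annotation displaced into the TU, refinement extends)
# with probability p_extension.
draw_offsets <- function(n, d) {
  if (n == 0L) return(integer(0))
  u <- runif(n)
  mag <- integer(n)
  small <- u >= d$p_zero & u < d$p_zero + (1 - d$p_zero - d$p_large)
  large <- u >= 1 - d$p_large
  mag[small] <- 1L + rgeom(sum(small), prob = 1 / d$geometric_mean_bp)
  mag[large] <- 101L + rgeom(sum(large), prob = 1 / 50)
  sgn <- ifelse(runif(n) < (d$p_extension %||% 0.8), 1L, -1L)
  as.integer(mag * sgn)
}

#' Generate a differential-expression table and per-TU TPM matrix
#'
#' The true log2 fold change of each gene is
#' `N(0, baseline_lfc_sd) + beta_rare * rareFreq + beta_at * (AT - genome
#' mean AT) + replicon effect + category effect`.  Genes whose |true lfc|
#' exceeds `lfc_sig_threshold` are called significant (adjusted p drawn
#' below alpha/2); a fraction `alpha` of the remaining null genes receive a
#' false-positive adjusted p.  Reported log2fc adds small observation noise.
#' Per-TU abundance (two replicate TPM columns, each summing to 1e6) is
#' log-normal with a positive shift for TUs whose first cistron is truly
#' downregulated.
#'
#' @param bundle A `genome_bundle`.
#' @param truth Truth list from [generate_tu_and_tss()] (needs `$tus`).
#' @param config The same [synthetic_config()].
#' @return List with `de` (gene_id, log2fc, padj), `tpm` (tu_id, tpm_rep1,
#'   tpm_rep2) and `truth` update (per-gene true_lfc, true_direction,
#'   rare_codon_freq, at_content).
#' @export
generate_de_table <- function(bundle, truth, config) {
  stopifnot(inherits(bundle, "genome_bundle"))
  genes <- bundle$genes
  comp <- composition_metrics(genes, bundle$sequences, rare_threshold = 0.10)
  met <- comp$metrics
  dm <- config$de_model
  with_seed(config$seed + 2L, {
    n <- nrow(genes)
    rep_eff <- (dm$replicon_effects %||% numeric(0))[genes$replicon]
    rep_eff[is.na(rep_eff)] <- 0
    cat_eff <- (dm$category_effects %||% numeric(0))[genes$category]
    cat_eff[is.na(cat_eff)] <- 0
    true_lfc <- rnorm(n, 0, dm$baseline_lfc_sd) +
      (dm$beta_rare %||% 0) * met$rare_codon_freq +
      (dm$beta_at %||% 0) * (met$at_content - mean(met$at_content)) +
      rep_eff + cat_eff
    sig <- abs(true_lfc) > dm$lfc_sig_threshold
    padj <- numeric(n)
    padj[sig] <- runif(sum(sig), 0, dm$alpha / 2)
    null_fp <- !sig & runif(n) < dm$alpha
    padj[null_fp] <- runif(sum(null_fp), 0, dm$alpha)
    padj[!sig & !null_fp] <- runif(sum(!sig & !null_fp), dm$alpha, 1)
    log2fc <- true_lfc + rnorm(n, 0, dm$lfc_obs_noise_sd %||% 0.1)
    de <- data.frame(gene_id = genes$gene_id, log2fc = log2fc, padj = padj,
                     stringsAsFactors = FALSE)
    true_direction <- ifelse(sig & true_lfc > 0, "up",
                             ifelse(sig & true_lfc < 0, "down", "ns"))

    tpm <- NULL
    if (!is.null(truth$tus)) {
      tt <- truth$tus
      first <- vapply(strsplit(tt$members, ","), `[`, "", 1L)
      down_first <- true_direction[match(first, genes$gene_id)] == "down"
      la <- rnorm(nrow(tt), dm$tpm_log2_mean %||% 8, dm$tpm_log2_sd %||% 2) +
        ifelse(down_first, dm$tpm_down_log2_shift %||% 0, 0)
      reps <- vapply(1:2, function(j)
        2^(la + rnorm(nrow(tt), 0, dm$tpm_rep_noise_sd %||% 0.15)),
        numeric(nrow(tt)))
      reps <- apply(reps, 2, function(col) col / sum(col) * 1e6)
      tpm <- data.frame(tu_id = tt$tu_id, tpm_rep1 = reps[, 1],
                        tpm_rep2 = reps[, 2], stringsAsFactors = FALSE)
    }
    list(de = de, tpm = tpm,
         truth = data.frame(gene_id = genes$gene_id, true_lfc = true_lfc,
                            true_direction = true_direction,
                            rare_codon_freq = met$rare_codon_freq,
                            at_content = met$at_content,
                            stringsAsFactors = FALSE))
  })
}

#' Run the full synthetic generator
#'
#' Convenience wrapper chaining [generate_genome()], [generate_tu_and_tss()]
#' and [generate_de_table()].
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_bundle`: `bundle`, `tus`, `tss`, `de`,
#'   `tpm`, `truth` (gene origins/categories, true TU map with offsets,
#'   internal TSS records, orphan genes, true DE).
#' @export
simulate_bundle <- function(config = synthetic_config()) {
  gg <- generate_genome(config)
  tt <- generate_tu_and_tss(gg$bundle, config)
  de <- generate_de_table(gg$bundle, tt$truth, config)
  structure(list(
    bundle = gg$bundle, tus = tt$tus, tss = tt$tss,
    de = de$de, tpm = de$tpm,
    truth = list(genes = gg$truth$genes, tus = tt$truth$tus,
                 internal_tss = tt$truth$internal_tss,
                 orphan_genes = tt$truth$orphan_genes,
                 de = de$truth)), class = "synthetic_bundle")
}

#' Write a synthetic bundle to disk
#'
#' Emits genome FASTA, gene GFF3 (CDS features with ID/category/origin
#' attributes), perturbed TU map BED6, TSS TSV, DE TSV, TPM TSV and a
#' ground-truth JSON.
#'
#' @param sim A `synthetic_bundle` from [simulate_bundle()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.gff3"),
    tus = file.path(dir, "tus.bed"),
    tss = file.path(dir, "tss.tsv"),
    de = file.path(dir, "de.tsv"),
    tpm = file.path(dir, "tpm.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  write_genome_fasta(sim$bundle$sequences, paths["genome"])
  write_genes_gff3(sim$bundle$genes, paths["genes"])
  write_tu_bed(sim$tus, paths["tus"])
  write_tss_table(sim$tss, paths["tss"])
  write_de_table(sim$de, paths["de"])
  if (!is.null(sim$tpm)) write_tpm_table(sim$tpm, paths["tpm"])
  truth <- sim$truth
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}
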