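# End-to-end orchestration: simulate -> write -> reload -> refine ->
# composition -> association, with a machine-readable report and manifest.

#' Run the full synthetic analysis pipeline
#'
#' Generates a synthetic bundle, writes it to disk, reloads every input
#' through the file readers (so the standard-format round trip is part of
#' the run), refines the transcription-unit map against the TSS table,
#' extracts promoter windows, computes composition metrics, and runs the
#' association battery: quartile contrasts for rare-codon frequency and AT
#' content, replicon contrasts against the native reference replicon,
#' category enrichment with Bonferroni correction, the prophage-like region
#' summary, and the abundance rank-sum contrast.  Ground-truth recovery
#' statistics (fraction of true TU 5' ends recovered, injected-offset
#' median) are added since the generator's truth is available.
#'
#' @param config A [synthetic_config()], or the path to a YAML file
#'   accepted by [read_config_yaml()].
#' @param out_dir Output directory (default: fresh temporary directory).
#' @param alpha Adjusted-p significance level for direction calls (0.01).
#' @param rare_threshold Strict rare-codon synonymous-fraction threshold (0.10).
#' @param max_distance_bp TSS-to-TU matching window (500).
#' @param upstream,downstream Promoter window extent (50, 10).
#' @param keep_upstream_remainder Passed to [refine_tu_map()].
#' @param quiet Suppress stage log messages?
#' @return List of class `foreignscan_run`: `report` (all analysis blocks),
#'   `manifest` (seed, config hash, file digests, row counts, version) and
#'   `paths`.
#' @export
run_pipeline <- function(config = synthetic_config(),
                         out_dir = tempfile("foreignscan_run_"),
                         alpha = 0.01, rare_threshold = 0.10,
                         max_distance_bp = 500L,
                         upstream = 50L, downstream = 10L,
                         keep_upstream_remainder = FALSE,
                         quiet = TRUE) {
  if (is.character(config)) config <- read_config_yaml(config)
  validate_synthetic_config(config)
  log_stage <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] seed=%d %s", stage, config$seed,
                                sprintf(fmt, ...)))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- simulate ---------------------------------------------------------
  sim <- simulate_bundle(config)
  sim_dir <- file.path(out_dir, "sim")
  paths <- write_simulation(sim, sim_dir)
  log_stage("simulate", "genes=%d tus=%d tss=%d", nrow(sim$bundle$genes),
            nrow(sim$tus), nrow(sim$tss))

  # -- reload through the file layer ------------------------------------
  genome <- read_genome_fasta(paths["genome"])
  genes <- load_genes(paths["genes"], replicons = names(genome))
  tus <- load_tu_map(paths["tus"], replicons = names(genome))
  tss <- load_tss_table(paths["tss"],
                        replicon_lengths = stats::setNames(
                          Biostrings::width(genome), names(genome)))
  de <- load_de_table(paths["de"])
  tpm <- load_tpm_table(paths["tpm"])
  log_stage("load", "genes=%d tus=%d tss=%d de=%d", nrow(genes), nrow(tus),
            nrow(tss), nrow(de))

  # -- refine TU map ----------------------------------------------------
  ref <- refine_tu_map(tus, tss, genes, max_distance_bp = max_distance_bp,
                       keep_upstream_remainder = keep_upstream_remainder)
  refined_path <- file.path(out_dir, "tus_refined.bed")
  write_tu_bed(ref$tus, refined_path)
  write_adjustment_report(ref$report, out_dir)
  pw <- extract_promoter_windows(tss, genome, upstream = upstream,
                                 downstream = downstream)
  prom_path <- file.path(out_dir, "promoter_windows.fa")
  write_promoter_fasta(pw$windows, prom_path)
  log_stage("refine-tu", "adjusted=%d shortened=%d added=%d windows=%d",
            ref$report$n_tus_adjusted, ref$report$n_internal_shortened,
            ref$report$n_orphan_added, length(pw$windows))

  # -- composition ------------------------------------------------------
  comp <- composition_metrics(genes, genome, rare_threshold = rare_threshold)
  write_metrics_table(comp$metrics, file.path(out_dir, "metrics.tsv"))
  write_codon_usage(comp$usage, file.path(out_dir, "codon_usage.tsv"))
  log_stage("composition", "genes=%d rare_codons=%d", nrow(comp$metrics),
            length(comp$rare_set$codons))

  # -- association ------------------------------------------------------
  de_lab <- classify_de(de, alpha = alpha)
  summ <- de_direction_summary(de_lab)
  rare_metric <- data.frame(gene_id = comp$metrics$gene_id,
                            value = comp$metrics$rare_codon_freq)
  at_metric <- data.frame(gene_id = comp$metrics$gene_id,
                          value = comp$metrics$at_content)
  q_rare <- quartile_contrast(rare_metric, de_lab, direction = "down")
  q_at <- quartile_contrast(at_metric, de_lab, direction = "down")
  reference <- native_reference(config)
  rep_res <- replicon_contrasts(de_lab,
                                data.frame(gene_id = genes$gene_id,
                                           replicon = genes$replicon),
                                reference = reference)
  cat_res <- category_enrichment(de_lab,
                                 data.frame(gene_id = genes$gene_id,
                                            category = genes$category))
  prophage_ids <- genes$gene_id[genes$category == "prophage_like"]
  region <- if (length(prophage_ids))
    region_summary(de_lab, prophage_ids) else NULL
  fc_map <- first_cistron_map(ref$tus, genes)
  abund <- tryCatch(abundance_contrast(tpm, de_lab, fc_map),
                    error = function(e) list(error = conditionMessage(e)))
  log_stage("associate", "up=%d down=%d ns=%d", summ$n_up, summ$n_down,
            summ$n_ns)

  # -- ground-truth recovery -------------------------------------------
  recovery <- tu_recovery_stats(ref, sim$truth)

  report <- list(
    de_summary = summ,
    adjustment = ref$report[c("n_tus_adjusted", "median_abs_adjustment_bp",
                              "n_adjustments_gt100", "n_internal_shortened",
                              "n_orphan_added", "n_unchanged")],
    promoter_windows = list(n = length(pw$windows),
                            n_skipped = nrow(pw$skipped)),
    composition = list(n_rare_codons = length(comp$rare_set$codons),
                       rare_threshold = comp$rare_set$threshold,
                       mean_rare_freq_native =
                         mean(comp$metrics$rare_codon_freq[
                           genes$origin == "native"]),
                       mean_rare_freq_foreign =
                         mean(comp$metrics$rare_codon_freq[
                           genes$origin == "foreign"])),
    quartile_rare = contingency_row(q_rare),
    quartile_at = contingency_row(q_at),
    replicon_contrasts = rep_res,
    replicon_counts = attr(rep_res, "counts"),
    category_enrichment = cat_res,
    region_prophage = region,
    abundance = if (!is.null(abund$p_value))
      list(p_value = abund$p_value, n_up = abund$table[1, "up"],
           n_down = abund$table[1, "down"],
           median_up = abund$median_up, median_down = abund$median_down)
      else abund,
    recovery = recovery)

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")

  cfg_path <- file.path(out_dir, "config.yaml")
  write_config_yaml(config, cfg_path)
  all_files <- c(paths, refined = refined_path, promoters = prom_path,
                 report = report_path, config = cfg_path)
  manifest <- list(
    tool = "foreignscan",
    version = as.character(utils::packageVersion("foreignscan")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    file_md5 = as.list(tools::md5sum(unname(all_files))),
    row_counts = list(genes = nrow(genes), tus = nrow(tus),
                      tus_refined = nrow(ref$tus), tss = nrow(tss),
                      de = nrow(de), tpm = nrow(tpm)),
    alpha = alpha, rare_threshold = rare_threshold,
    max_distance_bp = max_distance_bp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(report = report, manifest = manifest,
                 paths = all_files, out_dir = out_dir),
            class = "foreignscan_run")
}

contingency_row <- function(x) {
  list(table = as.vector(x$table), labels = dimnames(x$table),
       odds_ratio = x$odds_ratio, p_value = x$p_value, method = x$method)
}

native_reference <- function(config) {
  for (r in config$replicons) if (r$origin == "native") return(r$name)
  config$replicons[[1]]$name
}

# Compare refined TU 5' ends with the generator's truth.
tu_recovery_stats <- function(ref, truth) {
  tt <- truth$tus
  noninternal <- tt[!tt$has_internal_tss & !tt$is_orphan_tu, ]
  led <- ref$report$ledger
  led <- led[match(noninternal$tu_id, led$tu_id), ]
  recovered <- led$new_five_prime == noninternal$true_tss
  inj <- noninternal$offset_bp
  list(
    n_tus = nrow(noninternal),
    fraction_five_prime_recovered = mean(recovered, na.rm = TRUE),
    median_injected_abs_offset = stats::median(abs(inj[inj != 0])),
    n_injected_gt100 = sum(abs(inj) > 100),
    orphans_recovered = all(paste0("TU_", truth$orphan_genes) %in%
                              ref$tus$tu_id),
    internal_recovered = all(tt$tu_id[tt$has_internal_tss] %in%
                               led_class_ids(ref$report, "shortened_internal")))
}

led_class_ids <- function(report, cls) {
  report$ledger$tu_id[report$ledger$class == cls]
}

#' @export
print.foreignscan_run <- function(x, ...) {
  cat("foreignscan pipeline run\n")
  cat(sprintf("  seed %d, output %s\n", x$manifest$seed, x$out_dir))
  s <- x$report$de_summary
  cat(sprintf("  DE: %d up, %d down, %d ns of %d (%.1f%% misregulated)\n",
              s$n_up, s$n_down, s$n_ns, s$n_total, s$misregulated_percent))
  cat(sprintf("  TU refinement: %d adjusted (median |adj| %s bp), %d shortened, %d added\n",
              x$report$adjustment$n_tus_adjusted,
              format(x$report$adjustment$median_abs_adjustment_bp),
              x$report$adjustment$n_internal_shortened,
              x$report$adjustment$n_orphan_added))
  cat(sprintf("  Q1-vs-Q4 Fisher p: rare codons %.3g, AT content %.3g\n",
              x$report$quartile_rare$p_value, x$report$quartile_at$p_value))
  invisible(x)
}

#' Write/read a configuration as YAML
#' @param config A `synthetic_config`.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  x <- unclass(config)
  x$native_codon_profile <- as.list(x$native_codon_profile)
  x$foreign_codon_profile <- as.list(x$foreign_codon_profile)
  x$de_model$replicon_effects <- as.list(x$de_model$replicon_effects)
  x$de_model$category_effects <- as.list(x$de_model$category_effects)
  yaml::write_yaml(x, path, precision = 12L)
  invisible(path)
}

#' @rdname write_config_yaml
#' @return `read_config_yaml`: a validated `synthetic_config`.
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  args <- list(
    seed = x$seed,
    replicons = x$replicons,
    at_native = x$at_native, at_foreign = x$at_foreign,
    tss_offset_distribution = x$tss_offset_distribution,
    n_internal_tss_tus = x$n_internal_tss_tus,
    n_orphan_genes = x$n_orphan_genes,
    operon_break_prob = x$operon_break_prob,
    gene_codon_range = unlist(x$gene_codon_range),
    utr_range = unlist(x$utr_range),
    n_categories = x$n_categories,
    prophage_region_size = x$prophage_region_size)
  # renormalise profiles within each synonymous family to absorb the
  # rounding YAML serialisation introduces
  renorm <- function(p) {
    sc <- sense_codons()
    p <- p[unname(sc)]
    fam_tot <- tapply(p, names(sc), sum)
    stats::setNames(as.numeric(p) / fam_tot[names(sc)], unname(sc))
  }
  if (!is.null(x$native_codon_profile))
    args$native_codon_profile <- renorm(unlist(x$native_codon_profile))
  if (!is.null(x$foreign_codon_profile))
    args$foreign_codon_profile <- renorm(unlist(x$foreign_codon_profile))
  if (!is.null(x$de_model)) {
    dm <- x$de_model
    dm$replicon_effects <- unlist(dm$replicon_effects)
    dm$category_effects <- unlist(dm$category_effects)
    args$de_model <- dm
  }
  args <- args[!vapply(args, is.null, TRUE)]
  do.call(synthetic_config, args)
}
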