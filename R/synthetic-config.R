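# Configuration for the synthetic genome / TU / TSS / DE generator.

#' Default native and foreign synonymous codon profiles
#'
#' Two per-amino-acid codon probability regimes built from codon GC content:
#' the native regime strongly prefers G/C-ending codons (emulating a
#' GC-rich halophile main chromosome), the foreign regime prefers A/T-rich
#' codons — precisely the codons that are rare genome-wide under the native
#' regime.  Probabilities are normalised within each synonymous family.
#'
#' @param native_gc_weight,foreign_at_weight Exponential weight per G+C
#'   (native) or A+T (foreign) base in a codon.  The defaults put well over
#'   half of the foreign probability mass on codons with < 10% native
#'   synonymous usage in families of size >= 3.
#' @return List with elements `native` and `foreign`, each a numeric vector
#'   over the 61 sense codons summing to 1 within each synonymous family.
#' @export
default_codon_profiles <- function(native_gc_weight = 2.2,
                                   foreign_at_weight = 2.0) {
  sc <- sense_codons()
  gc_count <- vapply(strsplit(unname(sc), ""), function(b) sum(b %in% c("G", "C")),
                     integer(1))
  normalise <- function(w) {
    fam_tot <- tapply(w, names(sc), sum)
    stats::setNames(w / fam_tot[names(sc)], unname(sc))
  }
  list(native = normalise(exp(native_gc_weight * gc_count)),
       foreign = normalise(exp(foreign_at_weight * (3 - gc_count))))
}

#' Build a synthetic-study configuration
#'
#' Defines the study conditions the generator emulates: a GC-rich native
#' main replicon plus a smaller foreign (laterally acquired) replicon with a
#' divergent codon-usage regime; a transcription-unit map whose annotated
#' 5' ends are displaced from the true primary TSS by a two-regime offset
#' distribution (mostly small shifts, median 5 bp, with a ~9% tail of
#' > 100 bp shifts, mostly extensions); a handful of internal-TSS
#' polycistronic units and orphan genes missing from the TU map; and a
#' differential-expression model in which rare-codon frequency, AT content
#' and replicon of residence push log2 fold change downward.
#'
#' @param seed Integer seed; every generator stage derives its stream from it.
#' @param replicons List of replicon descriptors `list(name, length_bp,
#'   gene_count, origin)` with origin `"native"` or `"foreign"`.
#' @param native_codon_profile,foreign_codon_profile Named codon probability
#'   vectors over the 61 sense codons, normalised per synonymous family.
#' @param at_native,at_foreign Target intergenic AT fraction per origin.
#' @param tss_offset_distribution List `p_zero`, `geometric_mean_bp`,
#'   `p_large` (probability of an offset > 100 bp) and `p_extension`
#'   (probability that the annotated 5' end lies downstream of the true TSS,
#'   so that refinement extends the unit).
#' @param n_internal_tss_tus Number of multi-gene TUs given an additional
#'   internal primary TSS at a downstream cistron start.
#' @param n_orphan_genes Number of single-gene TUs removed from the TU map
#'   while keeping their TSS.
#' @param operon_break_prob Probability of a TU boundary between two
#'   adjacent same-strand genes (controls operon sizes).
#' @param gene_codon_range,utr_range Ranges for CDS body length (codons) and
#'   5' UTR length (bp).
#' @param de_model List of differential-expression parameters:
#'   `baseline_lfc_sd`, `lfc_sig_threshold`, `beta_rare`, `beta_at`,
#'   `replicon_effects` (named), `category_effects` (named),
#'   `alpha` (false-positive injection rate among null genes),
#'   `lfc_obs_noise_sd`, and the TPM block `tpm_log2_mean`, `tpm_log2_sd`,
#'   `tpm_down_log2_shift`, `tpm_rep_noise_sd`.
#' @param n_categories Number of functional category labels; the last one
#'   (`prophage_like`) is assigned to a contiguous gene block.
#' @param prophage_region_size Number of contiguous genes on the first
#'   replicon labelled `prophage_like`.
#' @return Validated object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    replicons = list(
      list(name = "chrSyn",  length_bp = 370000L, gene_count = 270L, origin = "native"),
      list(name = "pHVsyn1", length_bp = 48000L,  gene_count = 30L,  origin = "foreign")),
    native_codon_profile = default_codon_profiles()$native,
    foreign_codon_profile = default_codon_profiles()$foreign,
    at_native = 0.35,
    at_foreign = 0.48,
    tss_offset_distribution = list(p_zero = 0.30, geometric_mean_bp = 6,
                                   p_large = 0.09, p_extension = 0.8),
    n_internal_tss_tus = 2L,
    n_orphan_genes = 5L,
    operon_break_prob = 1 / 3,
    gene_codon_range = c(150L, 450L),
    utr_range = c(10L, 60L),
    de_model = list(
      baseline_lfc_sd = 1.2,
      lfc_sig_threshold = 1.2,
      beta_rare = -10,
      beta_at = -10,
      replicon_effects = c(pHVsyn1 = -1.0),
      category_effects = c(prophage_like = -2.5),
      alpha = 0.01,
      lfc_obs_noise_sd = 0.1,
      tpm_log2_mean = 8, tpm_log2_sd = 1.5,
      tpm_down_log2_shift = 2, tpm_rep_noise_sd = 0.15),
    n_categories = 8L,
    prophage_region_size = 15L) {
  cfg <- structure(list(
    seed = as.integer(seed),
    replicons = replicons,
    native_codon_profile = native_codon_profile,
    foreign_codon_profile = foreign_codon_profile,
    at_native = at_native, at_foreign = at_foreign,
    tss_offset_distribution = tss_offset_distribution,
    n_internal_tss_tus = as.integer(n_internal_tss_tus),
    n_orphan_genes = as.integer(n_orphan_genes),
    operon_break_prob = operon_break_prob,
    gene_codon_range = as.integer(gene_codon_range),
    utr_range = as.integer(utr_range),
    de_model = de_model,
    n_categories = as.integer(n_categories),
    prophage_region_size = as.integer(prophage_region_size)),
    class = "synthetic_config")
  validate_synthetic_config(cfg)
}

#' Validate a synthetic configuration
#' @param cfg A `synthetic_config`.
#' @return `cfg`, invisibly transformed (integer coercions applied); errors
#'   on violated invariants.
#' @export
validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.na(cfg$seed)) stop("seed must be an integer", call. = FALSE)
  if (!length(cfg$replicons)) stop("at least one replicon required", call. = FALSE)
  for (r in cfg$replicons) {
    if (!all(c("name", "length_bp", "gene_count", "origin") %in% names(r)))
      stop("replicon descriptor needs name, length_bp, gene_count, origin",
           call. = FALSE)
    if (r$length_bp <= 0 || r$gene_count < 0)
      stop("replicon lengths must be positive and gene counts non-negative",
           call. = FALSE)
    if (!r$origin %in% c("native", "foreign"))
      stop("replicon origin must be 'native' or 'foreign'", call. = FALSE)
  }
  if (anyDuplicated(vapply(cfg$replicons, `[[`, "", "name")))
    stop("replicon names must be unique", call. = FALSE)
  for (p in list(cfg$native_codon_profile, cfg$foreign_codon_profile))
    check_codon_profile(p)
  for (a in c(cfg$at_native, cfg$at_foreign))
    if (!is.numeric(a) || a < 0 || a > 1)
      stop("AT fractions must lie in [0, 1]", call. = FALSE)
  d <- cfg$tss_offset_distribution
  if (d$p_zero < 0 || d$p_large < 0 || d$p_zero + d$p_large > 1)
    stop("tss offset probabilities invalid", call. = FALSE)
  if (d$geometric_mean_bp < 1)
    stop("geometric_mean_bp must be >= 1", call. = FALSE)
  if (cfg$n_internal_tss_tus < 0 || cfg$n_orphan_genes < 0)
    stop("counts must be non-negative", call. = FALSE)
  if (cfg$operon_break_prob < 0 || cfg$operon_break_prob > 1)
    stop("operon_break_prob must lie in [0, 1]", call. = FALSE)
  dm <- cfg$de_model
  need <- c("baseline_lfc_sd", "lfc_sig_threshold", "alpha")
  if (!all(need %in% names(dm)))
    stop("de_model needs ", paste(need, collapse = ", "), call. = FALSE)
  if (dm$alpha <= 0 || dm$alpha >= 1)
    stop("de_model$alpha must lie in (0, 1)", call. = FALSE)
  invisible(cfg)
}

# Probability vectors must sum to 1 within each synonymous family (1e-9).
check_codon_profile <- function(p) {
  sc <- sense_codons()
  if (!all(unname(sc) %in% names(p)))
    stop("codon profile must cover all 61 sense codons", call. = FALSE)
  p <- p[unname(sc)]
  if (any(p < 0)) stop("codon profile has negative entries", call. = FALSE)
  fam_tot <- tapply(p, names(sc), sum)
  if (any(abs(fam_tot - 1) > 1e-9))
    stop("codon profile families must each sum to 1 (tolerance 1e-9)",
         call. = FALSE)
  invisible(p)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  seed: %d; replicons: %s\n", x$seed,
              paste(vapply(x$replicons, function(r)
                sprintf("%s[%s, %d genes, %d bp]", r$name, r$origin,
                        r$gene_count, r$length_bp), ""), collapse = ", ")))
  cat(sprintf("  offsets: p_zero=%.2f mean=%g p_large=%.2f; internal TSS TUs=%d; orphans=%d\n",
              x$tss_offset_distribution$p_zero,
              x$tss_offset_distribution$geometric_mean_bp,
              x$tss_offset_distribution$p_large,
              x$n_internal_tss_tus, x$n_orphan_genes))
  cat(sprintf("  DE: lfc_sd=%.2g thr=%.2g beta_rare=%.2g beta_at=%.2g alpha=%.3g\n",
              x$de_model$baseline_lfc_sd, x$de_model$lfc_sig_threshold,
              x$de_model$beta_rare %||% 0, x$de_model$beta_at %||% 0,
              x$de_model$alpha))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a derived seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed %% .Machine$integer.max)
  expr
}
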