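# Direction classification and contingency analyses: Fisher exact tests of
# replicon, composition quartile and functional category against the
# direction of differential expression, plus the abundance rank-sum contrast.

#' Classify differential-expression direction
#'
#' A gene is `up` when `padj < alpha` and `log2fc > 0`, `down` when
#' `padj < alpha` and `log2fc < 0`, otherwise `ns` (not significant).
#' Missing adjusted p-values are treated as `ns` and never dropped, so
#' "detected" denominators stay honest.
#'
#' @param de DE table with columns `gene_id`, `log2fc`, `padj`.
#' @param alpha Significance level on the adjusted p-value (default 0.01).
#' @return The table with an added `direction` column (attribute `alpha`
#'   records the level; attribute `n_na_padj` the number of missing padj).
#' @export
classify_de <- function(de, alpha = 0.01) {
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(de)),
            is.numeric(alpha), alpha > 0, alpha < 1)
  n_na <- sum(is.na(de$padj))
  if (n_na > 0)
    message(sprintf("%d gene(s) with missing padj classified as 'ns'", n_na))
  sig <- !is.na(de$padj) & de$padj < alpha
  de$direction <- ifelse(sig & de$log2fc > 0, "up",
                         ifelse(sig & de$log2fc < 0, "down", "ns"))
  attr(de, "alpha") <- alpha
  attr(de, "n_na_padj") <- n_na
  de
}

#' Summarise direction counts
#'
#' @param de_labeled Output of [classify_de()].
#' @return List: `n_up`, `n_down`, `n_ns`, `n_total`, `n_misregulated`
#'   (up + down) and `misregulated_percent` (100 * misregulated / total).
#' @export
de_direction_summary <- function(de_labeled) {
  stopifnot("direction" %in% names(de_labeled))
  n_up <- sum(de_labeled$direction == "up")
  n_down <- sum(de_labeled$direction == "down")
  n_total <- nrow(de_labeled)
  list(n_up = n_up, n_down = n_down, n_ns = n_total - n_up - n_down,
       n_total = n_total, n_misregulated = n_up + n_down,
       misregulated_percent = 100 * (n_up + n_down) / n_total)
}

# ---- Fisher exact test -----------------------------------------------------

new_contingency_result <- function(table, odds_ratio, p_value, method,
                                   or_type = "sample", p_adjusted = NA_real_,
                                   adjustment = "none", m = NA_integer_,
                                   extra = list()) {
  structure(c(list(table = table, odds_ratio = odds_ratio, or_type = or_type,
                   p_value = p_value, p_adjusted = p_adjusted,
                   method = method, adjustment = adjustment, m = m), extra),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("%s (adjustment: %s%s)\n", x$method, x$adjustment,
              if (!is.na(x$m)) sprintf(", m = %d", x$m) else ""))
  if (is.matrix(x$table)) print(x$table)
  cat(sprintf("  odds ratio (%s): %s   p = %.4g", x$or_type,
              format(x$odds_ratio, digits = 4), x$p_value))
  if (!is.na(x$p_adjusted)) cat(sprintf("   p_adj = %.4g", x$p_adjusted))
  cat("\n")
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability rule: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' whose probability does not exceed that of the observed table, using the
#' relative tolerance `1 + 1e-7` conventional in mainstream exact-test
#' implementations.  The reported odds ratio is the sample odds ratio
#' (`or_type = "sample"`), not the conditional MLE.
#'
#' @param table 2x2 matrix of non-negative integer counts, or a length-4
#'   vector filled row-wise.
#' @return A `contingency_result` (method `fisher_two_sided`).  A zero row
#'   or column margin gives p = 1 with a warning.
#' @examples
#' fisher_two_sided(matrix(c(5, 5, 5, 5), 2))$p_value  # 1
#' @export
fisher_two_sided <- function(table) {
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2L, byrow = TRUE)
  if (!all(dim(table) == 2L)) stop("need a 2x2 table", call. = FALSE)
  if (any(is.na(table)) || any(table < 0) ||
      any(abs(table - round(table)) > 1e-8))
    stop("counts must be non-negative integers", call. = FALSE)
  table <- round(table)
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  N <- a + b + c_ + d
  m1 <- a + b; c1 <- a + c_
  if (m1 == 0 || c1 == 0 || m1 == N || c1 == N) {
    warning("zero margin: Fisher p set to 1", call. = FALSE)
    return(new_contingency_result(table, odds_ratio = NaN, p_value = 1,
                                  method = "fisher_two_sided"))
  }
  support <- max(0, c1 - (N - m1)):min(m1, c1)
  probs <- stats::dhyper(support, c1, N - c1, m1)
  p_obs <- stats::dhyper(a, c1, N - c1, m1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- (a * d) / (b * c_)
  new_contingency_result(table, odds_ratio = or, p_value = p,
                         method = "fisher_two_sided")
}

# ---- Replicon contrasts (Table-1 style) ------------------------------------

#' Tally direction counts per replicon
#' @param de_labeled Output of [classify_de()].
#' @param replicon_map Data.frame `gene_id`, `replicon` (or named character
#'   vector keyed by gene id).
#' @return Data.frame: replicon, detected, increased, decreased.
#' @export
tally_replicon_counts <- function(de_labeled, replicon_map) {
  rmap <- as_gene_map(replicon_map, "replicon")
  miss <- setdiff(de_labeled$gene_id, names(rmap))
  if (length(miss))
    stop("gene(s) without replicon assignment: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  rep_of <- rmap[de_labeled$gene_id]
  out <- do.call(rbind, lapply(unique(rep_of), function(r) {
    d <- de_labeled[rep_of == r, ]
    data.frame(replicon = r, detected = nrow(d),
               increased = sum(d$direction == "up"),
               decreased = sum(d$direction == "down"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-replicon contingency contrasts against a reference replicon
#'
#' For each non-reference replicon and each direction (increased,
#' decreased), builds a 2x2 table against the reference replicon and runs a
#' two-sided Fisher exact test.  Two constructions of the table are
#' supported: `"vs_rest"` (direction vs not-direction among detected genes;
#' the default reading of a test "compared to the main chromosome") and
#' `"vs_opposite"` (direction vs the opposite direction; note this collapses
#' the two directions of a replicon onto the same table).
#'
#' @param counts Data.frame `replicon`, `detected`, `increased`,
#'   `decreased` — e.g. from [tally_replicon_counts()] or a printed table.
#' @param reference Name of the reference replicon (must be in `counts`).
#' @param construction `"vs_rest"` or `"vs_opposite"`.
#' @return Data.frame, one row per (replicon, direction): counts entering
#'   the 2x2 table, odds_ratio, p_value.
#' @export
replicon_contrasts_counts <- function(counts, reference,
                                      construction = c("vs_rest",
                                                       "vs_opposite")) {
  construction <- match.arg(construction)
  need <- c("replicon", "detected", "increased", "decreased")
  stopifnot(all(need %in% names(counts)))
  if (!reference %in% counts$replicon)
    stop("reference replicon '", reference, "' not in counts", call. = FALSE)
  others <- setdiff(counts$replicon, reference)
  if (!length(others))
    stop("reference replicon cannot be tested against itself", call. = FALSE)
  ref <- counts[counts$replicon == reference, ]
  rows <- list()
  for (r in others) {
    cr <- counts[counts$replicon == r, ]
    for (dir in c("increased", "decreased")) {
      x <- cr[[dir]]; rx <- ref[[dir]]
      if (construction == "vs_rest") {
        tab <- matrix(c(x, cr$detected - x, rx, ref$detected - rx), 2L,
                      byrow = TRUE,
                      dimnames = list(c(r, reference),
                                      c(dir, paste0("not_", dir))))
      } else {
        other <- setdiff(c("increased", "decreased"), dir)
        tab <- matrix(c(x, cr[[other]], rx, ref[[other]]), 2L, byrow = TRUE,
                      dimnames = list(c(r, reference), c(dir, other)))
      }
      res <- fisher_two_sided(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        replicon = r, direction = dir, construction = construction,
        n_replicon = x, n_replicon_other = tab[1, 2],
        n_reference = rx, n_reference_other = tab[2, 2],
        odds_ratio = res$odds_ratio, p_value = res$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname replicon_contrasts_counts
#' @inheritParams tally_replicon_counts
#' @param de_labeled Output of [classify_de()].
#' @export
replicon_contrasts <- function(de_labeled, replicon_map, reference,
                               construction = c("vs_rest", "vs_opposite")) {
  counts <- tally_replicon_counts(de_labeled, replicon_map)
  res <- replicon_contrasts_counts(counts, reference,
                                   construction = match.arg(construction))
  attr(res, "counts") <- counts
  res
}

# ---- Quartile contrasts ----------------------------------------------------

#' First-vs-fourth quartile contrast of a per-gene metric
#'
#' Orders genes by the metric (ties broken by gene id for determinism),
#' takes the bottom and top floor(n/4) genes as Q1 and Q4, and tests the
#' 2x2 table (Q4 vs Q1) x (direction vs not-direction) with a two-sided
#' Fisher exact test.  An odds ratio > 1 means the direction is enriched in
#' the high-metric quartile.
#'
#' @param metric Data.frame `gene_id`, `value`, or a named numeric vector.
#' @param de_labeled Output of [classify_de()].
#' @param direction Direction to test (default `"down"`).
#' @return A `contingency_result` with extra fields `quartiles` (gene
#'   assignment) and `direction`.
#' @export
quartile_contrast <- function(metric, de_labeled, direction = "down") {
  stopifnot(direction %in% c("up", "down"))
  met <- as_gene_map(metric, "value", numeric = TRUE)
  met <- met[!is.na(met)]
  common <- intersect(names(met), de_labeled$gene_id)
  if (length(common) < 4L)
    stop("metric defined for fewer than 4 genes in the DE table",
         call. = FALSE)
  met <- met[common]
  dir_of <- stats::setNames(de_labeled$direction, de_labeled$gene_id)[common]
  ord <- order(met, names(met))
  nq <- floor(length(common) / 4)
  q1 <- names(met)[ord[seq_len(nq)]]
  q4 <- names(met)[ord[seq(length(common) - nq + 1L, length(common))]]
  a <- sum(dir_of[q4] == direction); b <- nq - a
  c_ <- sum(dir_of[q1] == direction); d <- nq - c_
  tab <- matrix(c(a, b, c_, d), 2L, byrow = TRUE,
                dimnames = list(c("Q4", "Q1"),
                                c(direction, paste0("not_", direction))))
  res <- fisher_two_sided(tab)
  res$direction <- direction
  res$quartiles <- data.frame(
    gene_id = c(q1, q4),
    quartile = rep(c("Q1", "Q4"), c(length(q1), length(q4))),
    stringsAsFactors = FALSE)
  res
}

# ---- Category enrichment ---------------------------------------------------

#' Functional-category enrichment in differentially expressed genes
#'
#' For each category and each tested direction, builds the 2x2 table
#' (in-category vs out-of-category) x (direction vs not-direction), runs a
#' two-sided Fisher exact test and applies Bonferroni correction over
#' m = (number of categories) x (number of directions tested).
#' Uncategorised genes count in the out-of-category margin.
#'
#' @param de_labeled Output of [classify_de()].
#' @param category_map Data.frame `gene_id`, `category` (or named character
#'   vector); genes absent from the map are uncategorised.
#' @param directions Directions tested (default both `up` and `down`).
#' @return Data.frame, one row per (category, direction): counts,
#'   odds_ratio, p_value, p_adjusted = min(1, m p), m, and `effect`
#'   (`enriched` / `depleted` / `none` from the odds ratio).
#' @export
category_enrichment <- function(de_labeled, category_map,
                                directions = c("up", "down")) {
  stopifnot(all(directions %in% c("up", "down")))
  cmap <- as_gene_map(category_map, "category")
  cat_of <- cmap[de_labeled$gene_id]  # NA = uncategorised
  cats <- sort(unique(cat_of[!is.na(cat_of)]))
  if (!length(cats)) stop("no categorised genes", call. = FALSE)
  m <- length(cats) * length(directions)
  rows <- list()
  for (cat in cats) {
    in_cat <- !is.na(cat_of) & cat_of == cat
    for (dir in directions) {
      is_dir <- de_labeled$direction == dir
      tab <- matrix(c(sum(in_cat & is_dir), sum(in_cat & !is_dir),
                      sum(!in_cat & is_dir), sum(!in_cat & !is_dir)),
                    2L, byrow = TRUE,
                    dimnames = list(c("in_category", "out_of_category"),
                                    c(dir, paste0("not_", dir))))
      res <- fisher_two_sided(tab)
      p_adj <- min(1, m * res$p_value)
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat, direction = dir,
        n_in_dir = tab[1, 1], n_in_not = tab[1, 2],
        n_out_dir = tab[2, 1], n_out_not = tab[2, 2],
        odds_ratio = res$odds_ratio, p_value = res$p_value,
        p_adjusted = p_adj, m = m,
        effect = if (is.nan(res$odds_ratio) || res$odds_ratio == 1) "none"
                 else if (res$odds_ratio > 1) "enriched" else "depleted",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "adjustment") <- "bonferroni"
  out
}

# ---- Region summary --------------------------------------------------------

#' Direction counts within a gene region
#'
#' Plain counts (no test) for a set of genes, e.g. a prophage-like block.
#'
#' @param de_labeled Output of [classify_de()].
#' @param gene_ids Character vector of region gene ids; all must be present
#'   in the DE table.
#' @return List: n_genes, n_up, n_down, n_ns.
#' @export
region_summary <- function(de_labeled, gene_ids) {
  miss <- setdiff(gene_ids, de_labeled$gene_id)
  if (length(miss))
    stop("region gene(s) absent from DE table: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  d <- de_labeled[de_labeled$gene_id %in% gene_ids, ]
  list(n_genes = nrow(d),
       n_up = sum(d$direction == "up"),
       n_down = sum(d$direction == "down"),
       n_ns = sum(d$direction == "ns"))
}

# ---- Abundance contrast ----------------------------------------------------

#' First cistron of each transcription unit
#' @param tus TU table.
#' @param genes Gene table.
#' @return Data.frame `tu_id`, `gene_id` (TUs without genes omitted).
#' @export
first_cistron_map <- function(tus, genes) {
  members <- assign_genes_to_tus(tus, genes)$members
  first <- vapply(members, function(ids)
    if (length(ids)) ids[1] else NA_character_, "")
  out <- data.frame(tu_id = names(first), gene_id = unname(first),
                    stringsAsFactors = FALSE)
  out[!is.na(out$gene_id), ]
}

#' Abundance contrast between up- and downregulated transcription units
#'
#' Per-TU abundance is the geometric mean of the replicate TPM columns;
#' TUs are labelled by the DE direction of their first cistron, and the
#' log-abundances of the up and down groups are compared with a two-sided
#' Wilcoxon rank-sum test.
#'
#' @param tpm TPM table (`tu_id` + replicate columns, all positive for
#'   included TUs).
#' @param de_labeled Output of [classify_de()].
#' @param cistron_map Data.frame `tu_id`, `gene_id` from
#'   [first_cistron_map()].
#' @return A `contingency_result` with method `wilcoxon_rank_sum`, group
#'   sizes in `table`, and extra fields `median_up` / `median_down`
#'   (geometric-mean TPM medians).
#' @export
abundance_contrast <- function(tpm, de_labeled, cistron_map) {
  stopifnot("tu_id" %in% names(tpm),
            all(c("tu_id", "gene_id") %in% names(cistron_map)))
  rep_cols <- setdiff(names(tpm), "tu_id")
  vals <- as.matrix(tpm[, rep_cols, drop = FALSE])
  if (any(vals <= 0))
    stop("TPM must be positive for all included TUs", call. = FALSE)
  abund <- exp(rowMeans(log(vals)))
  names(abund) <- tpm$tu_id
  dir_of <- stats::setNames(de_labeled$direction, de_labeled$gene_id)
  tu_dir <- dir_of[cistron_map$gene_id]
  names(tu_dir) <- cistron_map$tu_id
  common <- intersect(names(abund), names(tu_dir))
  up <- abund[common][tu_dir[common] == "up" & !is.na(tu_dir[common])]
  down <- abund[common][tu_dir[common] == "down" & !is.na(tu_dir[common])]
  if (!length(up) || !length(down))
    stop(sprintf("empty group in abundance contrast (up: %d, down: %d TUs)",
                 length(up), length(down)), call. = FALSE)
  w <- stats::wilcox.test(log(up), log(down), alternative = "two.sided",
                          exact = FALSE)
  new_contingency_result(
    table = matrix(c(length(up), length(down)), 1L,
                   dimnames = list("n_tus", c("up", "down"))),
    odds_ratio = NA_real_, or_type = "none",
    p_value = w$p.value, method = "wilcoxon_rank_sum",
    extra = list(median_up = stats::median(up),
                 median_down = stats::median(down)))
}

# Accept either a two-column data.frame or a named vector as a gene map.
as_gene_map <- function(x, value_col, numeric = FALSE) {
  if (is.data.frame(x)) {
    stopifnot(all(c("gene_id", value_col) %in% names(x)))
    v <- x[[value_col]]
    names(v) <- x$gene_id
  } else {
    if (is.null(names(x)))
      stop("gene map vector must be named by gene id", call. = FALSE)
    v <- x
  }
  if (numeric) v <- stats::setNames(as.numeric(v), names(v))
  if (anyDuplicated(names(v)))
    stop("duplicated gene ids in gene map", call. = FALSE)
  v
}
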