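# Transcription-unit map refinement against a primary-TSS table, and
# strand-aware promoter window extraction.

# 0-based index of a TU's first transcribed base (its 5' end).
tu_five_prime0 <- function(tus) {
  ifelse(tus$strand == "+", tus$start, tus$end - 1L)
}

#' Assign genes to transcription units
#'
#' A gene belongs to the same-strand, same-replicon TU its interval overlaps;
#' if several TUs overlap it, the one with the largest overlap wins.
#'
#' @param tus TU table (tu_id, replicon, start, end, strand; 0-based
#'   half-open).
#' @param genes Gene table.
#' @return List: `membership` data.frame (gene_id, tu_id) and `members`, a
#'   named list of gene-id vectors per TU ordered 5' to 3'.
#' @export
assign_genes_to_tus <- function(tus, genes) {
  check_gene_table(genes)
  key_t <- paste(tus$replicon, tus$strand)
  key_g <- paste(genes$replicon, genes$strand)
  rows <- list()
  for (k in unique(key_t)) {
    ti <- which(key_t == k)
    gi <- which(key_g == k)
    if (!length(gi)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = genes$start[gi] + 1L, end = genes$end[gi]),
      IRanges::IRanges(start = tus$start[ti] + 1L, end = tus$end[ti]))
    if (!length(ov)) next
    qh <- gi[S4Vectors::queryHits(ov)]
    sh <- ti[S4Vectors::subjectHits(ov)]
    w <- pmin(genes$end[qh], tus$end[sh]) - pmax(genes$start[qh], tus$start[sh])
    rows[[k]] <- data.frame(gene_idx = qh, tu_idx = sh, overlap = w)
  }
  if (!length(rows)) {
    membership <- data.frame(gene_id = character(), tu_id = character(),
                             stringsAsFactors = FALSE)
  } else {
    hits <- do.call(rbind, rows)
    # keep the largest-overlap TU per gene (ties: first tu_id)
    hits <- hits[order(hits$gene_idx, -hits$overlap,
                       tus$tu_id[hits$tu_idx]), ]
    hits <- hits[!duplicated(hits$gene_idx), ]
    membership <- data.frame(gene_id = genes$gene_id[hits$gene_idx],
                             tu_id = tus$tu_id[hits$tu_idx],
                             stringsAsFactors = FALSE)
  }
  members <- lapply(stats::setNames(seq_len(nrow(tus)), tus$tu_id),
                    function(i) {
    ids <- membership$gene_id[membership$tu_id == tus$tu_id[i]]
    if (!length(ids)) return(character(0))
    g <- genes[match(ids, genes$gene_id), ]
    ord <- if (tus$strand[i] == "+") order(g$start) else order(-g$end)
    ids[ord]
  })
  list(membership = membership, members = members)
}

#' Match primary TSSs to transcription units
#'
#' A TSS carrying a gene id is routed through that gene's TU (the usual case
#' when TSS calling already assigned genes upstream of this analysis); a
#' gene-less TSS is matched positionally to the nearest same-strand TU whose
#' 5' end lies within `max_distance_bp` downstream, or that contains the
#' TSS.  A TSS strictly downstream of the TU's first cistron translation
#' start is flagged `internal`; a TSS whose gene belongs to no TU is
#' flagged `orphan`; anything else unmatched is `unassigned`.
#'
#' @param tss TSS table (1-based positions).
#' @param tus TU table.
#' @param genes Gene table (needed for internal/orphan classification).
#' @param max_distance_bp Maximum upstream distance for positional matching
#'   (default 500).
#' @return Data.frame, one row per TSS: replicon, position, strand, gene_id,
#'   tu_id, distance_bp (TSS to annotated TU 5' end), status in
#'   `assigned` / `internal` / `orphan` / `unassigned`.
#' @export
match_tss_to_tu <- function(tss, tus, genes, max_distance_bp = 500L) {
  stopifnot(is.data.frame(tss), is.data.frame(tus))
  check_gene_table(genes)
  asg <- assign_genes_to_tus(tus, genes)
  gene_tu <- stats::setNames(asg$membership$tu_id, asg$membership$gene_id)
  first_start0 <- first_cistron_start0(tus, genes, asg$members)
  five0 <- tu_five_prime0(tus)

  n <- nrow(tss)
  out <- data.frame(replicon = tss$replicon, position = tss$position,
                    strand = tss$strand, gene_id = tss$gene_id,
                    tu_id = NA_character_, distance_bp = NA_integer_,
                    status = "unassigned", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p0 <- tss$position[i] - 1L
    gid <- tss$gene_id[i]
    cand <- NULL
    if (!is.na(gid) && gid %in% genes$gene_id) {
      if (is.na(gene_tu[gid])) {
        out$status[i] <- "orphan"
        next
      }
      cand <- which(tus$tu_id == gene_tu[[gid]])
    } else {
      cand <- which(tus$replicon == tss$replicon[i] &
                      tus$strand == tss$strand[i])
    }
    if (!length(cand)) next
    dist5 <- abs(p0 - five0[cand])
    inside <- p0 >= tus$start[cand] & p0 < tus$end[cand]
    upstream <- if (tss$strand[i] == "+") p0 < tus$start[cand]
                else p0 > five0[cand]
    eligible <- inside | (upstream & dist5 <= max_distance_bp)
    # strand/replicon guard for gene-routed candidates
    eligible <- eligible & tus$strand[cand] == tss$strand[i] &
      tus$replicon[cand] == tss$replicon[i]
    if (!any(eligible)) next
    cand <- cand[eligible]
    dist5 <- dist5[eligible]
    j <- cand[order(dist5, tus$tu_id[cand])][1]
    out$tu_id[i] <- tus$tu_id[j]
    out$distance_bp[i] <- as.integer(min(dist5))
    fc0 <- first_start0[j]
    is_internal <- if (is.na(fc0)) FALSE
      else if (tss$strand[i] == "+") p0 > fc0 else p0 < fc0
    out$status[i] <- if (is_internal) "internal" else "assigned"
  }
  out
}

# 0-based translation start of each TU's first cistron (NA for gene-less TUs).
first_cistron_start0 <- function(tus, genes, members) {
  vapply(seq_len(nrow(tus)), function(i) {
    ids <- members[[tus$tu_id[i]]]
    if (!length(ids)) return(NA_integer_)
    g <- genes[genes$gene_id == ids[1], ]
    if (tus$strand[i] == "+") g$start else g$end - 1L
  }, integer(1))
}

#' Refine a transcription-unit map against primary TSSs
#'
#' Applies the three revision rules: (i) for each TU with a matched
#' non-internal primary TSS, the 5' coordinate is moved to the TSS (3' end,
#' strand and replicon untouched; when several TSSs match, the one nearest
#' the annotated 5' end wins, ties going to the more upstream TSS);
#' (ii) each TU with an internal primary TSS is shortened to start at that
#' TSS — by default the cistrons upstream of the internal TSS are discarded
#' (and logged), or retained as a residual unit with
#' `keep_upstream_remainder = TRUE`; (iii) each gene with an assigned TSS
#' that belongs to no TU becomes a new single-gene TU running from its TSS
#' to its gene 3' end.  A refinement that would produce an empty interval
#' leaves the TU unchanged and logs it.
#'
#' @inheritParams match_tss_to_tu
#' @param keep_upstream_remainder Keep cistrons upstream of an internal TSS
#'   as a residual TU (id suffix `_up`)?  Default FALSE (discard with log).
#' @return List with `tus` (refined TU table), `report` (class
#'   `tu_adjustment_report`) and `matches` (the TSS-TU match table).
#' @export
refine_tu_map <- function(tus, tss, genes, max_distance_bp = 500L,
                          keep_upstream_remainder = FALSE) {
  m <- match_tss_to_tu(tss, tus, genes, max_distance_bp = max_distance_bp)
  members <- assign_genes_to_tus(tus, genes)$members
  five0_old <- tu_five_prime0(tus)

  refined <- tus[, c("tu_id", "replicon", "start", "end", "strand")]
  ledger <- data.frame(tu_id = tus$tu_id, replicon = tus$replicon,
                       strand = tus$strand,
                       old_five_prime = five0_old + 1L,
                       new_five_prime = five0_old + 1L,
                       adjustment_bp = 0L, class = "unchanged",
                       note = "", stringsAsFactors = FALSE)
  dropped_genes <- character(0)

  # (i) 5' adjustment from the nearest non-internal matched TSS
  prim <- m[m$status == "assigned" & !is.na(m$tu_id), ]
  if (nrow(prim)) {
    for (id in unique(prim$tu_id)) {
      rows <- prim[prim$tu_id == id, ]
      i <- which(tus$tu_id == id)
      # nearest the annotated 5' end; ties -> more upstream TSS
      upstream_rank <- if (tus$strand[i] == "+") rows$position
                       else -rows$position
      rows <- rows[order(rows$distance_bp, upstream_rank), ]
      p0 <- rows$position[1] - 1L
      if (tus$strand[i] == "+") {
        new_start <- p0; new_end <- refined$end[i]
      } else {
        new_start <- refined$start[i]; new_end <- p0 + 1L
      }
      if (new_start >= new_end) {
        ledger$note[i] <- "refused: would produce empty interval"
        next
      }
      adj <- if (tus$strand[i] == "+") refined$start[i] - new_start
             else new_end - refined$end[i]
      refined$start[i] <- new_start
      refined$end[i] <- new_end
      ledger$new_five_prime[i] <- p0 + 1L
      ledger$adjustment_bp[i] <- as.integer(adj)
      ledger$class[i] <- if (adj != 0L) "adjusted" else "unchanged"
    }
  }

  # (ii) internal-TSS shortening
  extra <- list()
  internal <- m[m$status == "internal" & !is.na(m$tu_id), ]
  if (nrow(internal)) {
    for (id in unique(internal$tu_id)) {
      rows <- internal[internal$tu_id == id, ]
      i <- which(tus$tu_id == id)
      # most upstream internal TSS retains the most cistrons
      upstream_rank <- if (tus$strand[i] == "+") rows$position
                       else -rows$position
      p0 <- rows$position[order(upstream_rank)][1] - 1L
      if (tus$strand[i] == "+") {
        short_start <- p0; short_end <- refined$end[i]
        res_start <- refined$start[i]; res_end <- p0
      } else {
        short_start <- refined$start[i]; short_end <- p0 + 1L
        res_start <- p0 + 1L; res_end <- refined$end[i]
      }
      if (short_start >= short_end) {
        ledger$note[i] <- "refused: internal shortening would empty the TU"
        next
      }
      old_members <- members[[id]]
      kept <- genes_in_interval(genes, old_members, tus$replicon[i],
                                short_start, short_end, tus$strand[i])
      lost <- setdiff(old_members, kept)
      refined$start[i] <- short_start
      refined$end[i] <- short_end
      ledger$new_five_prime[i] <- p0 + 1L
      ledger$class[i] <- "shortened_internal"
      ledger$adjustment_bp[i] <-
        as.integer(abs(p0 - (ledger$old_five_prime[i] - 1L)))
      if (keep_upstream_remainder && res_start < res_end &&
          length(lost)) {
        extra[[length(extra) + 1L]] <- data.frame(
          tu_id = paste0(id, "_up"), replicon = tus$replicon[i],
          start = res_start, end = res_end, strand = tus$strand[i],
          stringsAsFactors = FALSE)
        ledger$note[i] <- sprintf("upstream cistrons kept in %s_up", id)
      } else if (length(lost)) {
        dropped_genes <- c(dropped_genes, lost)
        ledger$note[i] <- sprintf("dropped upstream cistron(s): %s",
                                  paste(lost, collapse = ","))
      }
    }
  }

  # (iii) orphan genes -> new single-gene TUs
  orphan <- m[m$status == "orphan" & !is.na(m$gene_id), ]
  added <- character(0)
  if (nrow(orphan)) {
    for (gid in unique(orphan$gene_id)) {
      g <- genes[genes$gene_id == gid, ]
      rows <- orphan[orphan$gene_id == gid, ]
      # nearest TSS to the gene translation start
      g5 <- if (g$strand == "+") g$start else g$end - 1L
      p0 <- rows$position[order(abs(rows$position - 1L - g5))][1] - 1L
      if (g$strand == "+") { ns <- p0; ne <- g$end }
      else { ns <- g$start; ne <- p0 + 1L }
      if (ns >= ne) next
      new_id <- paste0("TU_", gid)
      extra[[length(extra) + 1L]] <- data.frame(
        tu_id = new_id, replicon = g$replicon, start = ns, end = ne,
        strand = g$strand, stringsAsFactors = FALSE)
      added <- c(added, new_id)
      ledger <- rbind(ledger, data.frame(
        tu_id = new_id, replicon = g$replicon, strand = g$strand,
        old_five_prime = NA_integer_, new_five_prime = p0 + 1L,
        adjustment_bp = NA_integer_, class = "added",
        note = sprintf("orphan gene %s", gid), stringsAsFactors = FALSE))
    }
  }
  if (length(extra))
    refined <- rbind(refined, do.call(rbind, extra)[,
      c("tu_id", "replicon", "start", "end", "strand")])
  rownames(refined) <- NULL

  adj_rows <- ledger$class == "adjusted"
  report <- structure(list(
    n_tus_adjusted = sum(adj_rows),
    median_abs_adjustment_bp = if (any(adj_rows))
      stats::median(abs(ledger$adjustment_bp[adj_rows])) else NA_real_,
    n_adjustments_gt100 = sum(abs(ledger$adjustment_bp[adj_rows]) > 100L),
    n_internal_shortened = sum(ledger$class == "shortened_internal"),
    n_orphan_added = sum(ledger$class == "added"),
    n_unchanged = sum(ledger$class == "unchanged"),
    dropped_genes = unique(dropped_genes),
    ledger = ledger), class = "tu_adjustment_report")
  list(tus = refined, report = report, matches = m)
}

# Member genes (by id) fully containable within [start, end) on a strand.
genes_in_interval <- function(genes, ids, replicon, start, end, strand) {
  g <- genes[match(ids, genes$gene_id), ]
  keep <- g$replicon == replicon & g$strand == strand &
    g$start >= start & g$end <= end
  ids[keep]
}

#' @export
print.tu_adjustment_report <- function(x, ...) {
  cat("TU adjustment report\n")
  cat(sprintf("  5'-adjusted TUs:        %d (median |adj| %s bp, %d > 100 bp)\n",
              x$n_tus_adjusted,
              format(x$median_abs_adjustment_bp), x$n_adjustments_gt100))
  cat(sprintf("  internal-TSS shortened: %d\n", x$n_internal_shortened))
  cat(sprintf("  orphan TUs added:       %d\n", x$n_orphan_added))
  cat(sprintf("  unchanged:              %d\n", x$n_unchanged))
  if (length(x$dropped_genes))
    cat(sprintf("  dropped upstream cistrons: %s\n",
                paste(x$dropped_genes, collapse = ", ")))
  invisible(x)
}

#' Convert an adjustment report to JSON-ready summary + write outputs
#' @param report A `tu_adjustment_report`.
#' @param dir Output directory; writes `tu_adjustment_ledger.tsv` and
#'   `tu_adjustment_summary.json`.
#' @export
write_adjustment_report <- function(report, dir) {
  stopifnot(inherits(report, "tu_adjustment_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$ledger,
                     file.path(dir, "tu_adjustment_ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- report[c("n_tus_adjusted", "median_abs_adjustment_bp",
                   "n_adjustments_gt100", "n_internal_shortened",
                   "n_orphan_added", "n_unchanged", "dropped_genes")]
  jsonlite::write_json(summ, file.path(dir, "tu_adjustment_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Extract strand-aware promoter windows around TSSs
#'
#' For each TSS, extracts the genomic window from `upstream` bases before to
#' `downstream` bases after the TSS (61 nt at the defaults of 50 and 10);
#' minus-strand windows are reverse-complemented so the TSS-proximal end is
#' 3'-most.  Windows that would run off a replicon end are dropped and
#' counted.  Record ids are `replicon:position:strand`.
#'
#' @param tss TSS table (1-based positions).
#' @param genome Named `DNAStringSet`.
#' @param upstream,downstream Window extent in bp (defaults 50 and 10).
#' @return List: `windows` (`DNAStringSet`) and `skipped` (data.frame of
#'   dropped TSSs with reasons).
#' @export
extract_promoter_windows <- function(tss, genome, upstream = 50L,
                                     downstream = 10L) {
  stopifnot(is.data.frame(tss), is(genome, "DNAStringSet"))
  rep_len <- stats::setNames(Biostrings::width(genome), names(genome))
  skipped <- list()
  seqs <- character(0)
  ids <- character(0)
  for (i in seq_len(nrow(tss))) {
    rep_name <- tss$replicon[i]
    p <- tss$position[i]
    id <- sprintf("%s:%d:%s", rep_name, p, tss$strand[i])
    if (!rep_name %in% names(rep_len) || p < 1L || p > rep_len[[rep_name]]) {
      warning("TSS off sequence, skipped: ", id, call. = FALSE)
      skipped[[length(skipped) + 1L]] <-
        data.frame(replicon = rep_name, position = p, strand = tss$strand[i],
                   reason = "off_sequence", stringsAsFactors = FALSE)
      next
    }
    if (tss$strand[i] == "+") {
      from <- p - upstream; to <- p + downstream
    } else {
      from <- p - downstream; to <- p + upstream
    }
    if (from < 1L || to > rep_len[[rep_name]]) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(replicon = rep_name, position = p, strand = tss$strand[i],
                   reason = "clipped", stringsAsFactors = FALSE)
      next
    }
    s <- Biostrings::subseq(genome[[rep_name]], start = from, end = to)
    if (tss$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs <- c(seqs, as.character(s))
    ids <- c(ids, id)
  }
  windows <- Biostrings::DNAStringSet(seqs)
  names(windows) <- ids
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(replicon = character(), position = integer(),
               strand = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(windows = windows, skipped = skipped)
}
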