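# Small published summary tables used by the worked examples: the per-replicon
# direction tally and genome-wide direction counts of the Haloferax volcanii
# TFEbeta-deletion transcriptome response.

#' Replicon-level direction tally of the H. volcanii TFEbeta-deletion response
#'
#' Counts of detected genes and of genes with increased/decreased relative
#' mRNA abundance after *tfeB* deletion, per replicon (main chromosome
#' excluding the chromosomally integrated pHV4, and the three megaplasmids).
#' Feeding this table to [replicon_contrasts_counts()] reproduces the
#' replicon-vs-main-chromosome Fisher contrasts of the study design this
#' package implements.
#'
#' @return Data.frame with columns `replicon`, `detected`, `increased`,
#'   `decreased`.
#' @examples
#' replicon_contrasts_counts(hvo_tfeb_replicon_counts(), "main_chromosome")
#' @export
hvo_tfeb_replicon_counts <- function() {
  data.frame(
    replicon = c("main_chromosome", "pHV1", "pHV3", "pHV4"),
    detected = c(2940L, 75L, 372L, 606L),
    increased = c(617L, 1L, 81L, 82L),
    decreased = c(534L, 35L, 27L, 142L),
    stringsAsFactors = FALSE)
}

#' Genome-wide direction counts of the H. volcanii TFEbeta-deletion response
#'
#' Numbers of up- and downregulated genes (adjusted p < 0.01) among all
#' detected genes.
#'
#' @return List: `n_up`, `n_down`, `n_detected`.
#' @export
hvo_tfeb_de_counts <- function() {
  list(n_up = 781L, n_down = 738L, n_detected = 3993L)
}
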