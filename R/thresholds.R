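#' Detection thresholds
#'
#' Bundles every numeric knob of the circularity pipelines into one validated
#' list. Defaults reproduce the published workflow for a plasmid-enriched,
#' MDA-amplified metamobilome sequenced as 100 nt Illumina paired-end reads
#' (450--550 nt inserts) plus ~400 nt single-end reads.
#'
#' @param min_terminal_overlap Minimum terminal duplication (inclusive)
#'   accepted as evidence of circularity in the paired-end pipeline step one
#'   (nt). The default of 40 reflects identical contig ends of around 40 nt
#'   or more being diagnostic of an MDA-linearized circle.
#' @param max_terminal_overlap_frac Cap on the duplication length as a
#'   fraction of contig length; a duplication cannot meaningfully exceed one
#'   full copy of the circle.
#' @param min_contig_len_pe Minimum contig length for the paired-end pipeline
#'   (nt). 1000 nt keeps the two 500 nt end windows of step two from
#'   overlapping.
#' @param pe_end_window Read pairs must map within this many nt of the
#'   (trimmed) contig ends to count as junction support.
#' @param pe_min_mate_aln Minimum aligned length per mate (nt).
#' @param min_supporting_pairs Number of qualifying pairs required to confirm
#'   a junction (>= 1 mirrors "discard contigs where no read pairs mapped on
#'   opposite ends").
#' @param se_end_window Half-width w of the single-end junction window; the
#'   window is `suffix(w) + prefix(w)` = 2w nt (default 100, window 200 nt).
#' @param se_min_span_per_side Minimum gapless read coverage on each side of
#'   the window midpoint (nt); ">99 nt on both ends" = at least 99.
#' @param se_min_identity Minimum percent identity of the window alignment.
#' @param se_allow_gaps Accept gapped window alignments (the published rule
#'   is gapless; kept as a switch).
#' @param hmm_evalue_cutoff E-value cutoff for profile-HMM domain hits.
#' @param vpcr_max_mismatch,vpcr_max_insertion,vpcr_max_deletion Per-category
#'   edit tolerances of the virtual-PCR primer binding search (each applied
#'   simultaneously).
#' @param vpcr_min_template_len Minimum contig length loaded into the
#'   mispriming database (nt); 201 means contigs >200 nt.
#'
#' @return A named list of class `circ_thresholds`.
#' @examples
#' th <- thresholds()
#' th$pe_end_window
#' thresholds(min_supporting_pairs = 3)$min_supporting_pairs
#' @export
thresholds <- function(min_terminal_overlap = 40L,
                       max_terminal_overlap_frac = 0.5,
                       min_contig_len_pe = 1000L,
                       pe_end_window = 500L,
                       pe_min_mate_aln = 90L,
                       min_supporting_pairs = 1L,
                       se_end_window = 100L,
                       se_min_span_per_side = 99L,
                       se_min_identity = 98,
                       se_allow_gaps = FALSE,
                       hmm_evalue_cutoff = 1e-4,
                       vpcr_max_mismatch = 1L,
                       vpcr_max_insertion = 1L,
                       vpcr_max_deletion = 1L,
                       vpcr_min_template_len = 201L) {
  th <- list(
    min_terminal_overlap = as.integer(min_terminal_overlap),
    max_terminal_overlap_frac = as.numeric(max_terminal_overlap_frac),
    min_contig_len_pe = as.integer(min_contig_len_pe),
    pe_end_window = as.integer(pe_end_window),
    pe_min_mate_aln = as.integer(pe_min_mate_aln),
    min_supporting_pairs = as.integer(min_supporting_pairs),
    se_end_window = as.integer(se_end_window),
    se_min_span_per_side = as.integer(se_min_span_per_side),
    se_min_identity = as.numeric(se_min_identity),
    se_allow_gaps = isTRUE(se_allow_gaps),
    hmm_evalue_cutoff = as.numeric(hmm_evalue_cutoff),
    vpcr_max_mismatch = as.integer(vpcr_max_mismatch),
    vpcr_max_insertion = as.integer(vpcr_max_insertion),
    vpcr_max_deletion = as.integer(vpcr_max_deletion),
    vpcr_min_template_len = as.integer(vpcr_min_template_len)
  )
  lens <- c("min_terminal_overlap", "min_contig_len_pe", "pe_end_window",
            "pe_min_mate_aln", "min_supporting_pairs", "se_end_window",
            "se_min_span_per_side", "vpcr_min_template_len")
  for (nm in lens) {
    if (is.na(th[[nm]]) || th[[nm]] < 1L) {
      abort(sprintf("`%s` must be a positive integer.", nm))
    }
  }
  if (!(th$max_terminal_overlap_frac > 0 && th$max_terminal_overlap_frac <= 0.5)) {
    abort("`max_terminal_overlap_frac` must be in (0, 0.5].")
  }
  if (!(th$se_min_identity > 0 && th$se_min_identity <= 100)) {
    abort("`se_min_identity` must be in (0, 100].")
  }
  if (th$se_min_span_per_side > th$se_end_window) {
    abort("`se_min_span_per_side` cannot exceed `se_end_window`.")
  }
  if (th$hmm_evalue_cutoff < 0) abort("`hmm_evalue_cutoff` must be >= 0.")
  if (any(c(th$vpcr_max_mismatch, th$vpcr_max_insertion, th$vpcr_max_deletion) < 0L)) {
    abort("virtual-PCR edit tolerances must be >= 0.")
  }
  structure(th, class = "circ_thresholds")
}

#' @export
print.circ_thresholds <- function(x, ...) {
  cat("<circ_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
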