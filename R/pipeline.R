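# End-to-end orchestration: detect (PE and/or SE) -> dedup -> optional
# annotation -> reports. The per-stage funnel counts double as the run log.

#' Run the full circular-element workflow
#'
#' Executes whichever detection pipelines have inputs, deduplicates across
#' them, optionally classifies elements from supplied gene calls and domain
#' hits, and (optionally) writes a FASTA of representative elements plus TSV
#' reports to `out_dir`. Representative elements are renamed
#' `<prefix><ordinal>` (zero-padded); the mapping back to original contig
#' ids is kept in the cluster table.
#'
#' @param pe_contigs,pe_reads,pe_alignments Paired-end inputs (see
#'   [detect_circular_pe()]); `pe_contigs = NULL` skips the PE stage.
#' @param se_contigs,se_reads Single-end inputs; `se_contigs = NULL` skips
#'   the SE stage.
#' @param gene_calls,domain_hits Optional annotation inputs (see
#'   [classify_elements()]); gene calls must reference the renamed element
#'   ids *or* original contig ids (both are accepted).
#' @param reference_db Optional reference sequences for the single-end
#'   junction-repeat screen.
#' @param th A [thresholds()] object.
#' @param dedup_mode,dedup_policy Passed to [dedup_elements()].
#' @param prefix Element name prefix for representatives.
#' @param out_dir Optional output directory (created if needed).
#' @return List of class `circ_pipeline`: `elements` (renamed
#'   representatives), `clusters` (member map incl. original ids), `pe`,
#'   `se` (the raw `circ_detection` results or `NULL`), `annotation` (or
#'   `NULL`), `funnel` (combined stage counts).
#' @export
run_pipeline <- function(pe_contigs = NULL, pe_reads = NULL, pe_alignments = NULL,
                         se_contigs = NULL, se_reads = NULL,
                         gene_calls = NULL, domain_hits = NULL,
                         reference_db = character(0),
                         th = thresholds(),
                         dedup_mode = "exact",
                         dedup_policy = "prefer_single_end",
                         prefix = "pRC", out_dir = NULL) {
  if (is.null(pe_contigs) && is.null(se_contigs)) {
    abort("at least one of `pe_contigs` / `se_contigs` must be supplied.")
  }
  pe <- se <- NULL
  if (!is.null(pe_contigs)) {
    pe <- detect_circular_pe(pe_contigs, reads = pe_reads,
                             alignments = pe_alignments, th = th)
  }
  se <- if (!is.null(se_contigs)) {
    detect_circular_se(se_contigs, reads = se_reads, th = th,
                       reference_db = reference_db)
  }
  combined <- bind_rows(
    if (!is.null(pe)) as_tibble(pe),
    if (!is.null(se)) as_tibble(se)
  )
  reps <- dedup_elements(combined, mode = dedup_mode, policy = dedup_policy)
  members <- attr(reps, "members")

  width <- max(5L, nchar(nrow(reps)))
  reps$element_id <- sprintf("%s%0*d", prefix, width, seq_len(nrow(reps)))
  clusters <- left_join(members,
                        reps[, c("cluster_id", "element_id")], by = "cluster_id") |>
    rename(contig_id = "id")

  elements <- reps
  elements$contig_id <- elements$id
  elements$id <- elements$element_id
  elements$element_id <- NULL

  annotation <- NULL
  if (!is.null(gene_calls) && !is.null(domain_hits)) {
    gc_tbl <- as_gene_call_tbl(gene_calls)
    # accept original contig ids and translate to element ids
    remap <- match(gc_tbl$element_id, elements$contig_id)
    gc_tbl$element_id <- ifelse(is.na(remap), gc_tbl$element_id, elements$id[remap])
    annotation <- classify_elements(elements, gc_tbl, domain_hits, th = th)
  }

  funnel <- bind_rows(
    if (!is.null(pe)) mutate(attr(pe, "funnel"), pipeline = "paired_end"),
    if (!is.null(se)) mutate(attr(se, "funnel"), pipeline = "single_end"),
    tibble(stage = "deduplicated", count = nrow(elements), pipeline = "combined"),
    if (!is.null(annotation)) {
      tibble(stage = "replicon_positive",
             count = attr(annotation, "summary")$n_replicon_elements,
             pipeline = "combined")
    }
  )

  res <- structure(list(elements = elements, clusters = clusters,
                        pe = pe, se = se, annotation = annotation,
                        funnel = funnel),
                   class = "circ_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(res$elements, file.path(out_dir, "elements.fasta"))
  readr::write_tsv(res$clusters, file.path(out_dir, "clusters.tsv"))
  readr::write_tsv(res$funnel, file.path(out_dir, "funnel.tsv"))
  el <- res$elements |>
    select(dplyr::any_of(c("id", "contig_id", "length", "source_platform",
                           "overlap_trimmed", "n_supporting_pairs",
                           "n_spanning_reads", "uniqueness_clean", "cluster_id")))
  readr::write_tsv(el, file.path(out_dir, "elements.tsv"))
  if (!is.null(res$annotation)) {
    readr::write_tsv(as_tibble(res$annotation), file.path(out_dir, "annotation.tsv"))
    readr::write_tsv(attr(res$annotation, "family_counts"),
                     file.path(out_dir, "replicon_family_counts.tsv"))
  }
  invisible(out_dir)
}

#' @export
print.circ_pipeline <- function(x, ...) {
  cat("<circ_pipeline>\n")
  cat(sprintf("  elements: %d (after dedup)\n", nrow(x$elements)))
  if (!is.null(x$pe)) cat(sprintf("  paired-end confirmed: %d\n", nrow(x$pe)))
  if (!is.null(x$se)) cat(sprintf("  single-end confirmed: %d\n", nrow(x$se)))
  if (!is.null(x$annotation)) {
    s <- attr(x$annotation, "summary")
    cat(sprintf("  replicon-positive: %d (%d domain instances)\n",
                s$n_replicon_elements, s$n_replicon_instances))
  }
  invisible(x)
}

#' @method tidy circ_pipeline
#' @export
tidy.circ_pipeline <- function(x, ...) as_tibble(x$elements)

#' @method glance circ_pipeline
#' @export
glance.circ_pipeline <- function(x, ...) {
  tidyr::pivot_wider(x$funnel,
                     names_from = c("pipeline", "stage"), values_from = "count")
}
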