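#' Validate and normalise a contig table
#'
#' Contigs are plain tibbles with columns `id` (unique label), `seq` (DNA over
#' A,C,G,T,N; case-normalised to upper), and optionally `coverage`
#' (non-negative assembler-reported depth) and `platform` (`"paired_end"`,
#' `"single_end"` or `"unknown"`). All detection functions call this on
#' ingest.
#'
#' @param contigs A data frame with at least `id` and `seq` columns.
#' @return A tibble with columns `id`, `seq`, `length`, `coverage`,
#'   `platform`.
#' @examples
#' as_contig_tbl(data.frame(id = "c1", seq = "acgtACGT"))
#' @export
as_contig_tbl <- function(contigs) {
  if (!is.data.frame(contigs)) abort("`contigs` must be a data frame.")
  need <- setdiff(c("id", "seq"), names(contigs))
  if (length(need)) abort(paste0("`contigs` is missing column(s): ", paste(need, collapse = ", ")))
  out <- as_tibble(contigs)
  out$id <- as.character(out$id)
  out$seq <- str_to_upper(as.character(out$seq))
  if (anyNA(out$id) || any(out$id == "")) abort("contig ids must be non-missing and non-empty.")
  if (anyDuplicated(out$id)) {
    abort(paste0("duplicate contig id(s): ",
                 paste(unique(out$id[duplicated(out$id)]), collapse = ", ")))
  }
  assert_dna(out$seq, "contigs$seq")
  if (any(str_length(out$seq) == 0L)) abort("contig sequences must be non-empty.")
  if (!"coverage" %in% names(out)) out$coverage <- NA_real_
  out$coverage <- as.numeric(out$coverage)
  if (any(!is.na(out$coverage) & out$coverage < 0)) abort("`coverage` must be non-negative.")
  if (!"platform" %in% names(out)) out$platform <- "unknown"
  ok <- out$platform %in% c("paired_end", "single_end", "unknown")
  if (!all(ok)) abort("`platform` must be one of paired_end, single_end, unknown.")
  out$length <- str_length(out$seq)
  out[, c("id", "seq", "length", "coverage", "platform")]
}
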