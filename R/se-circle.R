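# Single-end pipeline: build a 2w-nt junction window (last w + first w bases
# of the contig) and require one read to cover at least
# `se_min_span_per_side` nt on both sides of the window midpoint, gapless and
# at high identity. Used for long single-end reads (~400 nt) where no mate
# information exists.

#' Build the junction window of a contig
#'
#' The window is `suffix(contig, w) + prefix(contig, w)` where
#' `w = se_end_window`; its midpoint (index `w`, 0-based) is the circular
#' junction. A read aligning across the midpoint demonstrates that the
#' contig's end runs on into its start.
#'
#' @param seq A single contig sequence.
#' @param th A [thresholds()] object.
#' @return The window string (length `2w`), or `NA` if the contig is shorter
#'   than `2w` (skipped, not an error).
#' @examples
#' build_junction_window("ACGTTGCA", thresholds(se_end_window = 3, se_min_span_per_side = 3))
#' # "GCAACG"
#' @export
build_junction_window <- function(seq, th = thresholds()) {
  assert_dna(seq)
  stopifnot(length(seq) == 1L)
  seq <- str_to_upper(seq)
  w <- th$se_end_window
  L <- str_length(seq)
  if (L < 2L * w) return(NA_character_)
  paste0(str_sub(seq, L - w + 1L, L), str_sub(seq, 1L, w))
}

#' Does a window alignment demonstrate a spanning read?
#'
#' Vectorised over alignment rows. An alignment passes when it is gapless
#' (unless `se_allow_gaps`), has identity >= `se_min_identity` percent, and
#' covers at least `se_min_span_per_side` nt on each side of the window
#' midpoint: `midpoint - window_start` on the left and
#' `window_end - midpoint` on the right.
#'
#' @param aln Data frame with columns `window_start`, `window_end` (0-based
#'   half-open on the window), `identity` (percent), `gapped` (logical).
#' @param th A [thresholds()] object.
#' @return Logical vector, one per row.
#' @examples
#' th <- thresholds()
#' read_spans_junction(data.frame(window_start = 0, window_end = 200,
#'                                identity = 99, gapped = FALSE), th)  # TRUE
#' @export
read_spans_junction <- function(aln, th = thresholds()) {
  aln <- as_tibble(aln)
  need <- setdiff(c("window_start", "window_end", "identity", "gapped"), names(aln))
  if (length(need)) abort(paste0("`aln` is missing column(s): ", paste(need, collapse = ", ")))
  if (any(aln$window_end <= aln$window_start)) {
    abort("window_end must be greater than window_start.")
  }
  w <- th$se_end_window
  left <- w - aln$window_start
  right <- aln$window_end - w
  (!aln$gapped | th$se_allow_gaps) &
    aln$identity >= th$se_min_identity &
    left >= th$se_min_span_per_side &
    right >= th$se_min_span_per_side
}

#' Screen a junction window against a reference database for repeats
#'
#' A circular call driven by a repetitive element rather than a true
#' junction would show its 2w-nt window twice in a single reference
#' replicon. The screen reports `TRUE` (clean) when no single reference
#' record contains the window sequence two or more times as an exact
#' substring on either strand. A failed screen flags the element as possibly
#' repeat-driven; it does not discard it.
#'
#' @param window_seq The window string.
#' @param reference_db Character vector of reference sequences (may be
#'   empty).
#' @return `TRUE` (clean) or `FALSE` (possible repeat).
#' @export
junction_uniqueness_screen <- function(window_seq, reference_db = character(0)) {
  stopifnot(length(window_seq) == 1L, !is.na(window_seq))
  if (is.data.frame(reference_db)) reference_db <- reference_db$seq
  if (length(reference_db) == 0L) return(TRUE)
  assert_dna(reference_db, "reference_db")
  wpat <- Biostrings::DNAString(str_to_upper(window_seq))
  rpat <- Biostrings::reverseComplement(wpat)
  for (rec in str_to_upper(reference_db)) {
    subj <- Biostrings::DNAString(rec)
    n <- Biostrings::countPattern(wpat, subj) + Biostrings::countPattern(rpat, subj)
    if (n >= 2L) return(FALSE)
  }
  TRUE
}

# Gapless single-diagonal scoring of an oriented read against a window at
# diagonal d (read position of window position 0 is -d ... specifically
# window pos j pairs with read pos d + j). Returns NULL when the overlap is
# empty.
score_window_diagonal <- function(read_int, window_int, d) {
  lw <- length(window_int)
  lr <- length(read_int)
  ws <- max(0L, -d)
  we <- min(lw, lr - d)
  if (we <= ws) return(NULL)
  wi <- window_int[(ws + 1L):we]
  ri <- read_int[(d + ws + 1L):(d + we)]
  matches <- sum(wi == ri)
  list(window_start = ws, window_end = we, columns = we - ws, matches = matches,
       identity = 100 * matches / (we - ws))
}

#' Best gapless alignment of a read against a junction window
#'
#' Exhaustive single-diagonal search: every ungapped offset of the read
#' against the window is scored by match count and the best diagonal is
#' returned (ties broken towards more aligned columns, then the smaller
#' window start). Strand is the caller's responsibility; pass the reverse
#' complement of the read to score the minus strand.
#'
#' @param read,window DNA strings.
#' @return A one-row tibble with `window_start`, `window_end`, `columns`,
#'   `matches`, `identity`, `gapped` (always `FALSE`), or a zero-row tibble
#'   if either input is empty.
#' @export
align_read_to_window <- function(read, window) {
  assert_dna(read, "read"); assert_dna(window, "window")
  read_int <- utf8ToInt(str_to_upper(read))
  window_int <- utf8ToInt(str_to_upper(window))
  lr <- length(read_int); lw <- length(window_int)
  empty <- tibble(window_start = integer(0), window_end = integer(0),
                  columns = integer(0), matches = integer(0),
                  identity = numeric(0), gapped = logical(0))
  if (lr == 0L || lw == 0L) return(empty)
  best <- NULL
  for (d in (-(lw - 1L)):(lr - 1L)) {
    sc <- score_window_diagonal(read_int, window_int, d)
    if (is.null(sc)) next
    if (is.null(best) || sc$matches > best$matches ||
        (sc$matches == best$matches && sc$columns > best$columns) ||
        (sc$matches == best$matches && sc$columns == best$columns &&
         sc$window_start < best$window_start)) {
      best <- sc
    }
  }
  tibble(window_start = best$window_start, window_end = best$window_end,
         columns = best$columns, matches = best$matches,
         identity = best$identity, gapped = FALSE)
}

#' Single-end circularity detection
#'
#' For each contig of length >= `2 * se_end_window`: build the junction
#' window, align reads to it on both strands (gapless, seed-anchored
#' diagonals), and call the contig circular when at least one read satisfies
#' [read_spans_junction()]. Passing contigs are reported with their sequence
#' unmodified (`overlap_trimmed = 0`). Each element's window is also screened
#' against `reference_db` for repeats ([junction_uniqueness_screen()]); the
#' result is attached, never used to discard.
#'
#' @param contigs Contig table.
#' @param reads Single-end read table with columns `read_id`, `seq`. Ignored
#'   when `window_alignments` is supplied.
#' @param th A [thresholds()] object.
#' @param reference_db Optional character vector (or tibble with `seq`) of
#'   reference replicons for the uniqueness screen.
#' @param window_alignments Optional pre-computed window alignments (columns
#'   `contig_id`, `read_id`, `window_start`, `window_end`, `identity`,
#'   `gapped`), e.g. parsed from tabular search output, used instead of the
#'   internal aligner.
#' @param seed_len,seed_step Geometry of the exact seeds used to nominate
#'   read/window diagonals for the internal aligner.
#' @return A `circ_detection` tibble as in [detect_circular_pe()], with
#'   `n_spanning_reads` filled, `overlap_trimmed = 0`, and a
#'   `uniqueness_clean` column.
#' @export
detect_circular_se <- function(contigs, reads = NULL, th = thresholds(),
                               reference_db = character(0),
                               window_alignments = NULL,
                               seed_len = 24L, seed_step = 25L) {
  contigs <- as_contig_tbl(contigs)
  n_input <- nrow(contigs)
  w <- th$se_end_window

  contigs$window <- map_chr(contigs$seq, build_junction_window, th = th)
  len_ok <- !is.na(contigs$window)
  skipped <- tibble(id = contigs$id[!len_ok],
                    reason = sprintf("length %d < 2 * se_end_window (%d)",
                                     contigs$length[!len_ok], 2L * w))
  cand <- contigs[len_ok, , drop = FALSE]

  span_tbl <- tibble(contig_id = character(0), read_id = character(0))
  if (nrow(cand)) {
    if (!is.null(window_alignments)) {
      wa <- as_tibble(window_alignments)
      need <- setdiff(c("contig_id", "read_id", "window_start", "window_end",
                        "identity", "gapped"), names(wa))
      if (length(need)) {
        abort(paste0("`window_alignments` is missing column(s): ",
                     paste(need, collapse = ", ")))
      }
      unknown <- setdiff(unique(wa$contig_id), contigs$id)
      if (length(unknown)) {
        abort(paste0("window alignments reference unknown contig id(s): ",
                     paste(head(unknown, 5), collapse = ", ")))
      }
      wa <- wa[wa$contig_id %in% cand$id, , drop = FALSE]
      if (nrow(wa)) {
        wa$spans <- read_spans_junction(wa, th)
        span_tbl <- wa[wa$spans, c("contig_id", "read_id")]
      }
    } else if (!is.null(reads)) {
      span_tbl <- se_window_spans(cand, reads, th, seed_len, seed_step)
    } else {
      abort("supply either `reads` or `window_alignments` as junction evidence.")
    }
  }
  n_span <- span_tbl |>
    distinct(.data$contig_id, .data$read_id) |>
    count(.data$contig_id, name = "n_spanning_reads")
  cand <- left_join(cand, n_span, by = c(id = "contig_id"))
  cand$n_spanning_reads[is.na(cand$n_spanning_reads)] <- 0L
  confirmed <- cand$n_spanning_reads >= 1L
  skipped <- bind_rows(skipped,
                       tibble(id = cand$id[!confirmed], reason = "no junction-spanning reads"))

  out <- cand[confirmed, , drop = FALSE]
  by_contig <- split(span_tbl$read_id, span_tbl$contig_id)
  elements <- tibble(
    id = out$id,
    seq = out$seq,
    length = out$length,
    source_platform = "single_end",
    overlap_trimmed = 0L,
    n_supporting_pairs = 0L,
    n_spanning_reads = as.integer(out$n_spanning_reads),
    supporting_ids = map(out$id, function(cid) sort(unique(by_contig[[cid]]))),
    coverage = out$coverage,
    uniqueness_clean = map_lgl(out$window, junction_uniqueness_screen,
                               reference_db = reference_db)
  )
  elements$canonical_seq <- if (nrow(elements)) canonical_rotation(elements$seq) else character(0)
  funnel <- tibble(
    stage = c("input", "length_pass", "se_confirmed"),
    count = c(n_input, nrow(cand), nrow(elements))
  )
  new_circ_detection(elements, funnel = funnel, platform = "single_end",
                     skipped = skipped)
}

# Seed-anchored spanning-read search shared by detect_circular_se.
# Returns tibble(contig_id, read_id) of reads passing the span test.
se_window_spans <- function(cand, reads, th, seed_len, seed_step) {
  if (!is.data.frame(reads)) abort("`reads` must be a data frame.")
  need <- setdiff(c("read_id", "seq"), names(reads))
  if (length(need)) abort(paste0("`reads` is missing column(s): ", paste(need, collapse = ", ")))
  reads <- as_tibble(reads)
  reads$read_id <- as.character(reads$read_id)
  if (anyDuplicated(reads$read_id)) abort("duplicate read ids in `reads`.")
  w2 <- 2L * th$se_end_window
  seed_len <- as.integer(seed_len)
  offs <- unique(c(seq.int(0L, w2 - seed_len, by = as.integer(seed_step)), w2 - seed_len))
  seeds <- tidyr::expand_grid(window_row = seq_len(nrow(cand)), offset = offs)
  seeds$seq <- str_sub(cand$window[seeds$window_row], seeds$offset + 1L,
                       seeds$offset + seed_len)

  read_f <- str_to_upper(reads$seq)
  read_r <- dna_revcomp(read_f)
  hits_f <- match_seeds_in_reads(seeds$seq, read_f)
  hits_r <- match_seeds_in_reads(seeds$seq, read_r)
  if (nrow(hits_f)) hits_f$orient <- "+"
  if (nrow(hits_r)) hits_r$orient <- "-"
  hits <- bind_rows(hits_f, hits_r)
  if (nrow(hits) == 0L) return(tibble(contig_id = character(0), read_id = character(0)))

  hits$window_row <- seeds$window_row[hits$seed_idx]
  hits$diag <- hits$read_pos - seeds$offset[hits$seed_idx]
  hits <- distinct(hits, .data$window_row, .data$read_idx, .data$orient, .data$diag)

  win_ints <- lapply(cand$window, utf8ToInt)
  read_ints_f <- lapply(read_f, utf8ToInt)
  read_ints_r <- lapply(read_r, utf8ToInt)
  res <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ri <- if (hits$orient[i] == "+") read_ints_f[[hits$read_idx[i]]] else read_ints_r[[hits$read_idx[i]]]
    sc <- score_window_diagonal(ri, win_ints[[hits$window_row[i]]], hits$diag[i])
    if (is.null(sc)) next
    res[[i]] <- tibble(contig_id = cand$id[hits$window_row[i]],
                       read_id = reads$read_id[hits$read_idx[i]],
                       window_start = sc$window_start, window_end = sc$window_end,
                       identity = sc$identity, gapped = FALSE)
  }
  aln <- bind_rows(compact(res))
  if (nrow(aln) == 0L) return(tibble(contig_id = character(0), read_id = character(0)))
  aln$spans <- read_spans_junction(aln, th)
  distinct(aln[aln$spans, c("contig_id", "read_id")])
}
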