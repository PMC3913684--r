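# Paired-end pipeline: (1) contigs assembled from MDA-amplified circles carry
# an identical terminal duplication -- find and trim it; (2) confirm the
# junction with read pairs whose mates map near opposite ends of the trimmed
# contig in junction-spanning orientation.

#' Find the terminal duplication of a contig
#'
#' Searches for the largest `k` with
#' `min_terminal_overlap <= k <= floor(max_terminal_overlap_frac * L)` such
#' that the first `k` bases are character-identical to the last `k` bases.
#' The match is exact: a misassembly of even a few nucleotides inside the
#' duplicated copy makes the test fail, trading false negatives for zero
#' false positives.
#'
#' @param seq A single contig sequence.
#' @param th A [thresholds()] object.
#' @return The overlap length `k` (integer), or `NA` if no qualifying overlap
#'   exists (including contigs shorter than `2 * min_terminal_overlap`, which
#'   are skipped, not an error).
#' @examples
#' find_terminal_overlap("ATGCCGTTAAGCATGCC", thresholds(min_terminal_overlap = 4))  # 5
#' @export
find_terminal_overlap <- function(seq, th = thresholds()) {
  assert_dna(seq)
  stopifnot(length(seq) == 1L)
  seq <- str_to_upper(seq)
  L <- str_length(seq)
  if (L < 2L * th$min_terminal_overlap) return(NA_integer_)
  kmax <- min(as.integer(floor(th$max_terminal_overlap_frac * L)), L - 1L)
  if (kmax < th$min_terminal_overlap) return(NA_integer_)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ks <- th$min_terminal_overlap:kmax
  # cheap prefilter: first/last characters of prefix and suffix must agree
  cand <- ks[ch[L - ks + 1L] == ch[1L] & ch[ks] == ch[L]]
  for (k in rev(cand)) {
    if (substr(seq, 1L, k) == substr(seq, L - k + 1L, L)) return(as.integer(k))
  }
  NA_integer_
}

#' Remove a detected terminal duplication
#'
#' Drops the last `k` bases, leaving exactly one copy of the putative circle.
#'
#' @param seq A single contig sequence.
#' @param k Overlap length as returned by [find_terminal_overlap()]; `k = 0`
#'   returns the input unchanged.
#' @return The trimmed sequence.
#' @examples
#' trim_terminal_overlap("ATGCCGTTAAGCATGCC", 5)  # "ATGCCGTTAAGC"
#' @export
trim_terminal_overlap <- function(seq, k) {
  stopifnot(length(seq) == 1L)
  k <- as.integer(k)
  if (is.na(k) || k < 0L) abort("`k` must be a non-negative integer.")
  L <- str_length(seq)
  if (k >= L) abort("`k` must be smaller than the contig length.")
  if (k == 0L) return(seq)
  str_sub(seq, 1L, L - k)
}

# Validate/normalise a mate-alignment table. Coordinates are 0-based
# half-open on the contig; `strand` is "+"/"-"; `mate` is 1 or 2 within
# `pair_id`. Gapless contract: aligned_len = end - start.
as_mate_aln_tbl <- function(alignments) {
  if (!is.data.frame(alignments)) abort("`alignments` must be a data frame.")
  need <- setdiff(c("contig_id", "pair_id", "mate", "start", "end", "strand"),
                  names(alignments))
  if (length(need)) abort(paste0("`alignments` is missing column(s): ", paste(need, collapse = ", ")))
  out <- as_tibble(alignments)
  out$contig_id <- as.character(out$contig_id)
  out$pair_id <- as.character(out$pair_id)
  out$mate <- as.integer(out$mate)
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  if (!all(out$strand %in% c("+", "-"))) abort("`strand` must be '+' or '-'.")
  if (any(out$start < 0L) || any(out$end <= out$start)) {
    abort("alignment coordinates must satisfy 0 <= start < end (0-based half-open).")
  }
  if (!"aligned_len" %in% names(out)) out$aligned_len <- out$end - out$start
  out$aligned_len <- as.integer(out$aligned_len)
  out
}

#' Does a read pair support the start/end junction?
#'
#' A pair supports circularity of a trimmed contig of length `L` when one
#' mate lies entirely within the last `pe_end_window` bases on the `+`
#' strand, the other entirely within the first `pe_end_window` bases on the
#' `-` strand, and both mates align over at least `pe_min_mate_aln` nt. This
#' is the orientation a forward--reverse library produces when the sequenced
#' fragment wraps the linearization origin.
#'
#' @param trimmed_len Length `L` of the trimmed contig.
#' @param a,b One-row data frames (or named lists) with fields `contig_id`,
#'   `start`, `end`, `strand`, `aligned_len` -- the two mates of one pair.
#' @param th A [thresholds()] object.
#' @return `TRUE` or `FALSE`.
#' @examples
#' th <- thresholds()
#' a <- list(contig_id = "c", start = 2600, end = 2700, strand = "+", aligned_len = 100)
#' b <- list(contig_id = "c", start = 100, end = 190, strand = "-", aligned_len = 90)
#' pair_supports_junction(3000, a, b, th)  # TRUE
#' @export
pair_supports_junction <- function(trimmed_len, a, b, th = thresholds()) {
  a <- as.list(a); b <- as.list(b)
  if (!identical(as.character(a$contig_id), as.character(b$contig_id))) {
    abort("mates aligned to different contigs.")
  }
  L <- as.integer(trimmed_len)
  w <- th$pe_end_window
  m <- th$pe_min_mate_aln
  near_end_plus <- function(x) {
    x$strand == "+" && x$start >= max(L - w, 0L) && x$end <= L && x$aligned_len >= m
  }
  near_start_minus <- function(x) {
    x$strand == "-" && x$start >= 0L && x$end <= min(w, L) && x$aligned_len >= m
  }
  (near_end_plus(a) && near_start_minus(b)) || (near_end_plus(b) && near_start_minus(a))
}

# Vectorised pair support over an alignment table for one contig.
# Returns the pair ids with junction-spanning evidence.
supporting_pair_ids <- function(trimmed_len, aln, th) {
  L <- as.integer(trimmed_len)
  w <- th$pe_end_window
  m <- th$pe_min_mate_aln
  ok_plus <- aln$strand == "+" & aln$start >= max(L - w, 0L) & aln$end <= L &
    aln$aligned_len >= m
  ok_minus <- aln$strand == "-" & aln$end <= min(w, L) & aln$aligned_len >= m
  keepers <- aln[ok_plus | ok_minus, , drop = FALSE]
  if (nrow(keepers) == 0L) return(character(0))
  flag <- tibble(pair_id = keepers$pair_id, mate = keepers$mate,
                 plus = ok_plus[ok_plus | ok_minus],
                 minus = ok_minus[ok_plus | ok_minus])
  res <- flag |>
    group_by(.data$pair_id) |>
    summarise(pass = any(.data$plus) && any(.data$minus) &&
                dplyr::n_distinct(.data$mate[.data$plus | .data$minus]) >= 2L,
              .groups = "drop")
  sort(res$pair_id[res$pass])
}

#' Paired-end circularity detection
#'
#' Runs the two-step paired-end pipeline over a contig set: length filter
#' (`min_contig_len_pe`), terminal-overlap detection and trimming
#' ([find_terminal_overlap()]), and junction confirmation by read pairs
#' mapping to opposite ends of the trimmed contig. Evidence alignments can be
#' supplied directly (e.g. from [read_sam_alignments()]; coordinates must
#' refer to the *trimmed* contigs) or computed by the built-in exact-seed
#' gapless mapper from raw paired reads, in which case reads are mapped to
#' the trimmed candidates internally.
#'
#' @param contigs Contig table (see [as_contig_tbl()]).
#' @param reads Optional paired-read table with columns `pair_id`, `mate`
#'   (1/2), `seq`, as produced by [simulate_pe_reads()].
#' @param alignments Optional mate-alignment table (columns `contig_id`,
#'   `pair_id`, `mate`, `start`, `end`, `strand`, `aligned_len`); used
#'   instead of `reads` when given.
#' @param th A [thresholds()] object.
#' @param seed_len,max_mismatch Passed to [internal_map_pe()] when mapping
#'   `reads`.
#' @return A tibble of confirmed circular elements (class `circ_detection`)
#'   with columns `id`, `seq` (trimmed, one copy of the circle), `length`,
#'   `source_platform`, `overlap_trimmed`, `n_supporting_pairs`,
#'   `n_spanning_reads`, `supporting_ids` (list), `canonical_seq`. Per-stage
#'   funnel counts are in `attr(, "funnel")` (also via [glance()]); skipped
#'   contigs and reasons in `attr(, "skipped")`.
#' @examples
#' sim <- simulate_metamobilome(sim_config(n_circles = 2, n_linear = 1,
#'   length_range = c(1200, 2000), seed = 1))
#' det <- detect_circular_pe(sim$contigs, reads = sim$pe_reads)
#' glance(det)
#' @export
detect_circular_pe <- function(contigs, reads = NULL, alignments = NULL,
                               th = thresholds(), seed_len = 31L,
                               max_mismatch = 2L) {
  contigs <- as_contig_tbl(contigs)
  n_input <- nrow(contigs)

  len_ok <- contigs$length >= th$min_contig_len_pe
  skipped <- tibble(id = contigs$id[!len_ok],
                    reason = sprintf("length %d < min_contig_len_pe %d",
                                     contigs$length[!len_ok], th$min_contig_len_pe))
  cand <- contigs[len_ok, , drop = FALSE]

  cand$overlap_len <- map_int(cand$seq, function(s) {
    k <- find_terminal_overlap(s, th)
    if (is.na(k)) NA_integer_ else k
  })
  no_ovl <- is.na(cand$overlap_len)
  skipped <- bind_rows(skipped,
                       tibble(id = cand$id[no_ovl], reason = "no qualifying terminal overlap"))
  cand <- cand[!no_ovl, , drop = FALSE]
  cand$trimmed_seq <- map2_chr(cand$seq, cand$overlap_len, trim_terminal_overlap)
  cand$trimmed_len <- str_length(cand$trimmed_seq)

  if (nrow(cand) > 0L) {
    if (!is.null(alignments)) {
      aln <- as_mate_aln_tbl(alignments)
      unknown <- setdiff(unique(aln$contig_id), contigs$id)
      if (length(unknown)) {
        abort(paste0("alignments reference unknown contig id(s): ",
                     paste(head(unknown, 5), collapse = ", ")))
      }
      aln <- aln[aln$contig_id %in% cand$id, , drop = FALSE]
    } else if (!is.null(reads)) {
      trimmed <- tibble(id = cand$id, seq = cand$trimmed_seq)
      aln <- internal_map_pe(reads, trimmed, seed_len = seed_len,
                             max_mismatch = max_mismatch)
    } else {
      abort("supply either `reads` or `alignments` as junction evidence.")
    }
    by_contig <- split(aln, factor(aln$contig_id, levels = cand$id))
    cand$supporting_ids <- map2(cand$id, cand$trimmed_len, function(cid, L) {
      supporting_pair_ids(L, by_contig[[cid]], th)
    })
  } else {
    cand$supporting_ids <- list()
  }
  cand$n_supporting_pairs <- map_int(cand$supporting_ids, length)
  confirmed <- cand$n_supporting_pairs >= th$min_supporting_pairs
  skipped <- bind_rows(skipped,
                       tibble(id = cand$id[!confirmed],
                              reason = "no junction-spanning read pairs"))

  out <- cand[confirmed, , drop = FALSE]
  elements <- tibble(
    id = out$id,
    seq = out$trimmed_seq,
    length = out$trimmed_len,
    source_platform = "paired_end",
    overlap_trimmed = out$overlap_len,
    n_supporting_pairs = out$n_supporting_pairs,
    n_spanning_reads = 0L,
    supporting_ids = out$supporting_ids,
    coverage = out$coverage
  )
  elements$canonical_seq <- if (nrow(elements)) canonical_rotation(elements$seq) else character(0)
  funnel <- tibble(
    stage = c("input", "length_pass", "overlap_pass", "pe_confirmed"),
    count = c(n_input, sum(len_ok), nrow(cand), nrow(elements))
  )
  new_circ_detection(elements, funnel = funnel, platform = "paired_end",
                     skipped = skipped)
}

map2_chr <- function(x, y, f) vapply(seq_along(x), function(i) f(x[[i]], y[[i]]), character(1))

new_circ_detection <- function(elements, funnel, platform, skipped) {
  structure(elements,
            funnel = funnel,
            platform = platform,
            skipped = skipped,
            class = c("circ_detection", class(tibble())))
}
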