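# Built-in test-scale read placement. Not a general-purpose aligner: exact or
# near-exact gapless placement of uniform-length reads, unique-best only, in
# the same record shape as SAM ingest so the detection stages are agnostic to
# where alignments came from.

# Match a constant-width DNAStringSet of patterns against one subject string;
# returns tibble(pattern_idx, start, end) with 0-based half-open coords.
match_pdict_hits <- function(pdict, subject, max_mismatch = 0L) {
  m <- Biostrings::matchPDict(pdict, subject, max.mismatch = max_mismatch)
  nh <- S4Vectors::elementNROWS(m)
  if (sum(nh) == 0L) {
    return(tibble(pattern_idx = integer(0), start = integer(0), end = integer(0)))
  }
  r <- IRanges::ranges(unlist(m, use.names = FALSE))
  tibble(pattern_idx = rep.int(seq_along(nh), nh),
         start = BiocGenerics::start(r) - 1L,
         end = BiocGenerics::end(r))
}

#' Exact-seed gapless paired-end mapper
#'
#' Places uniform-length paired reads on a contig set. Pass one demands an
#' exact full-length gapless match; reads left unplaced are retried with up
#' to `max_mismatch` substitutions outside an exact seed of length
#' `seed_len` anchored at the read 5' end. Only reads with a *unique* best
#' placement (across all contigs and both strands) are reported; multi-mapping
#' reads are discarded.
#'
#' @param reads Tibble with columns `pair_id`, `mate` (1/2), `seq`; every
#'   `pair_id` must appear with both mates.
#' @param contigs Contig table (`id`, `seq`).
#' @param seed_len Exact-match seed length for the mismatch pass.
#' @param max_mismatch Substitutions tolerated outside the seed (0 disables
#'   the second pass).
#' @return Mate-alignment tibble: `contig_id`, `pair_id`, `mate`, `start`,
#'   `end` (0-based half-open), `strand`, `aligned_len`.
#' @export
internal_map_pe <- function(reads, contigs, seed_len = 31L, max_mismatch = 2L) {
  if (!is.data.frame(reads)) abort("`reads` must be a data frame.")
  need <- setdiff(c("pair_id", "mate", "seq"), names(reads))
  if (length(need)) abort(paste0("`reads` is missing column(s): ", paste(need, collapse = ", ")))
  reads <- as_tibble(reads)
  reads$pair_id <- as.character(reads$pair_id)
  reads$mate <- as.integer(reads$mate)
  chk <- reads |>
    group_by(.data$pair_id) |>
    summarise(ok = all(sort(.data$mate) == c(1L, 2L)), .groups = "drop")
  if (!all(chk$ok)) {
    abort(paste0("unpaired read ids (need mates 1 and 2): ",
                 paste(head(chk$pair_id[!chk$ok], 5), collapse = ", ")))
  }
  contigs <- as_contig_tbl(contigs[, intersect(names(contigs), c("id", "seq", "coverage", "platform"))])
  # one Aho-Corasick scan over all contigs: concatenate with N spacers wider
  # than any read so no tolerated alignment can bridge two contigs, then
  # drop placements that stray outside a contig (into a spacer)
  spacer <- max(str_length(reads$seq)) + 2L
  cat_subj <- Biostrings::DNAString(paste(contigs$seq, collapse = strrep("N", spacer)))
  offsets <- cumsum(c(0L, head(contigs$length, -1L) + spacer))

  hits_for <- function(seqs, mm, tb) {
    pd <- if (tb) {
      Biostrings::PDict(seqs, tb.start = 1L, tb.end = as.integer(seed_len))
    } else {
      Biostrings::PDict(seqs)
    }
    h <- match_pdict_hits(pd, cat_subj, max_mismatch = mm)
    if (nrow(h) == 0L) return(h)
    ci <- findInterval(h$start, offsets)
    h$contig_idx <- ci
    h$start <- h$start - offsets[ci]
    h$end <- h$end - offsets[ci]
    h[h$start >= 0L & h$end <= contigs$length[ci], , drop = FALSE]
  }

  place_pass <- function(idx, mm, tb) {
    if (length(idx) == 0L) return(tibble())
    seqs_f <- Biostrings::DNAStringSet(reads$seq[idx])
    seqs_r <- Biostrings::reverseComplement(seqs_f)
    hf <- hits_for(seqs_f, mm, tb)
    hr <- hits_for(seqs_r, mm, tb)
    if (nrow(hf)) hf$strand <- "+"
    if (nrow(hr)) hr$strand <- "-"
    h <- bind_rows(hf, hr)
    if (nrow(h) == 0L) return(tibble())
    h$read_row <- idx[h$pattern_idx]
    nh <- table(h$read_row)
    uniq <- as.integer(names(nh)[nh == 1L])
    h[h$read_row %in% uniq, , drop = FALSE]
  }

  widths <- str_length(reads$seq)
  placed <- list()
  for (w in unique(widths)) {
    if (w < seed_len && max_mismatch > 0L) {
      abort(sprintf("read length %d shorter than seed_len %d.", w, seed_len))
    }
    rows <- which(widths == w)
    p1 <- place_pass(rows, 0L, tb = FALSE)
    done <- if (nrow(p1)) unique(p1$read_row) else integer(0)
    p2 <- tibble()
    if (max_mismatch > 0L) {
      # reads with zero (not multiple) exact placements get a tolerant retry
      had_any <- integer(0)
      if (nrow(p1)) had_any <- done
      rest <- setdiff(rows, had_any)
      if (length(rest)) p2 <- place_pass(rest, as.integer(max_mismatch), tb = TRUE)
    }
    placed[[as.character(w)]] <- bind_rows(p1, p2)
  }
  h <- bind_rows(placed)
  if (nrow(h) == 0L) {
    return(tibble(contig_id = character(0), pair_id = character(0), mate = integer(0),
                  start = integer(0), end = integer(0), strand = character(0),
                  aligned_len = integer(0)))
  }
  tibble(
    contig_id = contigs$id[h$contig_idx],
    pair_id = reads$pair_id[h$read_row],
    mate = reads$mate[h$read_row],
    start = h$start,
    end = h$end,
    strand = h$strand,
    aligned_len = h$end - h$start
  ) |>
    arrange(.data$contig_id, .data$pair_id, .data$mate)
}

# Locate exact seed occurrences inside a set of reads. Seeds are a
# constant-width character vector; reads are searched on the given strings
# as-is (caller handles orientation by passing reverse-complemented reads).
# Reads are concatenated with N spacers so one Aho-Corasick scan covers all.
# Returns tibble(seed_idx, read_idx, read_pos) with read_pos 0-based.
match_seeds_in_reads <- function(seeds, read_seqs) {
  if (length(seeds) == 0L || length(read_seqs) == 0L) {
    return(tibble(seed_idx = integer(0), read_idx = integer(0), read_pos = integer(0)))
  }
  wl <- unique(str_length(seeds))
  if (length(wl) != 1L) abort("seeds must have constant width.")
  sep <- strrep("N", wl)
  cat_seq <- paste(read_seqs, collapse = sep)
  offsets <- cumsum(c(0L, head(str_length(read_seqs), -1L) + wl))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  h <- match_pdict_hits(pd, Biostrings::DNAString(cat_seq))
  if (nrow(h) == 0L) {
    return(tibble(seed_idx = integer(0), read_idx = integer(0), read_pos = integer(0)))
  }
  ri <- findInterval(h$start, offsets)
  tibble(seed_idx = h$pattern_idx,
         read_idx = ri,
         read_pos = h$start - offsets[ri])
}
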