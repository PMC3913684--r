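# In-silico support for inverse-PCR validation of circularity. Outward-facing
# primers located away from the linearization origin can only amplify across
# the origin if the template is truly circular, so one product of the
# predicted size simultaneously confirms existence and length of an element.
# Mispriming is screened on every contig doubled (seq+seq) to mimic
# circularity.

#' Propose outward-facing primer regions for an element
#'
#' Returns two candidate windows for primer placement, each at least
#' `junction_buffer` nt away from both the element start (position 0) and
#' end (position L), with the reverse window left of the forward window. The
#' forward primer points toward increasing coordinates (across the junction)
#' and the reverse primer toward decreasing coordinates. Actual oligo
#' selection (melting temperature, hairpins) is delegated to external primer
#' design software; these regions are what you hand it.
#'
#' @param element_seq The element's linearized sequence (or a one-row
#'   element table with a `seq` column).
#' @param primer_len Expected primer length (nt).
#' @param junction_buffer Minimum distance from the linearization origin
#'   (nt).
#' @return Tibble with one row per region: `region` ("rev"/"fwd"), `start`,
#'   `end` (0-based half-open), `strand`.
#' @export
propose_primer_regions <- function(element_seq, primer_len = 20L,
                                   junction_buffer = 150L) {
  if (is.data.frame(element_seq)) element_seq <- element_seq$seq[[1L]]
  assert_dna(element_seq, "element_seq")
  L <- str_length(element_seq)
  primer_len <- as.integer(primer_len)
  junction_buffer <- as.integer(junction_buffer)
  min_len <- 2L * (junction_buffer + primer_len) + 2L
  if (L < min_len) {
    abort(sprintf("element too short for primer regions: length %d < required %d (2*(buffer %d + primer %d) + 2).",
                  L, min_len, junction_buffer, primer_len))
  }
  mid <- L %/% 2L
  tibble(
    region = c("rev", "fwd"),
    start = c(junction_buffer, mid),
    end = c(mid, L - junction_buffer),
    strand = c("-", "+")
  )
}

#' Pick a concrete outward primer pair from an element
#'
#' Convenience for testing and screening: takes exact sequence 20-mers (or
#' `primer_len`-mers) at the outer edges of the [propose_primer_regions()]
#' windows. The forward primer's 5' base sits at `L - junction_buffer -
#' primer_len`; the reverse primer's 5' base at `junction_buffer +
#' primer_len - 1` (reverse-complemented so it reads 5'->3').
#'
#' @inheritParams propose_primer_regions
#' @param element_id Id recorded on the pair.
#' @return One-row tibble: `element_id`, `fwd_seq`, `rev_seq`, `fwd_5prime`,
#'   `rev_5prime`.
#' @export
design_outward_primers <- function(element_seq, element_id = "element",
                                   primer_len = 20L, junction_buffer = 150L) {
  if (is.data.frame(element_seq)) {
    if (missing(element_id) && "id" %in% names(element_seq)) element_id <- element_seq$id[[1L]]
    element_seq <- element_seq$seq[[1L]]
  }
  regions <- propose_primer_regions(element_seq, primer_len, junction_buffer)
  L <- str_length(element_seq)
  fwd_5 <- L - as.integer(junction_buffer) - as.integer(primer_len)
  rev_5 <- as.integer(junction_buffer) + as.integer(primer_len) - 1L
  tibble(
    element_id = element_id,
    fwd_seq = str_sub(element_seq, fwd_5 + 1L, fwd_5 + primer_len),
    rev_seq = dna_revcomp(str_sub(element_seq, rev_5 - primer_len + 2L, rev_5 + 1L)),
    fwd_5prime = fwd_5,
    rev_5prime = rev_5
  )
}

#' Predicted inverse-PCR product length
#'
#' On a circle of length `L` linearized at position 0, an outward pair with
#' forward 5' end at `fwd_5prime` and reverse 5' end at `rev_5prime`
#' (`rev_5prime < fwd_5prime`) amplifies positions `fwd_5prime .. L-1` plus
#' `0 .. rev_5prime` inclusive: length `(L - fwd_5prime) + rev_5prime + 1`.
#'
#' @param L Element length (nt).
#' @param fwd_5prime,rev_5prime 0-based 5'-end positions on the element.
#' @return Product length (nt).
#' @examples
#' predicted_inverse_product_len(100, 80, 30)  # 51
#' @export
predicted_inverse_product_len <- function(L, fwd_5prime, rev_5prime) {
  L <- as.integer(L); fwd_5prime <- as.integer(fwd_5prime); rev_5prime <- as.integer(rev_5prime)
  if (!(0L <= rev_5prime && rev_5prime < fwd_5prime && fwd_5prime < L)) {
    abort("need 0 <= rev_5prime < fwd_5prime < L.")
  }
  (L - fwd_5prime) + rev_5prime + 1L
}

# Bit-state semi-global DP: can the full primer align ending at template
# column j with at most (mm, ins, del) = (1,1,1)-capped edits? States are the
# 8 combinations of {mm used, ins used, del used} (caps generalise to any
# small integer by widening the state grid; here each cap c contributes c+1
# levels). Vectorised over template columns.
#
# Returns tibble(end, mm, ins, del) of feasible end columns (0-based,
# half-open end) with a minimal-total-edit composition for each.
primer_dp_ends <- function(primer_int, tmpl_int, max_mm, max_ins, max_del) {
  m <- length(primer_int)
  n <- length(tmpl_int)
  if (m == 0L || n == 0L || m > n) {
    return(tibble(end = integer(0), mm = integer(0), ins = integer(0), del = integer(0)))
  }
  mm_lv <- max_mm + 1L; ins_lv <- max_ins + 1L; del_lv <- max_del + 1L
  n_states <- mm_lv * ins_lv * del_lv
  state_id <- function(mm, ins, del) 1L + mm + mm_lv * (ins + ins_lv * del)
  # reach[[s]][j+1] : primer prefix consumed so far can end at template col j
  # (0-based, j template chars consumed) in state s. Row 0: free start.
  reach <- replicate(n_states, rep(FALSE, n + 1L), simplify = FALSE)
  reach[[state_id(0L, 0L, 0L)]][] <- TRUE
  shift1 <- function(v) c(FALSE, v[-length(v)])
  for (i in seq_len(m)) {
    eq <- c(FALSE, tmpl_int == primer_int[i])  # aligned at column j consumes tmpl[j]
    nxt <- replicate(n_states, rep(FALSE, n + 1L), simplify = FALSE)
    for (del in 0:(del_lv - 1L)) for (ins in 0:(ins_lv - 1L)) for (mm in 0:(mm_lv - 1L)) {
      s <- state_id(mm, ins, del)
      acc <- shift1(reach[[s]]) & eq
      if (mm > 0L) acc <- acc | shift1(reach[[state_id(mm - 1L, ins, del)]])
      if (del > 0L) acc <- acc | reach[[state_id(mm, ins, del - 1L)]]
      nxt[[s]] <- acc
    }
    # insertions (extra template base) within the new row, cheapest-first so
    # a single pass suffices under the cap
    for (del in 0:(del_lv - 1L)) for (ins in seq_len(ins_lv - 1L)) for (mm in 0:(mm_lv - 1L)) {
      s <- state_id(mm, ins, del)
      nxt[[s]] <- nxt[[s]] | shift1(nxt[[state_id(mm, ins - 1L, del)]])
    }
    reach <- nxt
  }
  res <- list()
  for (del in 0:(del_lv - 1L)) for (ins in 0:(ins_lv - 1L)) for (mm in 0:(mm_lv - 1L)) {
    s <- state_id(mm, ins, del)
    ends <- which(reach[[s]]) - 1L
    if (length(ends)) res[[length(res) + 1L]] <- tibble(end = ends, mm = mm, ins = ins, del = del)
  }
  if (!length(res)) {
    return(tibble(end = integer(0), mm = integer(0), ins = integer(0), del = integer(0)))
  }
  out <- bind_rows(res)
  out$total <- out$mm + out$ins + out$del
  out <- out[order(out$end, out$total, out$mm), , drop = FALSE]
  out <- out[!duplicated(out$end), , drop = FALSE]
  # A capped composition must be realised by a *minimum-edit* alignment:
  # otherwise one extra insertion+deletion pair could impersonate a second
  # mismatch and let a two-substitution site through.
  dmin <- edit_distance_ends(primer_int, tmpl_int)
  out <- out[out$total == dmin[out$end + 1L], , drop = FALSE]
  out$total <- NULL
  out
}

# Unconstrained semi-global unit-cost edit distance of the full primer
# ending at each template column j (0..n), free start. Vectorised rows with
# a cummin scan for the within-row insertion recurrence.
edit_distance_ends <- function(primer_int, tmpl_int) {
  m <- length(primer_int)
  n <- length(tmpl_int)
  prev <- rep(0L, n + 1L)
  jj <- 0L:n
  for (i in seq_len(m)) {
    sub_cost <- c(1L, (tmpl_int != primer_int[i]) + 0L)
    t_ <- pmin(c(prev[1L] + 1L, prev[-(n + 1L)] + sub_cost[-1L]),  # diag (match/mm)
               prev + 1L)                                          # del (skip primer)
    cur <- jj + cummin(t_ - jj)                                    # ins scan
    prev <- cur
  }
  prev
}

#' Find primer binding sites on a template with capped edits
#'
#' Reports every placement of the primer (on either strand) that aligns with
#' at most `vpcr_max_mismatch` mismatches AND `vpcr_max_insertion`
#' insertions AND `vpcr_max_deletion` deletions (each cap applied
#' simultaneously). Overlapping placements are collapsed to the
#' fewest-edit position.
#'
#' @param primer Primer sequence, 5'->3'.
#' @param template Template sequence.
#' @param th A [thresholds()] object (edit caps).
#' @return Tibble: `start`, `end` (0-based half-open template coords of the
#'   binding site), `strand` (`"+"`: primer as given matches the template
#'   forward strand and extends rightward; `"-"`: primer binds the forward
#'   strand's complement and extends leftward), `mm`, `ins`, `del`. For a
#'   `+` hit the primer 3' end is at `end - 1`; for a `-` hit at `start`.
#' @export
find_primer_bindings <- function(primer, template, th = thresholds()) {
  assert_dna(primer, "primer"); assert_dna(template, "template")
  primer <- str_to_upper(primer); template <- str_to_upper(template)
  if (str_length(template) == 0L) abort("`template` must be non-empty.")
  if (str_length(primer) > str_length(template)) {
    return(tibble(start = integer(0), end = integer(0), strand = character(0),
                  mm = integer(0), ins = integer(0), del = integer(0)))
  }
  tmpl_int <- utf8ToInt(template)
  one_strand <- function(p, strand) {
    p_int <- utf8ToInt(p)
    hits <- primer_dp_ends(p_int, tmpl_int, th$vpcr_max_mismatch,
                           th$vpcr_max_insertion, th$vpcr_max_deletion)
    if (nrow(hits) == 0L) return(hits[0, ])
    m <- length(p_int)
    hits$start <- hits$end - m - hits$ins + hits$del
    hits$strand <- strand
    hits
  }
  fwd <- one_strand(primer, "+")
  rev <- one_strand(dna_revcomp(primer), "-")
  hits <- bind_rows(fwd, rev)
  if (nrow(hits) == 0L) {
    return(tibble(start = integer(0), end = integer(0), strand = character(0),
                  mm = integer(0), ins = integer(0), del = integer(0)))
  }
  hits$total <- hits$mm + hits$ins + hits$del
  # collapse overlapping placements (same strand, starts closer than the
  # primer length) to the best-scoring one, fewest edits first
  m <- str_length(primer)
  hits <- hits[order(hits$total, hits$start), , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    clash <- keep & hits$strand == hits$strand[i] & abs(hits$start - hits$start[i]) < m
    if (!any(clash)) keep[i] <- TRUE
  }
  hits <- hits[keep, c("start", "end", "strand", "mm", "ins", "del")]
  as_tibble(hits[order(hits$strand, hits$start), ])
}

#' Virtual-PCR mispriming screen on doubled templates
#'
#' Screens an outward primer pair against a contig collection: every contig
#' longer than `vpcr_min_template_len - 1` nt is loaded twice (`seq + seq`)
#' to mimic circularity, both primers are located with capped-edit binding
#' ([find_primer_bindings()]), and an amplicon is recorded for every
#' convergent forward/reverse binding pair with product length at most the
#' contig's original length. The screen passes when exactly one amplicon
#' exists, it lies on the pair's own element, and its length equals
#' [predicted_inverse_product_len()].
#'
#' @param pair One-row primer-pair table (`element_id`, `fwd_seq`,
#'   `rev_seq`, `fwd_5prime`, `rev_5prime`), e.g. from
#'   [design_outward_primers()].
#' @param contigs Contig table to use as the mispriming database; the
#'   pair's own element must be among them for the screen to pass.
#' @param th A [thresholds()] object.
#' @return A list with `pass` (flag), `amplicons` (tibble: `template_id`,
#'   `product_len`, `fwd_pos`, `rev_pos`, `fwd_edits`, `rev_edits`), and
#'   `predicted_len`.
#' @export
virtual_pcr_screen <- function(pair, contigs, th = thresholds()) {
  pair <- as_tibble(pair)
  need <- setdiff(c("element_id", "fwd_seq", "rev_seq", "fwd_5prime", "rev_5prime"),
                  names(pair))
  if (length(need)) abort(paste0("`pair` is missing column(s): ", paste(need, collapse = ", ")))
  if (nrow(pair) != 1L) abort("`pair` must have exactly one row.")
  contigs <- as_contig_tbl(contigs[, intersect(names(contigs), c("id", "seq", "coverage", "platform"))])
  db <- contigs[contigs$length >= th$vpcr_min_template_len, , drop = FALSE]

  amps <- list()
  for (i in seq_len(nrow(db))) {
    L <- db$length[i]
    doubled <- paste0(db$seq[i], db$seq[i])
    fwd_hits <- find_primer_bindings(pair$fwd_seq, doubled, th)
    fwd_hits <- fwd_hits[fwd_hits$strand == "+", , drop = FALSE]
    rev_hits <- find_primer_bindings(pair$rev_seq, doubled, th)
    rev_hits <- rev_hits[rev_hits$strand == "-", , drop = FALSE]
    if (nrow(fwd_hits) == 0L || nrow(rev_hits) == 0L) next
    min_prod <- str_length(pair$fwd_seq) + str_length(pair$rev_seq)
    for (f in seq_len(nrow(fwd_hits))) for (r in seq_len(nrow(rev_hits))) {
      p <- fwd_hits$start[f]           # fwd 5' position on doubled template
      q <- rev_hits$end[r] - 1L        # rev 5' position (rightmost base)
      prod <- q - p + 1L
      if (prod < min_prod || prod > L) next
      amps[[length(amps) + 1L]] <- tibble(
        template_id = db$id[i],
        product_len = prod,
        fwd_pos = p %% L,
        rev_pos = q %% L,
        fwd_edits = sprintf("%d,%d,%d", fwd_hits$mm[f], fwd_hits$ins[f], fwd_hits$del[f]),
        rev_edits = sprintf("%d,%d,%d", rev_hits$mm[r], rev_hits$ins[r], rev_hits$del[r])
      )
    }
  }
  amplicons <- if (length(amps)) {
    distinct(bind_rows(amps), .data$template_id, .data$product_len,
             .data$fwd_pos, .data$rev_pos, .keep_all = TRUE)
  } else {
    tibble(template_id = character(0), product_len = integer(0),
           fwd_pos = integer(0), rev_pos = integer(0),
           fwd_edits = character(0), rev_edits = character(0))
  }
  own <- pair$element_id
  own_len <- db$length[match(own, db$id)]
  predicted <- if (!is.na(own_len)) {
    predicted_inverse_product_len(own_len, pair$fwd_5prime, pair$rev_5prime)
  } else NA_integer_
  pass <- nrow(amplicons) == 1L &&
    identical(amplicons$template_id[1L], own) &&
    !is.na(predicted) &&
    amplicons$product_len[1L] == predicted
  list(pass = pass, amplicons = amplicons, predicted_len = predicted)
}
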