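# DNA string helpers shared by all stages. Alphabet is {A,C,G,T,N}; N
# complements to N and participates in rotation ordering as the literal
# character. Coordinates are 0-based half-open internally; conversion to
# 1-based happens only when writing reports.

assert_dna <- function(seq, arg = "seq") {
  if (!is.character(seq)) abort(sprintf("`%s` must be a character vector.", arg))
  if (any(is.na(seq))) abort(sprintf("`%s` contains NA.", arg))
  bad <- str_detect(seq, "[^ACGTNacgtn]")
  if (any(bad)) {
    abort(sprintf("`%s` contains non-DNA characters (allowed: A,C,G,T,N); first offender: '%s'.",
                  arg, seq[which(bad)[1]]))
  }
  invisible(TRUE)
}

#' Reverse complement of DNA strings
#'
#' Vectorised Watson--Crick reverse complement over the alphabet
#' \{A,C,G,T,N\}; `N` maps to `N`.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of the same length.
#' @examples
#' dna_revcomp("AAGC")  # "GCTT"
#' dna_revcomp(c("ACGT", "TAAC"))
#' @export
dna_revcomp <- function(seq) {
  assert_dna(seq)
  if (length(seq) == 0L) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(str_to_upper(seq)))))
}

#' Rotate a sequence left by k positions
#'
#' `rotate_seq(s, k)` moves the first `k` characters to the end, i.e. the
#' circle is re-linearized at origin `k` (0-based).
#'
#' @param seq A single DNA string.
#' @param k Non-negative rotation offset; taken modulo `nchar(seq)`.
#' @return The rotated string.
#' @examples
#' rotate_seq("ACGTT", 2)  # "GTTAC"
#' @export
rotate_seq <- function(seq, k) {
  stopifnot(length(seq) == 1L, !is.na(seq))
  n <- str_length(seq)
  if (n == 0L) abort("cannot rotate an empty sequence.")
  k <- as.integer(k %% n)
  if (k == 0L) return(seq)
  paste0(str_sub(seq, k + 1L, n), str_sub(seq, 1L, k))
}

# 0-based start of the lexicographically least rotation (two-pointer duel
# algorithm, O(n) over the doubled integer sequence).
least_rotation_offset <- function(seq) {
  x <- utf8ToInt(seq)
  n <- length(x)
  if (n <= 1L) return(0L)
  s <- c(x, x)
  i <- 0L; j <- 1L; k <- 0L
  while (i < n && j < n && k < n) {
    a <- s[i + k + 1L]
    b <- s[j + k + 1L]
    if (a == b) {
      k <- k + 1L
    } else if (a > b) {
      i <- i + k + 1L
      if (i == j) i <- i + 1L
      k <- 0L
    } else {
      j <- j + k + 1L
      if (j == i) j <- j + 1L
      k <- 0L
    }
  }
  min(i, j)
}

#' Canonical rotation of a circular sequence
#'
#' Returns the lexicographically smallest string among all rotations of `seq`
#' and all rotations of its reverse complement. Two linearizations of the
#' same circle -- any origin, either strand -- always map to the same
#' canonical string, which makes it a rotation/strand-invariant identifier
#' used for deduplication.
#'
#' @param seq Character vector of non-empty DNA strings.
#' @return Character vector of canonical strings.
#' @examples
#' canonical_rotation("TAAC")                      # "AACT"
#' canonical_rotation("ACGTT") == canonical_rotation("TTACG")
#' @export
canonical_rotation <- function(seq) {
  assert_dna(seq)
  if (any(str_length(seq) == 0L)) abort("`seq` contains an empty string.")
  seq <- str_to_upper(seq)
  rc <- dna_revcomp(seq)
  map2_chr_ <- function(a, b) {
    vapply(seq_along(a), function(i) {
      fwd <- rotate_seq(a[i], least_rotation_offset(a[i]))
      rev <- rotate_seq(b[i], least_rotation_offset(b[i]))
      if (fwd <= rev) fwd else rev
    }, character(1))
  }
  map2_chr_(seq, rc)
}

# Random DNA of given length/GC, using the current RNG state.
random_dna <- function(n, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
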