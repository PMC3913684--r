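# File-format frontends. Sequence formats go through Biostrings, SAM ingest
# through Rsamtools, GFF3 through rtracklayer; tables are written with readr.
# Coordinates are converted to the internal 0-based half-open convention on
# ingest and back to 1-based only inside the writers.

#' Read a FASTA file into a contig table
#'
#' @param path FASTA file.
#' @return Tibble: `id` (first whitespace-delimited token of the header),
#'   `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L),
         seq = unname(as.character(x)))
}

#' Write sequences to FASTA
#'
#' @param tbl Data frame with `id` and `seq`.
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(tbl, path, width = 70L) {
  x <- Biostrings::DNAStringSet(setNames(tbl$seq, tbl$id))
  Biostrings::writeXStringSet(x, path, width = as.integer(width))
  invisible(path)
}

#' Read single-end FASTQ into a read table
#'
#' @param path FASTQ file.
#' @return Tibble: `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L),
         seq = unname(as.character(x)))
}

#' Write reads to FASTQ (constant quality)
#'
#' Paired reads (columns `pair_id`, `mate`) get `/1` and `/2` id suffixes;
#' single-end reads use `read_id` as-is.
#'
#' @param reads Read table.
#' @param path Output file.
#' @param qual Single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual = "I") {
  if (all(c("pair_id", "mate") %in% names(reads))) {
    ids <- sprintf("%s/%d", reads$pair_id, reads$mate)
  } else {
    ids <- reads$read_id
  }
  x <- Biostrings::DNAStringSet(setNames(reads$seq, ids))
  q <- Biostrings::BStringSet(strrep(qual, str_length(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

cigar_single_match_len <- function(cigar) {
  m <- regmatches(cigar, regexec("^([0-9]+)M$", cigar))
  vapply(m, function(g) if (length(g) == 2L) as.integer(g[2]) else NA_integer_, integer(1))
}

#' Read mate alignments from a SAM file
#'
#' Ingests a SAM file (mandatory fields; converted via Rsamtools) into the
#' mate-alignment shape used by [detect_circular_pe()]. Only primary,
#' mapped records whose CIGAR is a single match-run (`<n>M`) are kept --
#' the gapless, unique-best contract under which junction evidence is
#' counted. Strand comes from FLAG 0x10, mate from 0x40/0x80; coordinates
#' are converted to 0-based half-open.
#'
#' @param path SAM file (with `@SQ` header lines).
#' @return Tibble: `contig_id`, `pair_id`, `mate`, `start`, `end`, `strand`,
#'   `aligned_len`.
#' @export
read_sam_alignments <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos", "cigar"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(b$pos) & !bitwAnd(b$flag, 0x4) & !bitwAnd(b$flag, 0x100) &
    !bitwAnd(b$flag, 0x800)
  mlen <- cigar_single_match_len(b$cigar)
  keep <- keep & !is.na(mlen)
  mate <- ifelse(bitwAnd(b$flag, 0x40) > 0L, 1L,
                 ifelse(bitwAnd(b$flag, 0x80) > 0L, 2L, 1L))
  tibble(
    contig_id = as.character(b$rname)[keep],
    pair_id = b$qname[keep],
    mate = mate[keep],
    start = b$pos[keep] - 1L,
    end = b$pos[keep] - 1L + mlen[keep],
    strand = ifelse(bitwAnd(b$flag[keep], 0x10) > 0L, "-", "+"),
    aligned_len = mlen[keep]
  )
}

#' Write mate alignments as SAM
#'
#' Emits a minimal valid SAM file (header `@SQ` lines from `contigs`,
#' mandatory fields, `<n>M` CIGAR, `*` sequence) for interoperability with
#' external tools and for round-trip testing of the ingest path.
#'
#' @param alignments Mate-alignment table.
#' @param contigs Contig table providing reference names/lengths.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, contigs, path) {
  aln <- as_mate_aln_tbl(alignments)
  contigs <- as_contig_tbl(contigs[, intersect(names(contigs), c("id", "seq", "coverage", "platform"))])
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", contigs$id, contigs$length), con)
  flag <- 0x1 + 0x2 +
    ifelse(aln$strand == "-", 0x10, 0L) +
    ifelse(aln$mate == 1L, 0x40, 0x80)
  writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                     aln$pair_id, flag, aln$contig_id, aln$start + 1L,
                     aln$aligned_len), con)
  invisible(path)
}

#' Parse HMMER per-domain tabular output (domtblout)
#'
#' Reads the `--domtblout` format of a profile-HMM search into a domain-hit
#' table. By default assumes `hmmscan` orientation (target = Pfam family,
#' query = gene); use `orientation = "hmmsearch"` when genes were the
#' targets. The per-domain independent E-value and per-domain bit score are
#' used.
#'
#' @param path domtblout file.
#' @param orientation `"hmmscan"` or `"hmmsearch"`.
#' @return Tibble: `gene_id`, `pfam_accession`, `family_name`, `e_value`,
#'   `bit_score`.
#' @export
read_domtblout <- function(path, orientation = c("hmmscan", "hmmsearch")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(gene_id = character(0), pfam_accession = character(0),
                  family_name = character(0), e_value = numeric(0),
                  bit_score = numeric(0)))
  }
  f <- strsplit(trimws(lines), "[ \t]+")
  bad <- vapply(f, length, integer(1)) < 14L
  if (any(bad)) abort(sprintf("malformed domtblout line %d.", which(bad)[1]))
  g <- function(i) vapply(f, `[`, character(1), i)
  if (orientation == "hmmscan") {
    tn <- g(1); ta <- g(2); qn <- g(4); qa <- g(5)
    fam <- tn; acc <- ta; gene <- qn
  } else {
    fam <- g(4); acc <- g(5); gene <- g(1)
  }
  tibble(
    gene_id = gene,
    pfam_accession = acc,
    family_name = fam,
    e_value = as.numeric(g(13)),   # i-Evalue (independent, this domain)
    bit_score = as.numeric(g(14))
  )
}

#' Read gene calls from GFF3 (+ optional protein FASTA)
#'
#' Parses the gene caller's GFF3 (CDS features) into a gene-call table. The
#' `partial` flag is read from the attribute field: a Prodigal-style
#' `partial` attribute of `"00"` means complete; any other value, or a
#' truncated-edge flag, marks the gene partial. Protein sequences, if a
#' FASTA is given, are matched by the gene `ID`.
#'
#' @param gff_path GFF3 file.
#' @param protein_path Optional protein FASTA whose record ids equal gene
#'   ids.
#' @return Tibble: `gene_id`, `element_id`, `start`, `end` (0-based
#'   half-open), `strand`, `partial`, `protein`.
#' @export
read_gene_calls <- function(gff_path, protein_path = NULL) {
  gr <- rtracklayer::import(gff_path)
  gr <- gr[gr$type %in% c("CDS", "gene")]
  md <- S4Vectors::mcols(gr)
  gene_id <- if ("ID" %in% names(md)) as.character(md$ID) else
    sprintf("gene_%05d", seq_along(gr))
  partial <- if ("partial" %in% names(md)) {
    as.character(md$partial) != "00"
  } else {
    rep(FALSE, length(gr))
  }
  out <- tibble(
    gene_id = gene_id,
    element_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    partial = partial,
    protein = NA_character_
  )
  if (!is.null(protein_path)) {
    aa <- Biostrings::readAAStringSet(protein_path)
    ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
    out$protein <- unname(as.character(aa))[match(out$gene_id, ids)]
  }
  out
}

#' Write candidate primer regions as BED
#'
#' @param regions Region table from [propose_primer_regions()].
#' @param element_id Name used in the BED name column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, element_id, path) {
  df <- tibble(chrom = element_id, start = regions$start, end = regions$end,
               name = paste0(element_id, "_", regions$region), score = 0L,
               strand = regions$strand)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
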