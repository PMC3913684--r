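# Replicon-domain classification. Gene calling (e.g. Prodigal) and the
# profile-HMM search (e.g. hmmscan against Pfam) are external; this module's
# contract is on their standard tabular outputs: filter hits at an E-value
# cutoff, keep the best hit per complete gene, and tag elements whose best
# hits fall in a curated list of plasmid replication-initiation families.

#' Pfam families diagnostic of plasmid replication initiation
#'
#' The curated list of 14 replicon-domain families used to call a circular
#' element a putative plasmid. Accession matching ignores the Pfam version
#' suffix (`PF01446.12` and `PF01446.27` are the same family).
#'
#' @return Tibble with columns `accession` (versioned), `name`,
#'   `description`.
#' @export
replicon_families <- function() {
  tribble_ <- function(...) tibble::tribble(...)
  tribble_(
    ~accession,   ~name,        ~description,
    "PF01446.12", "Rep_1",      "Replication protein",
    "PF01719.12", "Rep_2",      "Plasmid replication protein",
    "PF01051.16", "Rep_3",      "Initiator Replication protein",
    "PF05732.6",  "RepL",       "Firmicute plasmid replication protein",
    "PF07042.6",  "TrfA",       "TrfA protein",
    "PF04796.7",  "RepA_C",     "Plasmid encoded RepA protein",
    "PF02486.14", "Rep_trans",  "Replication initiation factor",
    "PF01402.16", "RHH_1",      "Ribbon-helix-helix protein, copG family",
    "PF01815.11", "Rop",        "Rop protein",
    "PF03428.8",  "RP-C",       "Replication protein C N-terminal domain",
    "PF10134.4",  "RPA",        "Replication initiator protein A",
    "PF06970.6",  "RepA_N",     "Replication initiator protein A (RepA) N-terminus",
    "PF06504.6",  "RepC",       "Replication protein C (RepC)",
    "PF03090.12", "Replicase",  "Replication initiator protein"
  )
}

#' Default trait-to-Pfam mapping for plasmid/phage trait tagging
#'
#' Editable approximation of the accessory-trait families commonly looked
#' for on mobile elements (mobilisation, toxin/antitoxin, type-IV secretion,
#' capsid, phage integrase, transposase). These lists are a documented
#' starting point, not a community standard; supply your own table to
#' [classify_elements()] for serious use. A domain accession may map to at
#' most one trait.
#'
#' @return Tibble with columns `trait`, `accession`.
#' @export
default_trait_table <- function() {
  tibble::tribble(
    ~trait,            ~accession,
    "mob",             "PF03432",  # Relaxase/mobilisation nuclease
    "mob",             "PF01076",  # Mob_Pre, plasmid recombination enzyme
    "toxin",           "PF05016",  # ParE toxin
    "toxin",           "PF01850",  # PIN domain toxin
    "antitoxin",       "PF02604",  # PhdYeFM antitoxin
    "antitoxin",       "PF03693",  # YoeB/Txe antitoxin partner
    "t4ss",            "PF02534",  # TraG/TraD/VirD4 coupling protein
    "t4ss",            "PF03135",  # VirB4 component
    "capsid",          "PF05065",  # Phage capsid family
    "phage_integrase", "PF00589",  # Phage integrase (tyrosine recombinase)
    "transposase",     "PF01527",  # Transposase_8 (IS3/IS911 family)
    "transposase",     "PF00872"   # Transposase_mut (IS256 family)
  )
}

strip_pfam_version <- function(acc) sub("\\..*$", "", acc)

# Normalise a domain-hit table (gene_id, pfam_accession, family_name,
# e_value, bit_score).
as_domain_hit_tbl <- function(hits) {
  if (!is.data.frame(hits)) abort("`hits` must be a data frame.")
  need <- setdiff(c("gene_id", "pfam_accession", "e_value"), names(hits))
  if (length(need)) abort(paste0("`hits` is missing column(s): ", paste(need, collapse = ", ")))
  out <- as_tibble(hits)
  out$gene_id <- as.character(out$gene_id)
  out$pfam_accession <- as.character(out$pfam_accession)
  out$e_value <- as.numeric(out$e_value)
  if (any(is.na(out$e_value)) || any(out$e_value < 0)) abort("`e_value` must be >= 0.")
  if (!"bit_score" %in% names(out)) out$bit_score <- NA_real_
  if (!"family_name" %in% names(out)) out$family_name <- NA_character_
  out
}

#' Best domain hit of one gene
#'
#' Discards hits with E-value above `cutoff`; among survivors returns the
#' one with the smallest E-value (ties to the larger bit score, then the
#' lexicographically smallest accession).
#'
#' @param hits Domain-hit rows for a single gene (columns `gene_id`,
#'   `pfam_accession`, `e_value`; optionally `bit_score`, `family_name`).
#' @param cutoff E-value cutoff.
#' @return One-row tibble, or a zero-row tibble when nothing survives.
#' @examples
#' h <- data.frame(gene_id = "g", pfam_accession = c("PF01446.12", "PF01051.16"),
#'                 e_value = c(1e-10, 1e-6), bit_score = c(50, 30))
#' select_best_hit(h)$pfam_accession  # "PF01446.12"
#' @export
select_best_hit <- function(hits, cutoff = 1e-4) {
  hits <- as_domain_hit_tbl(hits)
  if (nrow(hits) && length(unique(hits$gene_id)) > 1L) {
    abort("`hits` mixes gene ids; use best_hits_per_gene() for tables.")
  }
  best_hits_per_gene(hits, cutoff)
}

#' Best hit per gene over a whole domain-hit table
#'
#' @inheritParams select_best_hit
#' @return Tibble with one row per gene that has a hit at or below `cutoff`.
#' @export
best_hits_per_gene <- function(hits, cutoff = 1e-4) {
  hits <- as_domain_hit_tbl(hits)
  hits <- hits[hits$e_value <= cutoff, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  score <- ifelse(is.na(hits$bit_score), -Inf, hits$bit_score)
  hits[order(hits$gene_id, hits$e_value, -score, hits$pfam_accession), ] |>
    group_by(.data$gene_id) |>
    slice(1L) |>
    ungroup()
}

# Normalise gene calls (gene_id, element_id, start, end, strand, partial).
as_gene_call_tbl <- function(gene_calls) {
  if (!is.data.frame(gene_calls)) abort("`gene_calls` must be a data frame.")
  need <- setdiff(c("gene_id", "element_id"), names(gene_calls))
  if (length(need)) abort(paste0("`gene_calls` is missing column(s): ", paste(need, collapse = ", ")))
  out <- as_tibble(gene_calls)
  out$gene_id <- as.character(out$gene_id)
  out$element_id <- as.character(out$element_id)
  if (anyDuplicated(out$gene_id)) abort("duplicate gene ids in `gene_calls`.")
  if (!"partial" %in% names(out)) out$partial <- FALSE
  out$partial <- as.logical(out$partial)
  out
}

#' Classify circular elements by replicon domains and traits
#'
#' For each element: takes its *complete* predicted genes (partial genes are
#' excluded from classification), keeps each gene's best domain hit at the
#' E-value cutoff, and reports whether any best hit falls in the replicon
#' family table (`has_replicon`), which replicon families (multiset), and
#' which accessory traits. An element with n replicon-carrying genes
#' contributes n to the per-family instance counts but 1 to the
#' replicon-positive element count, so total instances can exceed the number
#' of positive elements.
#'
#' @param elements Element table (column `id`; e.g. from
#'   [dedup_elements()]).
#' @param gene_calls Gene table (columns `gene_id`, `element_id`, optional
#'   `partial`). Every `element_id` must exist in `elements`.
#' @param hits Domain-hit table (columns `gene_id`, `pfam_accession`,
#'   `e_value`, optional `bit_score`, `family_name`).
#' @param replicon_table Replicon family table; defaults to
#'   [replicon_families()].
#' @param trait_table Trait mapping; defaults to [default_trait_table()].
#' @param th A [thresholds()] object (supplies `hmm_evalue_cutoff`).
#' @return Tibble (class `circ_annotation`) with one row per element:
#'   `id`, `n_genes`, `n_complete_genes`, `has_replicon`,
#'   `n_replicon_domains`, `replicon_families` (comma-joined), `traits`
#'   (comma-joined `trait:count`). Global summaries are attached:
#'   `attr(, "family_counts")` (per-family instance counts in the shape of a
#'   family/count table, zeros included) and `attr(, "summary")`
#'   (`n_elements`, `n_replicon_elements`, `n_replicon_instances`); also via
#'   [glance()].
#' @export
classify_elements <- function(elements, gene_calls, hits,
                              replicon_table = replicon_families(),
                              trait_table = default_trait_table(),
                              th = thresholds()) {
  if (!is.data.frame(elements)) abort("`elements` must be a data frame.")
  if (!"id" %in% names(elements)) abort("`elements` needs an `id` column.")
  el_ids <- as.character(elements$id)
  genes <- as_gene_call_tbl(gene_calls)
  dangling <- setdiff(unique(genes$element_id), el_ids)
  if (length(dangling)) {
    abort(paste0("gene calls reference unknown element id(s): ",
                 paste(head(dangling, 5), collapse = ", ")))
  }
  if (anyDuplicated(trait_table$accession)) {
    abort("a domain accession may map to at most one trait.")
  }
  complete <- genes[!genes$partial, , drop = FALSE]
  best <- best_hits_per_gene(hits, cutoff = th$hmm_evalue_cutoff)
  best <- best[best$gene_id %in% complete$gene_id, , drop = FALSE]
  best$acc_base <- strip_pfam_version(best$pfam_accession)

  rep_tbl <- as_tibble(replicon_table)
  rep_tbl$acc_base <- strip_pfam_version(rep_tbl$accession)
  trait_tbl <- as_tibble(trait_table)
  trait_tbl$acc_base <- strip_pfam_version(trait_tbl$accession)

  best <- left_join(best, complete[, c("gene_id", "element_id")], by = "gene_id")
  best$replicon_name <- rep_tbl$name[match(best$acc_base, rep_tbl$acc_base)]
  best$trait <- trait_tbl$trait[match(best$acc_base, trait_tbl$acc_base)]

  per_el <- function(eid) {
    g_all <- genes$element_id == eid
    g_cmp <- complete$element_id == eid
    b <- best[best$element_id == eid, , drop = FALSE]
    repb <- b[!is.na(b$replicon_name), , drop = FALSE]
    trb <- b[!is.na(b$trait), , drop = FALSE]
    traits <- if (nrow(trb)) {
      tc <- sort(table(trb$trait))
      paste(sprintf("%s:%d", names(tc), as.integer(tc)), collapse = ",")
    } else ""
    tibble(
      id = eid,
      n_genes = sum(g_all),
      n_complete_genes = sum(g_cmp),
      has_replicon = nrow(repb) > 0L,
      n_replicon_domains = nrow(repb),
      replicon_families = paste(sort(repb$replicon_name), collapse = ","),
      traits = traits
    )
  }
  ann <- map_dfr(el_ids, per_el)

  fam_counts <- rep_tbl[, c("accession", "name")]
  inst <- table(best$replicon_name[!is.na(best$replicon_name)])
  fam_counts$count <- as.integer(ifelse(is.na(match(fam_counts$name, names(inst))),
                                        0L, inst[fam_counts$name]))
  summary_tbl <- tibble(
    n_elements = length(el_ids),
    n_replicon_elements = sum(ann$has_replicon),
    n_replicon_instances = sum(ann$n_replicon_domains)
  )
  structure(ann,
            family_counts = fam_counts,
            summary = summary_tbl,
            class = c("circ_annotation", class(tibble())))
}
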