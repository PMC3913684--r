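# Cross-pipeline deduplication. The same circle found twice -- by both
# pipelines, or in two assemblies -- is linearized at arbitrary origins and
# strands, so equality is decided on the canonical minimal rotation.

#' Cluster circular elements into duplicate groups
#'
#' `exact` mode groups elements whose [canonical_rotation()] strings are
#' identical. `near` mode additionally merges cluster pairs whose sequences
#' differ by at most `2` nt in length and whose rotation-aligned global
#' identity is at least `near_identity` percent (one sequence aligned against
#' the doubled other, so the anchor rotation is found automatically). Near
#' mode exists because a single indel -- e.g. one extra base in a
#' homopolymer from a sequencing error -- can otherwise split one real
#' element into two; it is off by default to keep behaviour auditable.
#'
#' @param elements Element table with at least `id` and `seq`;
#'   `canonical_seq` is computed if absent. Typically a
#'   [detect_circular_pe()] / [detect_circular_se()] result or a row-bound
#'   combination of both.
#' @param mode `"exact"` (default) or `"near"`.
#' @param near_identity Percent identity threshold for near mode.
#' @return The element table with added columns `cluster_id` (stable: the
#'   rank of the cluster's smallest canonical string), `cluster_size`.
#' @examples
#' els <- tibble::tibble(id = c("a", "b", "c"),
#'   seq = c("ACGTTACGGA", rotate_seq(dna_revcomp("ACGTTACGGA"), 3), "ACCGTGTTAA"))
#' cluster_elements(els)$cluster_id
#' @export
cluster_elements <- function(elements, mode = c("exact", "near"),
                             near_identity = 99.5) {
  mode <- match.arg(mode)
  if (!is.data.frame(elements)) abort("`elements` must be a data frame.")
  need <- setdiff(c("id", "seq"), names(elements))
  if (length(need)) abort(paste0("`elements` is missing column(s): ", paste(need, collapse = ", ")))
  out <- as_tibble(elements)
  out$id <- as.character(out$id)
  if (anyDuplicated(out$id)) abort("duplicate element ids.")
  if (!"canonical_seq" %in% names(out)) out$canonical_seq <- canonical_rotation(out$seq)
  if (nrow(out) == 0L) {
    out$cluster_id <- character(0); out$cluster_size <- integer(0)
    return(out)
  }

  # exact grouping by canonical string
  grp <- match(out$canonical_seq, sort(unique(out$canonical_seq)))

  if (mode == "near") {
    reps <- tibble(g = seq_along(sort(unique(out$canonical_seq))),
                   seq = sort(unique(out$canonical_seq)))
    reps$len <- str_length(reps$seq)
    parent <- seq_len(nrow(reps))
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (nrow(reps) > 1L) {
      for (i in seq_len(nrow(reps) - 1L)) {
        for (j in (i + 1L):nrow(reps)) {
          if (abs(reps$len[i] - reps$len[j]) > 2L) next
          if (rotation_identity(reps$seq[i], reps$seq[j]) >= near_identity) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
          }
        }
      }
    }
    root <- vapply(seq_len(nrow(reps)), find, integer(1))
    grp <- root[grp]
  }

  # stable labels: order clusters by their smallest canonical string
  key <- vapply(split(out$canonical_seq, grp), min, character(1))
  lab <- rank(key, ties.method = "first")
  width <- max(3L, nchar(length(key)))
  cluster_of <- setNames(sprintf("CL%0*d", width, lab), names(key))
  out$cluster_id <- cluster_of[as.character(grp)]
  out <- out |>
    group_by(.data$cluster_id) |>
    mutate(cluster_size = n()) |>
    ungroup()
  out
}

# Rotation-aligned global identity between two circular sequences:
# align s1 globally against doubled s2 (free ends on the subject), identity
# = matched positions / length of the longer sequence * 100.
rotation_identity <- function(s1, s2) {
  if (identical(s1, s2)) return(100)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s1),
    Biostrings::DNAString(paste0(s2, s2)),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1),
    gapOpening = 2, gapExtension = 1
  )
  100 * Biostrings::nmatch(pa) / max(str_length(s1), str_length(s2))
}

#' Choose the representative of a duplicate cluster
#'
#' Deterministic per policy: `prefer_single_end` keeps a single-end-derived
#' member when one exists (the choice made when the long-read copy of a
#' twice-found element is retained and the short-read copy dropped),
#' `prefer_paired_end` the reverse, `longest` the longest member. All ties
#' break to the lexicographically smallest id.
#'
#' @param cluster A data frame of one cluster's members (columns `id`,
#'   `length`, `source_platform`; `length` computed from `seq` if absent).
#' @param policy Selection policy.
#' @return The representative row (one-row tibble).
#' @export
select_representative <- function(cluster,
                                  policy = c("prefer_single_end",
                                             "prefer_paired_end", "longest")) {
  policy <- match.arg(policy)
  cluster <- as_tibble(cluster)
  if (nrow(cluster) == 0L) abort("empty cluster.")
  if (!"length" %in% names(cluster)) cluster$length <- str_length(cluster$seq)
  if (!"source_platform" %in% names(cluster)) cluster$source_platform <- "unknown"
  ord <- switch(policy,
    prefer_single_end = order(cluster$source_platform != "single_end", cluster$id),
    prefer_paired_end = order(cluster$source_platform != "paired_end", cluster$id),
    longest = order(-cluster$length, cluster$id)
  )
  cluster[ord[1L], , drop = FALSE]
}

#' Deduplicate circular elements across pipelines/datasets
#'
#' Clusters elements ([cluster_elements()]) and keeps one representative per
#' cluster ([select_representative()]). Representatives of clusters that
#' contain members from both platforms are tagged `source_platform = "both"`.
#'
#' @inheritParams cluster_elements
#' @inheritParams select_representative
#' @return Tibble of representatives (one row per cluster) with
#'   `cluster_id`, `cluster_size`; the full membership map is attached as
#'   `attr(, "members")` (columns `id`, `cluster_id`, `is_representative`).
#' @examples
#' pe <- tibble::tibble(id = "pe1", seq = "ACGGTTACCA", source_platform = "paired_end")
#' se <- tibble::tibble(id = "se1", seq = rotate_seq("ACGGTTACCA", 4),
#'                      source_platform = "single_end")
#' dedup_elements(rbind(pe, se))$id  # "se1"
#' @export
dedup_elements <- function(elements, mode = c("exact", "near"),
                           near_identity = 99.5,
                           policy = c("prefer_single_end", "prefer_paired_end",
                                      "longest")) {
  clustered <- cluster_elements(elements, mode = mode, near_identity = near_identity)
  policy <- match.arg(policy)
  reps <- clustered |>
    group_by(.data$cluster_id) |>
    dplyr::group_modify(function(df, key) {
      rep <- select_representative(df, policy = policy)
      if ("source_platform" %in% names(df) &&
          length(unique(df$source_platform)) > 1L) {
        rep$source_platform <- "both"
      }
      rep
    }) |>
    ungroup() |>
    arrange(.data$cluster_id)
  members <- clustered |>
    mutate(is_representative = .data$id %in% reps$id) |>
    select("id", "cluster_id", "is_representative")
  attr(reps, "members") <- members
  reps
}
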