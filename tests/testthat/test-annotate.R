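# Replicon-domain classification from gene calls and profile-HMM hits.

test_that("best-hit selection applies cutoff and tie rules", {
  h <- data.frame(gene_id = "g", pfam_accession = c("PF01446.12", "PF01051.16"),
                  e_value = c(1e-10, 1e-6), bit_score = c(50, 40))
  expect_equal(select_best_hit(h)$pfam_accession, "PF01446.12")
  h2 <- data.frame(gene_id = "g", pfam_accession = "PF01719.12", e_value = 2e-4)
  expect_equal(nrow(select_best_hit(h2)), 0L)
  expect_equal(nrow(select_best_hit(h[0, ])), 0L)
  # tie on E-value: larger bit score wins; then accession
  h3 <- data.frame(gene_id = "g",
                   pfam_accession = c("PF09999.1", "PF00001.1"),
                   e_value = c(1e-8, 1e-8), bit_score = c(60, 30))
  expect_equal(select_best_hit(h3)$pfam_accession, "PF09999.1")
  h4 <- data.frame(gene_id = "g",
                   pfam_accession = c("PF09999.1", "PF00001.1"),
                   e_value = 1e-8, bit_score = 30)
  expect_equal(select_best_hit(h4)$pfam_accession, "PF00001.1")
  mixed <- data.frame(gene_id = c("g1", "g2"), pfam_accession = "PF01446.12",
                      e_value = 1e-9)
  expect_error(select_best_hit(mixed), "mixes gene ids")
})

test_that("Pfam version suffixes do not affect classification", {
  els <- data.frame(id = c("E1", "E2"))
  genes <- data.frame(gene_id = c("g1", "g2"), element_id = c("E1", "E2"),
                      partial = FALSE)
  hits <- data.frame(gene_id = c("g1", "g2"),
                     pfam_accession = c("PF01446.12", "PF01446.27"),
                     e_value = 1e-9)
  ann <- classify_elements(els, genes, hits)
  expect_true(all(ann$has_replicon))
  expect_equal(attr(ann, "family_counts")$count[
    attr(ann, "family_counts")$name == "Rep_1"], 2L)
})

test_that("instances-vs-elements arithmetic and per-element annotation", {
  els <- data.frame(id = sprintf("E%02d", 1:10))
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:13),
    element_id = c("E01", "E01", "E02", "E02", "E03", "E03",
                   "E04", "E05", "E06", "E07", "E08", "E09", "E10"),
    partial = FALSE
  )
  hits <- data.frame(
    gene_id = sprintf("g%02d", 1:13),
    pfam_accession = c("PF01446.12", "PF01051.16", "PF01719.12", "PF05732.6",
                       "PF02486.14", "PF01402.16", "PF01446.12", "PF01051.16",
                       "PF01815.11", "PF03090.12", "PF01446.27", "PF01719.12",
                       "PF01051.16"),
    e_value = c(rep(1e-9, 12), 2e-4),  # last hit above the 1e-4 cutoff
    bit_score = 50
  )
  ann <- classify_elements(els, genes, hits)
  s <- attr(ann, "summary")
  expect_equal(s$n_replicon_elements, 9L)
  expect_equal(s$n_replicon_instances, 12L)
  expect_equal(sum(attr(ann, "family_counts")$count), 12L)
  expect_equal(ann$n_replicon_domains[ann$id == "E01"], 2L)
  expect_false(ann$has_replicon[ann$id == "E10"])
  expect_equal(ann$replicon_families[ann$id == "E01"], "Rep_1,Rep_3")
  # classification order-invariance
  ann2 <- classify_elements(els, genes[sample(13), ], hits[sample(13), ])
  expect_identical(as.list(ann), as.list(ann2))
  expect_identical(attr(ann, "family_counts"), attr(ann2, "family_counts"))
})

test_that("partial genes are excluded and traits tallied separately", {
  els <- data.frame(id = "E1")
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), element_id = "E1",
                      partial = c(FALSE, TRUE, FALSE))
  hits <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    pfam_accession = c("PF00589.22", "PF01446.12", "PF01527.19"),
    e_value = 1e-9
  )
  ann <- classify_elements(els, genes, hits)
  expect_false(ann$has_replicon)   # the replicon hit sits on a partial gene
  expect_equal(ann$n_complete_genes, 2L)
  expect_equal(ann$traits, "phage_integrase:1,transposase:1")
})

test_that("dangling element references and ambiguous traits error", {
  els <- data.frame(id = "E1")
  genes <- data.frame(gene_id = "g1", element_id = "E9", partial = FALSE)
  hits <- data.frame(gene_id = "g1", pfam_accession = "PF01446.12", e_value = 1e-9)
  expect_error(classify_elements(els, genes, hits), "unknown element")
  genes_ok <- transform(genes, element_id = "E1")
  dup_traits <- rbind(default_trait_table(),
                      data.frame(trait = "toxin", accession = "PF00589"))
  dup_traits$accession[nrow(dup_traits)] <- "PF00589"
  expect_error(classify_elements(els, genes_ok, hits, trait_table = dup_traits),
               "at most one trait")
})

test_that("domtblout and gene-call files parse into the expected tables", {
  dom <- read_domtblout(system.file("extdata", "example_hits.domtblout",
                                    package = "circontig"))
  expect_equal(nrow(dom), 4L)
  expect_equal(dom$gene_id, c("g001", "g001", "g002", "g003"))
  expect_equal(dom$pfam_accession[1], "PF01446.12")
  expect_equal(dom$e_value[1], 1.2e-12)
  expect_equal(dom$bit_score[1], 44.8)

  genes <- read_gene_calls(
    system.file("extdata", "example_genes.gff", package = "circontig"),
    system.file("extdata", "example_proteins.faa", package = "circontig")
  )
  expect_equal(nrow(genes), 3L)
  expect_equal(genes$element_id, c("E01", "E01", "E02"))
  expect_equal(genes$partial, c(FALSE, FALSE, TRUE))
  expect_equal(genes$start[1], 100L)  # 0-based half-open
  expect_equal(genes$end[1], 600L)
  expect_match(genes$protein[1], "^MKKLDRETV")

  # fixture-driven end-to-end classification
  els <- data.frame(id = c("E01", "E02"))
  ann <- classify_elements(els, genes, dom)
  expect_true(ann$has_replicon[ann$id == "E01"])
  expect_equal(ann$n_replicon_domains[ann$id == "E01"], 2L)
  expect_false(ann$has_replicon[ann$id == "E02"])  # its gene is partial
})
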