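# The assembler is exercised end to end through populate() elsewhere; here
# the stage contracts are checked in isolation on a populated fixture and on
# hand-built degenerate stores.

test_that("assembly stages refuse to run before their prerequisites", {
  db <- local_db()
  expect_error(assemble_genomes_and_contigs(db, assembly_id = 1),
               class = "magdb_stage_order_error")
  expect_error(assemble_genes(db, assembly_id = 1),
               class = "magdb_stage_order_error")
  expect_error(assemble_proteins(db, assembly_id = 1),
               class = "magdb_stage_order_error")
  expect_error(
    link_protein_annotations(db, 1, tibble::tibble()),
    class = "magdb_stage_order_error"
  )
  expect_error(assemble_taxonomy(db, 1, tibble::tibble(x = 1)),
               class = "magdb_stage_order_error")
  # and a clean failure inserts nothing
  expect_true(all(table_counts(db)$n_rows == 0L))
})

test_that("stage reports carry the counts the fixture dictates", {
  fx <- populated_fixture(seed = 31)
  td <- tidy(fx$report)
  m <- fx$manifest
  expect_equal(td$created[td$entity == "genome"], m$n_genomes)
  expect_equal(td$created[td$entity == "contig"], m$n_contigs)
  expect_equal(td$created[td$entity == "gene"], m$n_genes)
  expect_equal(td$created[td$entity == "protein"], m$n_proteins)
  expect_equal(td$created[td$entity == "genome_cluster"], m$n_clusters)
  expect_equal(td$created[td$entity == "taxonomy_assignment"], m$n_genomes)
  expect_equal(sum(td$created[td$entity == "protein_annotation"]),
               sum(unlist(m$annotation_counts)))
  expect_equal(sum(td$n_unmatched), 0L)
})

test_that("conservation: genes equal ingested CDS features, proteins never
           exceed genes, annotations never exceed submissions", {
  fx <- populated_fixture(seed = 37)
  con <- fx$db$con
  n_cds <- DBI::dbGetQuery(con,
    "SELECT COUNT(*) FROM gff_entry WHERE feature_type = 'CDS'")[[1]]
  n_genes <- DBI::dbGetQuery(con, "SELECT COUNT(*) FROM gene")[[1]]
  n_prot <- DBI::dbGetQuery(con, "SELECT COUNT(*) FROM protein")[[1]]
  expect_equal(n_genes, n_cds)
  expect_lte(n_prot, n_genes)
  n_ann <- DBI::dbGetQuery(con, "SELECT COUNT(*) FROM protein_annotation")[[1]]
  expect_lte(n_ann, sum(unlist(fx$manifest$annotation_counts)))
  # non-CDS features were ingested but not promoted
  n_trna <- DBI::dbGetQuery(con,
    "SELECT COUNT(*) FROM gff_entry WHERE feature_type = 'tRNA'")[[1]]
  expect_gt(n_trna, 0L)
})

test_that("a CDS pointing at an unknown contig is a strict error naming it", {
  fx <- local_fixture(seed = 41, n_genomes = 2, contigs_per_genome = 2,
                      genes_per_contig = 2)
  # corrupt one GFF seqid before ingest
  gff <- list.files(file.path(fx$dir, "gff"), full.names = TRUE)[1]
  lines <- readLines(gff)
  i <- which(grepl("\tCDS\t", lines))[1]
  lines[i] <- sub("^[^\t]+", "ghost", lines[i])
  writeLines(lines, gff)
  db <- local_db()
  cfg <- load_config(file.path(fx$dir, "project.toml"))
  err <- tryCatch(populate(cfg, db = db), error = identity)
  expect_s3_class(err, "magdb_unresolved_reference")
  expect_match(conditionMessage(err), "ghost")
  # lenient mode records the key instead
  cfg$options$strict <- FALSE
  db2 <- local_db()
  rep <- populate(cfg, db = db2)
  unmatched <- unlist(lapply(rep$stages, `[[`, "unmatched_keys"))
  expect_true("ghost" %in% unmatched)
})

test_that("a trailing stop mark is excluded from protein length", {
  fx <- populated_fixture(seed = 43, n_genomes = 2, contigs_per_genome = 2,
                          genes_per_contig = 3)
  con <- fx$db$con
  got <- DBI::dbGetQuery(con,
    "SELECT p.sequence_length_aa, fe.sequence
     FROM protein p JOIN fasta_entry fe ON p.fasta_entry_id = fe.fasta_entry_id")
  expect_true(all(endsWith(got$sequence, "*")))
  expect_equal(got$sequence_length_aa, nchar(got$sequence) - 1L)
})

test_that("re-running every assembly stage is a no-op on row counts", {
  fx <- populated_fixture(seed = 47)
  before <- table_counts(fx$db)$n_rows
  aid <- DBI::dbGetQuery(fx$db$con, "SELECT assembly_id FROM assembly")[[1]]
  cache <- magdb_cache()
  assemble_genomes_and_contigs(fx$db, aid, cache = cache)
  assemble_genes(fx$db, aid, cache = cache)
  assemble_proteins(fx$db, aid, cache = cache)
  after <- table_counts(fx$db)$n_rows
  expect_equal(after, before)
})

test_that("shared lineages reuse taxon rows across genomes", {
  fx <- populated_fixture(seed = 53)
  con <- fx$db$con
  # all genomes share one domain..family chain; genera alternate between two
  per_rank <- DBI::dbGetQuery(con,
    "SELECT rank, COUNT(*) AS n FROM taxon GROUP BY rank")
  ranks <- stats::setNames(per_rank$n, per_rank$rank)
  expect_equal(unname(ranks[c("domain", "phylum", "class", "order", "family")]),
               rep(1L, 5))
  expect_equal(unname(ranks[["genus"]]), 2L)
  # parent chain: every non-domain taxon with a parent sits one rank below it
  expect_true(integrity_check(fx$db)$ok)
  n_novel_assign <- DBI::dbGetQuery(con,
    "SELECT COUNT(*) FROM taxonomy_assignment WHERE is_novel_species = 1")[[1]]
  expect_equal(n_novel_assign, fx$manifest$n_novel_genomes)
  # novel genomes point at their genus taxon, not a species
  deep <- DBI::dbGetQuery(con,
    "SELECT t.rank FROM taxonomy_assignment ta JOIN taxon t ON ta.taxon_id = t.taxon_id
     WHERE ta.is_novel_species = 1")
  expect_true(all(deep$rank == "genus"))
})

test_that("duplicate annotations collapse onto one row", {
  fx <- populated_fixture(seed = 59, n_genomes = 2, contigs_per_genome = 2,
                          genes_per_contig = 3, cazyme_density = 0.5)
  con <- fx$db$con
  aid <- DBI::dbGetQuery(con, "SELECT assembly_id FROM assembly")[[1]]
  prot <- DBI::dbGetQuery(con, "SELECT name FROM protein LIMIT 1")$name
  entry <- DBI::dbGetQuery(con,
    "SELECT protein_annotation_entry_id FROM protein_annotation_entry LIMIT 1")[[1]]
  ann <- unified_annotation(prot, "dbcan", "family", "GH99",
                            coord_start = 1L, coord_stop = 50L)
  ann$protein_annotation_entry_id <- entry
  before <- DBI::dbGetQuery(con, "SELECT COUNT(*) FROM protein_annotation")[[1]]
  r1 <- link_protein_annotations(fx$db, aid, ann)
  r2 <- link_protein_annotations(fx$db, aid, ann)
  after <- DBI::dbGetQuery(con, "SELECT COUNT(*) FROM protein_annotation")[[1]]
  expect_equal(after, before + 1L)
  expect_equal(unname(r1$created[["protein_annotation"]]), 1L)
  expect_equal(unname(r2$created[["protein_annotation"]]), 0L)
})
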