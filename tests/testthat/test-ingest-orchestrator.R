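test_that("file_checksum is deterministic and content-sensitive", {
  f <- withr::local_tempfile()
  file.create(f)
  # SHA-256 of empty input
  expect_equal(
    file_checksum(f),
    "e3b0c44298fc1c149afbf4c8996fb92427ae41e4649b934ca495991b7852b855"
  )
  writeLines("a", f)
  d1 <- file_checksum(f)
  expect_equal(file_checksum(f), d1)
  writeLines("b", f)
  expect_false(file_checksum(f) == d1)
  expect_error(file_checksum(file.path(tempdir(), "missing-file")),
               class = "magdb_io_error")
})

test_that("load_config validates structure, paths and plugins", {
  fx <- local_fixture(seed = 61)
  cfg <- load_config(file.path(fx$dir, "project.toml"))
  expect_s3_class(cfg, "magdb_config")
  expect_true(cfg$options$strict)
  expect_equal(cfg$options$batch_size, 1000L)
  expect_length(cfg$assemblies, 1L)
  expect_length(cfg$assemblies[[1]]$annotations, 4L)
  # loading twice round-trips to an equal structure
  expect_equal(load_config(file.path(fx$dir, "project.toml")), cfg)

  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "bins"))
  writeLines(c(">c1", "ACGT"), file.path(dir, "bins", "g1.fa"))

  # minimal config: one assembly, bins only
  writeLines(c('[project]', 'name = "mini"', '[[assemblies]]',
               'name = "a1"', 'bins_dir = "bins"'),
             file.path(dir, "mini.toml"))
  mini <- load_config(file.path(dir, "mini.toml"))
  expect_null(mini$assemblies[[1]]$gff_dir)
  expect_null(mini$assemblies[[1]]$gtdbtk_summary)

  # missing mandatory key
  writeLines(c('[project]', 'name = ""'), file.path(dir, "bad1.toml"))
  err <- tryCatch(load_config(file.path(dir, "bad1.toml")), error = identity)
  expect_s3_class(err, "magdb_config_error")
  expect_match(conditionMessage(err), "project.name")

  # nonexistent path
  writeLines(c('[project]', 'name = "p"', '[[assemblies]]', 'name = "a"',
               'bins_dir = "no-such-dir"'), file.path(dir, "bad2.toml"))
  expect_error(load_config(file.path(dir, "bad2.toml")),
               class = "magdb_config_error")

  # unknown plugin
  writeLines(c('[project]', 'name = "p"', '[[assemblies]]', 'name = "a"',
               'bins_dir = "bins"', '[[assemblies.annotations]]',
               'plugin_name = "nonexistent"', 'path = "bins"'),
             file.path(dir, "bad3.toml"))
  err3 <- tryCatch(load_config(file.path(dir, "bad3.toml")), error = identity)
  expect_s3_class(err3, "magdb_config_error")
  expect_match(conditionMessage(err3), "nonexistent")
})

test_that("a bins-only project populates genomes and contigs, nothing more", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "bins"))
  writeLines(c(">c1 first", "ACGTACGT", ">c2", "GGCC"),
             file.path(dir, "bins", "g1.fa"))
  writeLines(c('[project]', 'name = "mini"', '[[assemblies]]',
               'name = "a1"', 'bins_dir = "bins"'),
             file.path(dir, "mini.toml"))
  db <- local_db()
  rep <- populate(load_config(file.path(dir, "mini.toml")), db = db)
  tc <- table_counts(db)
  n <- stats::setNames(tc$n_rows, tc$table_name)
  expect_equal(unname(n[c("genome", "contig", "gene", "protein",
                          "protein_annotation", "taxonomy_assignment")]),
               c(1L, 2L, 0L, 0L, 0L, 0L))
  expect_true(integrity_check(db)$ok)
})

test_that("the audit covers every configured file exactly once, with digests", {
  fx <- populated_fixture(seed = 67)
  audit <- fx$report$files
  expect_false(any(duplicated(audit$path)))
  expect_true(all(nchar(audit$sha256) == 64))
  cfg_a <- fx$config$assemblies[[1]]
  configured <- c(
    list.files(cfg_a$bins_dir, full.names = TRUE),
    list.files(cfg_a$gff_dir, full.names = TRUE),
    list.files(cfg_a$proteins_dir, full.names = TRUE),
    cfg_a$gtdbtk_summary, cfg_a$drep_cluster_table, cfg_a$drep_winners_table,
    cfg_a$checkm2_report,
    vapply(cfg_a$annotations, `[[`, "", "path")
  )
  expect_setequal(normalizePath(audit$path), normalizePath(configured))
  for (p in audit$path) {
    expect_equal(file_checksum(p), audit$sha256[audit$path == p])
  }
})

test_that("a file changed on disk since first ingest aborts in strict mode", {
  fx <- populated_fixture(seed = 71, n_genomes = 2, contigs_per_genome = 2,
                          genes_per_contig = 2)
  bin <- list.files(file.path(fx$dir, "bins"), full.names = TRUE)[1]
  cat(">extra\nACGT\n", file = bin, append = TRUE)
  expect_error(populate(fx$config, db = fx$db), class = "magdb_file_changed")
})

test_that("tool and source metadata default to unknown when unconfigured", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "bins"))
  writeLines(c(">c1", "ACGT"), file.path(dir, "bins", "g1.fa"))
  writeLines(c('[project]', 'name = "mini"', '[[assemblies]]',
               'name = "a1"', 'bins_dir = "bins"'),
             file.path(dir, "mini.toml"))
  db <- local_db()
  populate(load_config(file.path(dir, "mini.toml")), db = db)
  tools <- DBI::dbGetQuery(db$con, "SELECT name, version FROM tool")
  expect_equal(tools$name, "unknown")
  expect_equal(tools$version, "unknown")
  runs <- DBI::dbGetQuery(db$con, "SELECT COUNT(*) FROM run")[[1]]
  expect_equal(runs, 1L)
})

test_that("tidy() and glance() summarize an ingest report", {
  fx <- populated_fixture(seed = 73)
  td <- tidy(fx$report)
  expect_true(all(c("stage", "entity", "created", "linked", "n_unmatched")
                  %in% names(td)))
  expect_gt(nrow(td), 5L)
  gl <- glance(fx$report)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_files, nrow(fx$report$files))
  expect_equal(gl$total_rows, sum(fx$report$table_counts$n_rows))
  expect_equal(gl$n_unmatched, 0L)
})
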