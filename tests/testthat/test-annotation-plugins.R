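write_tmp <- function(lines, ext = ".txt", env = parent.frame()) {
  f <- withr::local_tempfile(fileext = ext, .local_envir = env)
  writeLines(lines, f)
  f
}

dbcan_header <- "Gene ID\tEC#\tHMMER\tdbCAN_sub\tDIAMOND\tRecommend Results\t#ofTools"

test_that("dbCAN consensus units expand to family and subfamily annotations", {
  f <- write_tmp(c(dbcan_header,
                   "p1\t-\tGH5_2(31-330)\t-\t-\tGH5_2(31-330)\t3"), ".tsv")
  ann <- parse_dbcan_overview(f)
  expect_equal(nrow(ann), 2L)
  fam <- ann[ann$annotation_type == "family", ]
  expect_equal(fam$accession, "GH5")
  expect_equal(fam$coord_start, 31L)
  expect_equal(fam$coord_stop, 330L)
  expect_equal(fam$score, 3)
  sub <- ann[ann$annotation_type == "subfamily", ]
  expect_equal(sub$accession, "GH5_2")
  expect_true(all(ann$source_tool == "dbcan"))

  multi <- write_tmp(c(dbcan_header,
                       "p2\t-\t-\t-\t-\tCBM3(5-90)+GH5(120-400)\t2"), ".tsv")
  ann2 <- parse_dbcan_overview(multi)
  expect_equal(ann2$annotation_type, c("family", "family"))
  expect_setequal(ann2$accession, c("CBM3", "GH5"))

  dash <- write_tmp(c(dbcan_header, "p3\t-\t-\t-\t-\t-\t0"), ".tsv")
  expect_equal(nrow(parse_dbcan_overview(dash)), 0L)
})

test_that("dbCAN rows with malformed family tokens are skipped with a count", {
  f <- write_tmp(c(dbcan_header,
                   "p1\t-\t-\t-\t-\tZZ9(1-5)\t1",
                   "p2\t-\t-\t-\t-\tGH13\t2"), ".tsv")
  expect_warning(ann <- parse_dbcan_overview(f), "skipped 1 row")
  expect_equal(attr(ann, "skipped_rows"), 1L)
  expect_equal(ann$protein_key, "p2")
  expect_equal(ann$accession, "GH13")
})

test_that("InterProScan lines yield signature, InterPro and GO annotations", {
  line <- paste("p5", "md5", "420", "Pfam", "PF00150",
                "Cellulase (glycosyl hydrolase family 5)", "40", "310",
                "1.2e-50", "T", "01-01-2026", "IPR001547",
                "Glycoside hydrolase family 5",
                "GO:0004553|GO:0005975", sep = "\t")
  f <- write_tmp(line, ".tsv")
  ann <- parse_interproscan_tsv(f)
  expect_equal(nrow(ann), 4L)
  sig <- ann[ann$accession == "PF00150", ]
  expect_equal(sig$annotation_type, "domain")
  expect_equal(sig$source_tool, "interproscan:Pfam")
  expect_equal(sig$score, 1.2e-50)
  expect_equal(sig$coord_start, 40L)
  expect_equal(sig$coord_stop, 310L)
  ipr <- ann[ann$accession == "IPR001547", ]
  expect_equal(ipr$annotation_type, "domain")
  go <- ann[ann$annotation_type == "go_term", ]
  expect_setequal(go$accession, c("GO:0004553", "GO:0005975"))

  # '-' e-value means absent score; 11 plain columns stay valid
  line2 <- paste("p6", "md5", "100", "CDD", "cd00001", "-", "1", "90", "-",
                 "T", "01-01-2026", sep = "\t")
  ann2 <- parse_interproscan_tsv(write_tmp(line2, ".tsv"))
  expect_equal(nrow(ann2), 1L)
  expect_true(is.na(ann2$score))

  short <- write_tmp("p7\tmd5\t100\tPfam", ".tsv")
  err <- tryCatch(parse_interproscan_tsv(short), error = identity)
  expect_s3_class(err, "magdb_format_error")
  expect_match(conditionMessage(err), "line 1")
})

test_that("CLEAN terms split into scored EC annotations", {
  f <- write_tmp("p7,EC:3.2.1.4/0.8731;EC:3.2.1.91/0.1012", ".csv")
  ann <- parse_clean_output(f)
  expect_equal(nrow(ann), 2L)
  expect_true(all(ann$annotation_type == "ec_number"))
  expect_equal(ann$accession, c("3.2.1.4", "3.2.1.91"))
  expect_equal(ann$score, c(0.8731, 0.1012))

  expect_equal(nrow(parse_clean_output(write_tmp(character(), ".csv"))), 0L)

  # scores are not range-constrained
  big <- parse_clean_output(write_tmp("p1,EC:1.1.1.1/1.5", ".csv"))
  expect_equal(big$score, 1.5)

  expect_error(parse_clean_output(write_tmp("p1,EC:1.1.1.1", ".csv")),
               class = "magdb_format_error")
})

test_that("ProteInfer labels map to go_term / ec_number / description", {
  f <- write_tmp(c("sequence_name\tpredicted_label\tconfidence",
                   "p3\tGO:0016787\t0.97",
                   "p3\tEC:3.2.1.-\t0.88",
                   "p4\tputative hydrolase\t0.5"), ".tsv")
  ann <- parse_proteinfer_output(f)
  expect_equal(ann$annotation_type, c("go_term", "ec_number", "description"))
  expect_equal(ann$accession[1], "GO:0016787")
  expect_equal(ann$accession[2], "3.2.1.-")
  expect_equal(ann$score, c(0.97, 0.88, 0.5))

  header_only <- write_tmp("sequence_name\tpredicted_label\tconfidence", ".tsv")
  expect_equal(nrow(parse_proteinfer_output(header_only)), 0L)

  bad <- write_tmp(c("sequence_name\tpredicted_label\tconfidence",
                     "p1\tGO:1\thigh"), ".tsv")
  expect_error(parse_proteinfer_output(bad), class = "magdb_format_error")
})

test_that("every reference parser is deterministic and emits valid records", {
  fx <- local_fixture(seed = 23)
  files <- list(
    dbcan = file.path(fx$dir, "annotations", "dbcan_overview.tsv"),
    interpro = file.path(fx$dir, "annotations", "interproscan.tsv"),
    clean = file.path(fx$dir, "annotations", "clean.csv"),
    proteinfer = file.path(fx$dir, "annotations", "proteinfer.tsv")
  )
  parsers <- list(parse_dbcan_overview, parse_interproscan_tsv,
                  parse_clean_output, parse_proteinfer_output)
  for (i in seq_along(files)) {
    a <- parsers[[i]](files[[i]])
    b <- parsers[[i]](files[[i]])
    expect_identical(a, b)
    expect_silent(validate_annotations(a))
    expect_gt(nrow(a), 0L)
  }
})

test_that("plugins never touch the schema catalog", {
  db <- local_db()
  fx <- local_fixture(seed = 29)
  before <- sort(DBI::dbListTables(db$con))
  invisible(parse_dbcan_overview(
    file.path(fx$dir, "annotations", "dbcan_overview.tsv")))
  invisible(parse_clean_output(file.path(fx$dir, "annotations", "clean.csv")))
  expect_identical(sort(DBI::dbListTables(db$con)), before)
})

test_that("plugin discovery lists the reference set and honors disabling", {
  desc <- discover_plugins()
  expect_true(all(c("dbcan", "interpro", "clean", "proteinfer") %in% desc$name))
  expect_false(any(duplicated(desc$name)))
  expect_equal(nrow(discover_plugins(include_builtins = FALSE)), 0L)

  withr::defer(plugin_set_enabled("dbcan", TRUE))
  plugin_set_enabled("dbcan", FALSE)
  desc2 <- discover_plugins()
  expect_false(desc2$enabled[desc2$name == "dbcan"])
  expect_true(desc2$enabled[desc2$name == "clean"])
  expect_error(plugin_set_enabled("no-such-plugin", TRUE),
               class = "magdb_plugin_error")
})
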