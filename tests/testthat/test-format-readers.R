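write_tmp <- function(lines, ext = ".txt", env = parent.frame()) {
  f <- withr::local_tempfile(fileext = ext, .local_envir = env)
  writeLines(lines, f)
  f
}

test_that("read_fasta concatenates, uppercases and splits headers", {
  f <- write_tmp(c(">c1 circular", "ACGT", "acgt"), ".fa")
  rec <- read_fasta(f)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$id, "c1")
  expect_equal(rec$description, "circular")
  expect_equal(rec$sequence, "ACGTACGT")

  empty <- write_tmp(character(), ".fa")
  expect_equal(nrow(read_fasta(empty)), 0L)

  bad <- write_tmp(c("ACGT", ">c1", "ACGT"), ".fa")
  expect_error(read_fasta(bad), class = "magdb_malformed_fasta")
  expect_error(read_fasta(file.path(tempdir(), "no-such-file.fa")),
               class = "magdb_io_error")
})

test_that("FASTA write-then-read round-trips on (id, description, sequence)", {
  withr::local_seed(99)
  records <- tibble::tibble(
    id = sprintf("seq%02d", 1:12),
    description = ifelse(1:12 %% 3 == 0, "", sprintf("desc %d", 1:12)),
    sequence = vapply(
      sample(c(0, 1, 3, 79, 80, 81, 200), 12, replace = TRUE),
      function(n) paste(sample(c(LETTERS, "*", "-"), n, replace = TRUE),
                        collapse = ""),
      ""
    )
  )
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(records, f, width = 80)
  back <- read_fasta(f)
  expect_equal(back$id, records$id)
  expect_equal(back$description, records$description)
  expect_equal(back$sequence, records$sequence)
})

test_that("read_fasta agrees with Biostrings on a generated bin file", {
  skip_if_not_installed("Biostrings")
  fx <- local_fixture(seed = 3)
  bin <- list.files(file.path(fx$dir, "bins"), full.names = TRUE)[1]
  ours <- read_fasta(bin)
  ref <- Biostrings::readBStringSet(bin)
  expect_equal(ours$id, vapply(strsplit(names(ref), " "), `[[`, "", 1))
  expect_equal(ours$sequence, unname(as.character(ref)))
})

test_that("read_gff3 maps columns, skips comments and stops at ##FASTA", {
  only_directive <- write_tmp("##gff-version 3", ".gff")
  expect_equal(nrow(read_gff3(only_directive)), 0L)

  f <- write_tmp(c(
    "##gff-version 3",
    "c1\tProdigal\tCDS\t10\t39\t.\t+\t0\tID=g1;product=hypothetical protein",
    "c1\tProdigal\tCDS\t50\t70\t3.5\t-\t.\tID=g2;note=x%3By"
  ), ".gff")
  feats <- read_gff3(f)
  expect_equal(nrow(feats), 2L)
  expect_equal(feats$seqid[1], "c1")
  expect_equal(feats$feature_type[1], "CDS")
  expect_equal(feats$start[1], 10L)
  expect_equal(feats$end[1], 39L)
  expect_equal(feats$strand[1], "+")
  expect_equal(feats$frame[1], 0L)
  expect_true(is.na(feats$score[1]))
  expect_equal(feats$attributes[[1]][["ID"]], "g1")
  expect_equal(feats$attributes[[1]][["product"]], "hypothetical protein")
  # percent-decoding and '.' handling
  expect_equal(feats$attributes[[2]][["note"]], "x;y")
  expect_equal(feats$score[2], 3.5)
  expect_true(is.na(feats$frame[2]))

  bad <- write_tmp("c1\tProdigal\tCDS\t10\t39\t.\t+", ".gff")
  err <- tryCatch(read_gff3(bad), error = identity)
  expect_s3_class(err, "magdb_malformed_gff")
  expect_match(conditionMessage(err), "line 1")
})

test_that("feature count ignores the trailing ##FASTA block", {
  fx <- local_fixture(seed = 5)
  gff <- list.files(file.path(fx$dir, "gff"), full.names = TRUE)[1]
  feats <- read_gff3(gff)
  # independent text scan: 9-column lines above the directive
  lines <- readLines(gff)
  cut <- which(startsWith(lines, "##FASTA"))[1]
  body <- lines[seq_len(cut - 1)]
  body <- body[!startsWith(body, "#")]
  expect_equal(nrow(feats), length(body))
  expect_true(all(feats$start <= feats$end))
  # removing the FASTA block changes nothing
  f2 <- withr::local_tempfile(fileext = ".gff")
  writeLines(lines[seq_len(cut - 1)], f2)
  expect_equal(nrow(read_gff3(f2)), nrow(feats))
})

test_that("read_gff3 agrees with rtracklayer on a generated file", {
  skip_if_not_installed("rtracklayer")
  fx <- local_fixture(seed = 13)
  gff <- list.files(file.path(fx$dir, "gff"), full.names = TRUE)[1]
  ours <- read_gff3(gff)
  ref <- suppressWarnings(rtracklayer::readGFF(gff))
  expect_equal(nrow(ours), nrow(ref))
  expect_equal(ours$start, as.integer(ref$start))
  expect_equal(ours$end, as.integer(ref$end))
  expect_equal(vapply(ours$attributes, `[[`, "", "ID"), as.character(ref$ID))
})

test_that("GTDB-style lineage strings split into ranks with novelty flags", {
  f <- write_tmp(c(
    "user_genome\tclassification",
    "bin1\td__Bacteria;p__Bacillota;c__;o__;f__;g__;s__",
    "bin2\td__Bacteria;p__Bacillota;c__Clostridia;o__Lachnospirales;f__Lachnospiraceae;g__Blautia;s__Blautia sp1",
    "bin3\tUnclassified"
  ), ".tsv")
  rows <- parse_gtdbtk_summary(f)
  expect_equal(rows$lowest_assigned_rank, c("phylum", "species", NA))
  expect_equal(rows$is_novel_species, c(TRUE, FALSE, TRUE))
  expect_equal(rows$lineage[[2]][["genus"]], "Blautia")
  expect_length(rows$lineage[[3]], 7L)
  expect_true(all(is.na(rows$lineage[[3]])))

  missing_col <- write_tmp(c("genome\tlineage", "x\ty"), ".tsv")
  expect_error(parse_gtdbtk_summary(missing_col), class = "magdb_format_error")
  out_of_order <- write_tmp(c("user_genome\tclassification",
                              "b\tp__Bacillota;d__Bacteria"), ".tsv")
  expect_error(parse_gtdbtk_summary(out_of_order), class = "magdb_format_error")
})

test_that("filling a row's species slot flips only its novelty", {
  # novelty is monotone in the species slot
  base <- c(
    "user_genome\tclassification",
    sprintf("bin%d\td__Bacteria;p__B;c__C;o__O;f__F;g__G%d;s__", 1:4, 1:4)
  )
  f <- write_tmp(base, ".tsv")
  before <- parse_gtdbtk_summary(f)
  expect_true(all(before$is_novel_species))
  for (i in 1:4) {
    amended <- base
    amended[i + 1] <- sub("s__$", sprintf("s__G%d sp", i), amended[i + 1])
    fa <- write_tmp(amended, ".tsv")
    after <- parse_gtdbtk_summary(fa)
    expect_false(after$is_novel_species[i])
    expect_equal(after$is_novel_species[-i], before$is_novel_species[-i])
    expect_equal(after$lineage[-i], before$lineage[-i])
  }
})

test_that("dRep tables group genomes and flag winners", {
  cl <- write_tmp(c("genome,secondary_cluster",
                    "g1.fa,1_1", "g2.fa,1_1", "g3.fa,2_1"), ".csv")
  rows <- parse_drep_tables(cl)
  expect_equal(nrow(rows), 3L)
  expect_equal(length(unique(rows$cluster_label)), 2L)
  expect_equal(as.integer(table(rows$cluster_label)[c("1_1", "2_1")]), c(2L, 1L))
  expect_false(any(rows$is_winner))

  wn <- write_tmp(c("genome", "g1.fa", "g3.fa"), ".csv")
  rows2 <- parse_drep_tables(cl, wn)
  expect_equal(sum(rows2$is_winner), 2L)
  expect_setequal(rows2$genome_name[rows2$is_winner], c("g1", "g3"))

  empty <- write_tmp("genome,secondary_cluster", ".csv")
  expect_equal(nrow(parse_drep_tables(empty)), 0L)

  ghost <- write_tmp(c("genome", "g9.fa"), ".csv")
  expect_error(parse_drep_tables(cl, ghost), class = "magdb_crossfile_error")
})

test_that("CheckM2 reports parse with range validation", {
  f <- write_tmp(c("Name\tCompleteness\tContamination", "bin1\t98.5\t1.2"),
                 ".tsv")
  rows <- parse_checkm2_report(f)
  expect_equal(rows$genome_name, "bin1")
  expect_equal(rows$completeness_pct, 98.5)
  expect_equal(rows$contamination_pct, 1.2)

  over <- write_tmp(c("Name\tCompleteness\tContamination", "bin1\t101.0\t1.2"),
                    ".tsv")
  expect_error(parse_checkm2_report(over), class = "magdb_validation_error")
  nonnum <- write_tmp(c("Name\tCompleteness\tContamination", "bin1\thigh\t1.2"),
                      ".tsv")
  expect_error(parse_checkm2_report(nonnum), class = "magdb_format_error")

  fx <- local_fixture(seed = 17, n_genomes = 5)
  rep <- parse_checkm2_report(file.path(fx$dir, "checkm2", "quality_report.tsv"))
  expect_equal(nrow(rep), fx$manifest$n_genomes)
  expect_setequal(rep$genome_name, sprintf("bin_%02d", 1:5))
})

test_that("genome names are normalized by stripping one FASTA extension", {
  expect_equal(normalize_genome_name(c("a/b/bin_01.fa", "x.fasta", "y.fna")),
               c("bin_01", "x", "y"))
  expect_equal(normalize_genome_name("bin.v2.fasta"), "bin.v2")
  expect_equal(normalize_genome_name("plain"), "plain")
})
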