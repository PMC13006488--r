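test_that("CAZyme queries match the flat-file oracle on a fixture", {
  fx <- populated_fixture(seed = 79)
  hits <- query_cazymes_novel_taxa(fx$db)
  expect_identical(hits_key(hits), oracle_cazyme_hits(fx$dir))
  expect_true(all(grepl("^(GH|GT|PL|CE|AA|CBM)", hits$family_accession)))
  counts <- query_family_counts_per_genome(fx$db, "GH5", novel_only = TRUE)
  expect_identical(counts_key(counts), oracle_family_counts(fx$dir, "GH5"))
  # absent family: empty, not an error
  expect_equal(nrow(query_family_counts_per_genome(fx$db, "GH999")), 0L)
})

test_that("a fixture without novel genomes yields no novel-taxon CAZymes", {
  fx <- populated_fixture(seed = 83, novel_fraction = 0)
  expect_equal(nrow(query_cazymes_novel_taxa(fx$db)), 0L)
  expect_equal(nrow(query_family_counts_per_genome(fx$db, "GH5",
                                                   novel_only = TRUE)), 0L)
  # without the novelty filter the families are there
  expect_gt(nrow(query_family_counts_per_genome(fx$db, "GH5",
                                                novel_only = FALSE)), 0L)
})

test_that("novel_only=FALSE differs from novel_only=TRUE exactly by
           non-novel genomes", {
  fx <- populated_fixture(seed = 89)
  all_rows <- query_family_counts_per_genome(fx$db, "GH5", novel_only = FALSE)
  novel_rows <- query_family_counts_per_genome(fx$db, "GH5", novel_only = TRUE)
  novel <- oracle_novel_genomes(fx$dir)
  expect_setequal(setdiff(all_rows$genome_name, novel_rows$genome_name),
                  setdiff(all_rows$genome_name, novel))
  joined <- merge(all_rows, novel_rows, by = "genome_name")
  expect_equal(joined$protein_count.x, joined$protein_count.y)
})

test_that("the novelty rank threshold is configurable", {
  fx <- populated_fixture(seed = 97)
  # every fixture genome is assigned at genus, so genus-level novelty is empty
  expect_equal(nrow(query_cazymes_novel_taxa(fx$db, novelty_rank = "genus")),
               0L)
  # domain-level novelty is empty a fortiori; species matches the default
  species <- query_cazymes_novel_taxa(fx$db, novelty_rank = "species")
  expect_identical(hits_key(species), hits_key(query_cazymes_novel_taxa(fx$db)))
  expect_error(query_cazymes_novel_taxa(fx$db, novelty_rank = "strain"),
               class = "magdb_validation_error")
})

test_that("results over all projects equal the union of per-project results", {
  db <- local_db()
  dirs <- list()
  for (p in c("proj_a", "proj_b")) {
    dir <- withr::local_tempdir()
    generate_project_fixture(dir, seed = if (p == "proj_a") 101 else 102,
                             project_name = p)
    populate(load_config(file.path(dir, "project.toml")), db = db)
    dirs[[p]] <- dir
  }
  all_hits <- query_cazymes_novel_taxa(db)
  per_project <- lapply(names(dirs), function(p) {
    query_cazymes_novel_taxa(db, project = p)
  })
  union_key <- sort(unlist(lapply(per_project, function(h) {
    paste(h$project_name, h$genome_name, h$protein_name, h$family_accession)
  })))
  all_key <- sort(paste(all_hits$project_name, all_hits$genome_name,
                        all_hits$protein_name, all_hits$family_accession))
  expect_identical(all_key, union_key)
  # and each per-project result matches its own flat files
  for (p in names(dirs)) {
    got <- query_cazymes_novel_taxa(db, project = p)
    expect_identical(hits_key(got), oracle_cazyme_hits(dirs[[p]]))
  }
})

test_that("the query registry dispatches, validates and serializes", {
  fx <- populated_fixture(seed = 103)
  direct <- query_cazymes_novel_taxa(fx$db)
  via_registry <- run_named_query(fx$db, "cazymes-novel-taxa")
  expect_equal(tibble::as_tibble(via_registry), tibble::as_tibble(direct))

  err <- tryCatch(run_named_query(fx$db, "foo"), error = identity)
  expect_s3_class(err, "magdb_lookup_error")
  expect_match(conditionMessage(err), "cazymes-novel-taxa")
  expect_match(conditionMessage(err), "family-counts")

  expect_error(
    run_named_query(fx$db, "family-counts",
                    list(family_accession = "GH5", bogus = 1)),
    class = "magdb_validation_error"
  )

  tsv <- run_named_query(fx$db, "family-counts",
                         list(family_accession = "GH5"), "tsv")
  lines <- strsplit(tsv, "\n")[[1]]
  expect_equal(lines[1],
               "project_name\tgenome_name\tfamily_accession\tprotein_count")
  expect_equal(length(lines) - 1L,
               nrow(query_family_counts_per_genome(fx$db, "GH5")))

  js <- run_named_query(fx$db, "family-counts",
                        list(family_accession = "GH5"), "json")
  parsed <- jsonlite::fromJSON(js)
  expect_equal(nrow(parsed), length(lines) - 1L)
})

test_that("named queries and the API never change any table's row count", {
  fx <- populated_fixture(seed = 107)
  before <- table_counts(fx$db)$n_rows
  invisible(query_cazymes_novel_taxa(fx$db))
  invisible(query_family_counts_per_genome(fx$db, "GH5"))
  gid <- DBI::dbGetQuery(fx$db$con, "SELECT genome_id FROM genome LIMIT 1")[[1]]
  pid <- DBI::dbGetQuery(fx$db$con, "SELECT protein_id FROM protein LIMIT 1")[[1]]
  for (route in list(
    "/projects",
    "/projects/1/genomes",
    paste0("/genomes/", gid),
    paste0("/genomes/", gid, "/proteins"),
    paste0("/proteins/", pid, "/annotations"),
    "/queries/cazymes-novel-taxa",
    "/queries/family-counts"
  )) {
    res <- api_request(fx$db, "GET", route,
                       if (grepl("family-counts", route)) list(family = "GH5")
                       else list())
    expect_equal(res$status, 200L)
  }
  expect_equal(table_counts(fx$db)$n_rows, before)
  # mutating verbs are refused outright
  expect_equal(api_request(fx$db, "POST", "/projects")$status, 405L)
  expect_equal(api_request(fx$db, "DELETE", "/genomes/1")$status, 405L)
})

test_that("API query endpoints serve the in-process query results", {
  fx <- populated_fixture(seed = 109)
  res <- api_request(fx$db, "GET", "/queries/family-counts",
                     list(family = "GH5", novel_only = "true"))
  expect_equal(tibble::as_tibble(res$body),
               tibble::as_tibble(
                 query_family_counts_per_genome(fx$db, "GH5",
                                                novel_only = TRUE)))
  res2 <- api_request(fx$db, "GET", "/queries/cazymes-novel-taxa")
  expect_equal(tibble::as_tibble(res2$body),
               tibble::as_tibble(query_cazymes_novel_taxa(fx$db)))
  expect_equal(api_request(fx$db, "GET", "/queries/unknown")$status, 404L)
})

test_that("list endpoints paginate with limit and offset", {
  fx <- populated_fixture(seed = 113)
  page1 <- api_request(fx$db, "GET", "/projects/1/genomes",
                       list(limit = "2", offset = "0"))$body
  page2 <- api_request(fx$db, "GET", "/projects/1/genomes",
                       list(limit = "2", offset = "2"))$body
  expect_equal(nrow(page1), 2L)
  expect_equal(nrow(page2), 2L)
  expect_false(any(page1$genome_id %in% page2$genome_id))
})

test_that("query result plots build without error", {
  fx <- populated_fixture(seed = 127)
  counts <- query_family_counts_per_genome(fx$db, "GH5", novel_only = FALSE)
  p1 <- ggplot2::autoplot(counts)
  expect_s3_class(p1, "ggplot")
  hits <- query_cazymes_novel_taxa(fx$db)
  p2 <- ggplot2::autoplot(hits)
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
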