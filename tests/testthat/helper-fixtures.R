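# Shared test helpers: throwaway databases, generated fixture projects and
# an independent flat-file oracle for the biological queries. The oracle
# deliberately uses only base R line parsing -- no package readers, no
# database -- so it cannot share a defect with the code it checks.

local_db <- function(env = parent.frame()) {
  db <- magdb_connect(":memory:")
  withr::defer(magdb_disconnect(db), envir = env)
  initialize_schema(db)
  db
}

local_fixture <- function(seed = 42, ..., env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  manifest <- generate_project_fixture(dir, seed = seed, ...)
  list(
    dir = dir,
    manifest = manifest,
    config = load_config(file.path(dir, "project.toml"))
  )
}

populated_fixture <- function(seed = 42, ..., env = parent.frame()) {
  fx <- local_fixture(seed = seed, ..., env = env)
  fx$db <- local_db(env = env)
  fx$report <- populate(fx$config, db = fx$db)
  fx
}

# -- flat-file oracle --------------------------------------------------------

oracle_split <- function(line, sep = "\t") strsplit(line, sep, fixed = TRUE)[[1]]

# Genome names whose species slot is empty in the taxonomy summary.
oracle_novel_genomes <- function(dir) {
  lines <- readLines(file.path(dir, "gtdbtk", "summary.tsv"))[-1]
  out <- character()
  for (l in lines) {
    f <- oracle_split(l)
    ranks <- oracle_split(f[2], ";")
    if (length(ranks) < 7 || ranks[7] == "s__") out <- c(out, f[1])
  }
  out
}

# Family/subfamily accessions carried by one dbCAN consensus unit.
oracle_unit_accessions <- function(unit) {
  base <- sub("\\(.*$", "", unit)
  fam <- sub("_.*$", "", base)
  unique(c(fam, if (base != fam) base))
}

# Distinct (genome, protein, accession) triples for novel genomes, straight
# from the fixture's files. Protein ids embed their genome as the first two
# underscore-separated fields.
oracle_cazyme_hits <- function(dir) {
  novel <- oracle_novel_genomes(dir)
  lines <- readLines(file.path(dir, "annotations", "dbcan_overview.tsv"))
  header <- oracle_split(lines[1])
  cons_col <- match("Recommend Results", header)
  hits <- character()
  for (l in lines[-1]) {
    f <- oracle_split(l)
    protein <- f[1]
    genome <- paste(oracle_split(protein, "_")[1:2], collapse = "_")
    if (!genome %in% novel) next
    cons <- f[cons_col]
    if (cons %in% c("-", "")) next
    for (unit in oracle_split(cons, "+")) {
      for (acc in oracle_unit_accessions(unit)) {
        hits <- c(hits, paste(genome, protein, acc, sep = "\r"))
      }
    }
  }
  sort(unique(hits))
}

# Per-genome distinct-protein counts for one exact accession, novel only.
oracle_family_counts <- function(dir, family = "GH5", novel_only = TRUE) {
  novel <- oracle_novel_genomes(dir)
  lines <- readLines(file.path(dir, "annotations", "dbcan_overview.tsv"))
  header <- oracle_split(lines[1])
  cons_col <- match("Recommend Results", header)
  pairs <- character()
  for (l in lines[-1]) {
    f <- oracle_split(l)
    protein <- f[1]
    genome <- paste(oracle_split(protein, "_")[1:2], collapse = "_")
    if (novel_only && !genome %in% novel) next
    cons <- f[cons_col]
    if (cons %in% c("-", "")) next
    accs <- unique(unlist(lapply(oracle_split(cons, "+"),
                                 oracle_unit_accessions)))
    if (family %in% accs) pairs <- c(pairs, paste(genome, protein, sep = "\r"))
  }
  pairs <- unique(pairs)
  if (length(pairs) == 0) return(stats::setNames(integer(), character()))
  genomes <- vapply(strsplit(pairs, "\r", fixed = TRUE), `[[`, "", 1)
  tab <- table(genomes)
  stats::setNames(as.integer(tab), names(tab))
}

# Canonical comparison forms for query results.
hits_key <- function(hits) {
  sort(paste(hits$genome_name, hits$protein_name, hits$family_accession,
             sep = "\r"))
}

counts_key <- function(counts) {
  stats::setNames(as.integer(counts$protein_count), counts$genome_name)
}
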