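# Seeded generator of a complete synthetic MAG project directory tree plus
# a ground-truth manifest. The generator builds the whole project in memory
# first and derives every manifest count from that truth, then writes the
# files; it emulates file dialects (Prokka-style GFF3 + .faa, GTDB-style
# summary, dRep Cdb/Wdb, CheckM2 report, dbCAN/InterProScan/CLEAN/ProteInfer
# outputs), not biologically realistic sequence composition.

# One RNG stream per file type, derived from the master seed, so adding a
# file type never perturbs existing files across versions. Streams restore
# the caller's RNG state.
with_stream <- function(seed, offset, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed((as.integer(seed) * 97L + as.integer(offset)) %% 2147483629L)
  force(expr)
}

random_string <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Generate a synthetic MAG project with a ground-truth manifest
#'
#' Writes a complete project directory tree: genome bin FASTA files, one
#' Prokka-style GFF3 (with a trailing `##FASTA` section and one tRNA per
#' genome) and protein FASTA per genome, a GTDB-style taxonomy summary, a
#' dRep cluster/winners table pair, a CheckM2 quality report, one output
#' file per reference annotation plugin, and the TOML configuration that
#' ingests it all. Deterministic for a given seed.
#'
#' Genes are laid out as sequential non-overlapping windows with a fixed
#' 50 bp inter-gene gap, so the coordinate invariants hold by
#' construction. Protein lengths are `floor(gene_length / 3)` residues
#' (written with a trailing `*` stop). `round(novel_fraction * n_genomes)`
#' genomes get an empty species slot in the taxonomy summary;
#' `round(cazyme_density * n_proteins)` proteins get a dbCAN family
#' (GH5 among them); genomes are grouped into `ceiling(n_genomes / 2)`
#' dereplication clusters.
#'
#' @param out_dir Output directory (created; must not require privileges).
#' @param seed Master seed; every random stream derives from it.
#' @param n_genomes,contigs_per_genome,genes_per_contig Project size.
#' @param novel_fraction Fraction of genomes left species-unassigned.
#' @param cazyme_density Fraction of proteins given a dbCAN family.
#' @param project_name Name recorded in the configuration.
#' @return A `magdb_fixture_manifest` list: the generation parameters, the
#'   headline counts (`n_genomes`, `n_contigs`, `n_genes`, `n_proteins`,
#'   `n_clusters`, `n_novel_genomes`), `novel_genomes`,
#'   `annotation_counts` per tool, `per_genome_gh5` distinct-protein
#'   counts, and `expected_tables` -- the post-ingest row count for each
#'   of the 28 tables. Also written to `manifest.json` in `out_dir`.
#' @export
#' @examples
#' \donttest{
#' dir <- tempfile()
#' m <- generate_project_fixture(dir, seed = 42)
#' m$n_genes
#' }
generate_project_fixture <- function(out_dir, seed = 42, n_genomes = 5,
                                     contigs_per_genome = 4,
                                     genes_per_contig = 6,
                                     novel_fraction = 0.4,
                                     cazyme_density = 0.2,
                                     project_name = "synthetic_project") {
  stopifnot(n_genomes >= 1, contigs_per_genome >= 1, genes_per_contig >= 1,
            novel_fraction >= 0, novel_fraction <= 1,
            cazyme_density >= 0, cazyme_density <= 1)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    magdb_abort(paste0("cannot create output directory: ", out_dir),
                "magdb_io_error")
  }
  for (d in c("bins", "gff", "proteins", "gtdbtk", "drep", "checkm2",
              "annotations")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  G <- as.integer(n_genomes)
  C <- as.integer(contigs_per_genome)
  K <- as.integer(genes_per_contig)
  genomes <- sprintf("bin_%02d", seq_len(G))
  gap <- 50L; tail_bp <- 150L

  # -- structural truth: contigs, genes, proteins ------------------------
  structure_tbl <- with_stream(seed, 1L, {
    purrr::map_dfr(seq_len(G), function(g) {
      purrr::map_dfr(seq_len(C), function(ci) {
        glen <- 3L * sample(60:160, K, replace = TRUE)
        starts <- integer(K); ends <- integer(K)
        pos <- gap
        for (k in seq_len(K)) {
          starts[k] <- pos + 1L
          ends[k] <- pos + glen[k]
          pos <- ends[k] + gap
        }
        tibble::tibble(
          genome = genomes[g], contig = sprintf("%s_c%d", genomes[g], ci),
          gene_idx = seq_len(K),
          gene_id = sprintf("%s_c%d_g%d", genomes[g], ci, seq_len(K)),
          start = starts, end = ends,
          strand = ifelse(seq_len(K) %% 2 == 1, "+", "-"),
          contig_len = ends[K] + tail_bp
        )
      })
    })
  })
  contig_tbl <- dplyr::distinct(structure_tbl, .data$genome, .data$contig,
                                .data$contig_len)
  n_proteins <- nrow(structure_tbl)
  structure_tbl$protein_len <- (structure_tbl$end - structure_tbl$start + 1L) %/% 3L
  structure_tbl$protein_idx <- seq_len(n_proteins)

  # -- sequences ---------------------------------------------------------
  contig_tbl$sequence <- with_stream(seed, 2L, {
    purrr::map_chr(contig_tbl$contig_len, random_string,
                   alphabet = c("A", "C", "G", "T"))
  })
  structure_tbl$protein_seq <- with_stream(seed, 3L, {
    purrr::map_chr(structure_tbl$protein_len,
                   function(n) paste0(random_string(n, AA20), "*"))
  })

  # -- taxonomy truth ----------------------------------------------------
  n_novel <- round(novel_fraction * G)
  novel <- with_stream(seed, 4L, sort(sample(seq_len(G), n_novel)))
  genera <- c("Roseburia", "Blautia")
  lineages <- purrr::map(seq_len(G), function(g) {
    genus <- genera[(g - 1) %% 2 + 1]
    c(domain = "Bacteria", phylum = "Bacillota", class = "Clostridia",
      order = "Lachnospirales", family = "Lachnospiraceae",
      genus = genus,
      species = if (g %in% novel) NA_character_
                else sprintf("%s synthetica%d", genus, g))
  })
  taxon_pairs <- unique(purrr::map_dfr(lineages, function(l) {
    tibble::tibble(rank = names(l)[!is.na(l)], name = l[!is.na(l)])
  }))

  # -- dereplication truth -----------------------------------------------
  cluster_of <- ceiling(seq_len(G) / 2)
  cluster_labels <- sprintf("%d_1", cluster_of)
  is_winner <- !duplicated(cluster_of)
  n_clusters <- length(unique(cluster_of))

  # -- quality truth -----------------------------------------------------
  quality <- with_stream(seed, 5L, tibble::tibble(
    genome = genomes,
    completeness = round(stats::runif(G, 90, 99.9), 2),
    contamination = round(stats::runif(G, 0, 5), 2)
  ))

  # -- dbCAN truth -------------------------------------------------------
  n_cazyme <- round(cazyme_density * n_proteins)
  cazyme_idx <- with_stream(seed, 6L,
                            sort(sample(seq_len(n_proteins), n_cazyme)))
  # Cycle through four consensus patterns; families per pattern below.
  dbcan_rows <- purrr::map_dfr(seq_along(cazyme_idx), function(i) {
    p <- structure_tbl[structure_tbl$protein_idx == cazyme_idx[i], ]
    pat <- (i - 1) %% 4
    span <- function(frac_lo, frac_hi) {
      c(max(1L, as.integer(p$protein_len * frac_lo)),
        max(2L, as.integer(p$protein_len * frac_hi)))
    }
    s1 <- span(0.1, 0.8)
    cons <- switch(as.character(pat),
      "0" = sprintf("GH5(%d-%d)", s1[1], s1[2]),
      "1" = "GH13",
      "2" = sprintf("GH5_2(%d-%d)", s1[1], s1[2]),
      "3" = {
        s2 <- span(0.05, 0.35); s3 <- span(0.45, 0.9)
        sprintf("CBM3(%d-%d)+AA9(%d-%d)", s2[1], s2[2], s3[1], s3[2])
      }
    )
    fams <- switch(as.character(pat),
      "0" = "GH5", "1" = "GH13", "2" = "GH5", "3" = c("CBM3", "AA9"))
    subfams <- if (pat == 2) "GH5_2" else character()
    tibble::tibble(
      protein = p$gene_id, genome = p$genome, consensus = cons,
      ntools = 2L + (i %% 2),
      families = list(fams), subfamilies = list(subfams)
    )
  })
  n_dbcan_ann <- if (nrow(dbcan_rows) == 0) 0L else {
    sum(lengths(dbcan_rows$families)) + sum(lengths(dbcan_rows$subfamilies))
  }
  gh5 <- dbcan_rows[purrr::map_lgl(dbcan_rows$families %||% list(),
                                   ~ "GH5" %in% .x), ]
  per_genome_gh5 <- if (nrow(gh5) == 0) {
    stats::setNames(integer(), character())
  } else {
    counts <- dplyr::count(dplyr::distinct(gh5, .data$genome, .data$protein),
                           .data$genome)
    stats::setNames(as.integer(counts$n), counts$genome)
  }

  # -- other annotation sources (fixed modular rules) --------------------
  ipr_idx <- seq(1, n_proteins, by = 10)
  clean_idx <- seq(1, n_proteins, by = 7)
  pinf_idx <- seq(1, n_proteins, by = 9)
  n_ipr_ann <- length(ipr_idx) * 4L  # signature + InterPro + 2 GO per line
  n_clean_ann <- length(clean_idx) * 2L
  n_pinf_ann <- length(pinf_idx) * 1L

  # -- write files -------------------------------------------------------
  wl <- function(lines, ...) writeLines(lines, file.path(out_dir, ...))
  for (g in seq_len(G)) {
    ct <- contig_tbl[contig_tbl$genome == genomes[g], ]
    write_fasta(
      tibble::tibble(id = ct$contig,
                     description = sprintf("length=%d", ct$contig_len),
                     sequence = ct$sequence),
      file.path(out_dir, "bins", paste0(genomes[g], ".fa"))
    )
    st <- structure_tbl[structure_tbl$genome == genomes[g], ]
    gff <- c("##gff-version 3")
    for (ci in unique(st$contig)) {
      sc <- st[st$contig == ci, ]
      gff <- c(gff, sprintf(
        "%s\tProdigal\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=hypothetical protein",
        ci, sc$start, sc$end, sc$strand, sc$gene_id
      ))
    }
    first_contig <- ct$contig[1]
    clen <- ct$contig_len[1]
    gff <- c(gff, sprintf(
      "%s\tAragorn\ttRNA\t%d\t%d\t.\t+\t.\tID=%s_trna1;product=tRNA-Ala",
      first_contig, clen - 100L, clen - 29L, genomes[g]
    ))
    gff <- c(gff, "##FASTA",
             unlist(purrr::map(seq_len(nrow(ct)), function(i) {
               c(paste0(">", ct$contig[i]),
                 substring(ct$sequence[i],
                           seq(1, nchar(ct$sequence[i]), 80),
                           pmin(seq(1, nchar(ct$sequence[i]), 80) + 79,
                                nchar(ct$sequence[i]))))
             })))
    wl(gff, "gff", paste0(genomes[g], ".gff"))
    write_fasta(
      tibble::tibble(id = st$gene_id,
                     description = "hypothetical protein",
                     sequence = st$protein_seq),
      file.path(out_dir, "proteins", paste0(genomes[g], ".faa"))
    )
  }

  wl(c("user_genome\tclassification",
       purrr::map_chr(seq_len(G), function(g) {
         l <- lineages[[g]]
         cls <- paste0(
           c("d__", "p__", "c__", "o__", "f__", "g__", "s__"),
           ifelse(is.na(l), "", l), collapse = ";"
         )
         paste0(genomes[g], "\t", cls)
       })),
     "gtdbtk", "summary.tsv")

  wl(c("genome,secondary_cluster",
       sprintf("%s.fa,%s", genomes, cluster_labels)),
     "drep", "Cdb.csv")
  wl(c("genome", sprintf("%s.fa", genomes[is_winner])), "drep", "Wdb.csv")

  wl(c("Name\tCompleteness\tContamination",
       sprintf("%s\t%.2f\t%.2f", quality$genome, quality$completeness,
               quality$contamination)),
     "checkm2", "quality_report.tsv")

  wl(c("Gene ID\tEC#\tHMMER\tdbCAN_sub\tDIAMOND\tRecommend Results\t#ofTools",
       if (nrow(dbcan_rows) > 0) {
         sprintf("%s\t-\t%s\t-\t%s\t%s\t%d",
                 dbcan_rows$protein, dbcan_rows$consensus,
                 dbcan_rows$consensus, dbcan_rows$consensus,
                 dbcan_rows$ntools)
       }),
     "annotations", "dbcan_overview.tsv")

  ipr_proteins <- structure_tbl$gene_id[ipr_idx]
  ipr_len <- structure_tbl$protein_len[ipr_idx]
  wl(sprintf(paste0(
       "%s\td41d8cd98f00b204e9800998ecf8427e\t%d\tPfam\tPF00150\t",
       "Cellulase (glycosyl hydrolase family 5)\t%d\t%d\t1.2e-50\tT\t",
       "01-01-2026\tIPR001547\tGlycoside hydrolase family 5\t",
       "GO:0004553|GO:0005975\t-"),
       ipr_proteins, ipr_len, pmax(1L, ipr_len %/% 10L),
       pmax(2L, (ipr_len * 9L) %/% 10L)),
     "annotations", "interproscan.tsv")

  wl(sprintf("%s,EC:3.2.1.4/0.8731;EC:3.2.1.91/0.1012",
             structure_tbl$gene_id[clean_idx]),
     "annotations", "clean.csv")

  wl(c("sequence_name\tpredicted_label\tconfidence",
       sprintf("%s\tGO:0016787\t0.97", structure_tbl$gene_id[pinf_idx])),
     "annotations", "proteinfer.tsv")

  # -- configuration -----------------------------------------------------
  config_lines <- c(
    "[project]",
    sprintf('name = "%s"', project_name),
    'samples = ["sample_01"]',
    "",
    "[options]",
    "strict = true",
    "batch_size = 1000",
    'database_target = "magdb.sqlite"',
    "",
    "[tools.bins]",
    'name = "metawrap"', 'version = "1.3.0"',
    "[tools.genes]",
    'name = "prokka"', 'version = "1.14.6"',
    "[tools.dereplication]",
    'name = "drep"', 'version = "3.4.5"',
    "[tools.taxonomy]",
    'name = "gtdbtk"', 'version = "2.3.2"',
    "[tools.quality]",
    'name = "checkm2"', 'version = "1.0.2"',
    "",
    "[[assemblies]]",
    'name = "assembly_01"',
    'bins_dir = "bins"',
    'gff_dir = "gff"',
    'proteins_dir = "proteins"',
    'gtdbtk_summary = "gtdbtk/summary.tsv"',
    'drep_cluster_table = "drep/Cdb.csv"',
    'drep_winners_table = "drep/Wdb.csv"',
    'checkm2_report = "checkm2/quality_report.tsv"',
    "",
    "[[assemblies.annotations]]",
    'plugin_name = "dbcan"',
    'path = "annotations/dbcan_overview.tsv"',
    "[[assemblies.annotations]]",
    'plugin_name = "interpro"',
    'path = "annotations/interproscan.tsv"',
    "[[assemblies.annotations]]",
    'plugin_name = "clean"',
    'path = "annotations/clean.csv"',
    "[[assemblies.annotations]]",
    'plugin_name = "proteinfer"',
    'path = "annotations/proteinfer.tsv"'
  )
  wl(config_lines, "project.toml")

  # -- manifest ----------------------------------------------------------
  n_plugins <- nrow(discover_plugins())
  ann_entries <- c(
    dbcan = nrow(dbcan_rows) + 1L,          # header + one line per protein
    interproscan = length(ipr_idx),          # headerless
    clean = length(clean_idx),
    proteinfer = length(pinf_idx) + 1L
  )
  expected_tables <- c(
    project = 1L, sample = 1L, assembly = 1L,
    tool = 5L + 4L,                          # 5 configured roles + 4 plugin tools
    source = 3L + 4L + 1L + 1L + 1L,         # dirs + annotation files + drep/gtdbtk/checkm2
    run = 10L,
    plugin_registration = n_plugins,
    fasta_file = 2L * G, fasta_entry = G * C + n_proteins,
    gff_file = G, gff_entry = G * (C * K + 1L),
    dereplication_file = 2L, dereplication_entry = G,
    taxonomy_file = 1L, taxonomy_entry = G,
    quality_file = 1L, quality_entry = G,
    protein_annotation_file = 4L,
    protein_annotation_entry = sum(ann_entries),
    genome = G, genome_cluster = n_clusters, contig = G * C,
    gene = n_proteins, protein = n_proteins,
    taxon = nrow(taxon_pairs), taxonomy_assignment = G,
    protein_annotation = n_dbcan_ann + n_ipr_ann + n_clean_ann + n_pinf_ann,
    genome_quality = G
  )
  manifest <- structure(
    list(
      seed = seed,
      params = list(
        n_genomes = G, contigs_per_genome = C, genes_per_contig = K,
        novel_fraction = novel_fraction, cazyme_density = cazyme_density
      ),
      project_name = project_name,
      n_genomes = G, n_contigs = G * C, n_genes = G * C * K,
      n_proteins = n_proteins, n_clusters = n_clusters,
      n_novel_genomes = n_novel,
      novel_genomes = genomes[novel],
      annotation_counts = list(
        dbcan = n_dbcan_ann, interproscan = n_ipr_ann,
        clean = n_clean_ann, proteinfer = n_pinf_ann
      ),
      per_genome_gh5 = as.list(per_genome_gh5),
      expected_tables = as.list(expected_tables)
    ),
    class = "magdb_fixture_manifest"
  )
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' @export
print.magdb_fixture_manifest <- function(x, ...) {
  cat("Synthetic project '", x$project_name, "' (seed ", x$seed, ")\n",
      sep = "")
  cat(sprintf("  %d genomes, %d contigs, %d genes/proteins, %d clusters, %d novel\n",
              x$n_genomes, x$n_contigs, x$n_genes, x$n_clusters,
              x$n_novel_genomes))
  cat("  expected total rows:", sum(unlist(x$expected_tables)), "\n")
  invisible(x)
}
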