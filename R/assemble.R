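# Assembly of biological entities from already-ingested file entities,
# resolving cross-file identifiers into foreign keys in dependency order:
# genomes/contigs -> genes -> proteins -> annotations/clusters/taxonomy/
# quality. Parents are always inserted before children, so an interrupted
# stage never leaves orphan references.

link_report <- function(stage, created, linked = sum(created),
                        unmatched_keys = character()) {
  structure(
    list(stage = stage, created = created, linked = linked,
         unmatched_keys = unmatched_keys),
    class = "magdb_link_report"
  )
}

#' @export
print.magdb_link_report <- function(x, ...) {
  cat("Stage", x$stage, "- created:",
      paste(names(x$created), x$created, collapse = ", "),
      "| linked:", x$linked, "\n")
  if (length(x$unmatched_keys) > 0) {
    cat("  unmatched keys:", paste(x$unmatched_keys, collapse = ", "), "\n")
  }
  invisible(x)
}

db_tbl <- function(db, sql, params = NULL) {
  res <- if (is.null(params) || length(params) == 0) {
    DBI::dbGetQuery(db_con(db), sql)
  } else {
    DBI::dbGetQuery(db_con(db), sql, params = params)
  }
  tibble::as_tibble(res)
}

assembly_genomes <- function(db, assembly_id) {
  db_tbl(db, "SELECT genome_id, name, fasta_file_id FROM genome
              WHERE assembly_id = ?", params = list(assembly_id))
}

assembly_contigs <- function(db, assembly_id) {
  db_tbl(db, "SELECT c.contig_id, c.genome_id, c.name, c.length_bp
              FROM contig c JOIN genome g ON c.genome_id = g.genome_id
              WHERE g.assembly_id = ?", params = list(assembly_id))
}

assembly_genes <- function(db, assembly_id) {
  db_tbl(db, "SELECT ge.gene_id, ge.identifier, c.genome_id
              FROM gene ge
              JOIN contig c ON ge.contig_id = c.contig_id
              JOIN genome g ON c.genome_id = g.genome_id
              WHERE g.assembly_id = ?", params = list(assembly_id))
}

assembly_proteins <- function(db, assembly_id) {
  db_tbl(db, "SELECT p.protein_id, p.name, c.genome_id
              FROM protein p
              JOIN gene ge ON p.gene_id = ge.gene_id
              JOIN contig c ON ge.contig_id = c.contig_id
              JOIN genome g ON c.genome_id = g.genome_id
              WHERE g.assembly_id = ?", params = list(assembly_id))
}

require_stage <- function(ok, stage, needed) {
  if (!ok) {
    magdb_abort(
      sprintf("cannot run stage '%s': prerequisite stage '%s' has not run",
              stage, needed),
      "magdb_stage_order_error"
    )
  }
}

unmatched_or_abort <- function(keys, what, strict) {
  if (length(keys) == 0) return(character())
  if (strict) {
    magdb_abort(
      sprintf("unresolved reference(s) for %s: %s", what,
              paste(unique(keys), collapse = ", ")),
      "magdb_unresolved_reference"
    )
  }
  unique(keys)
}

#' Assemble genome and contig entities from ingested bin FASTA files
#'
#' One genome per bin FASTA file (name = normalized file stem) and one
#' contig per FASTA record, with `length_bp` taken from the stored
#' sequence.
#'
#' @param db A `magdb` connection.
#' @param assembly_id Surrogate key of the assembly.
#' @param fasta_file_ids Ids of the bin `fasta_file` rows to assemble; by
#'   default every `file_kind = "bin"` file of the assembly's project.
#' @param cache Natural-key cache ([magdb_cache()]).
#' @param strict Abort on any unresolved key (default) instead of
#'   recording it.
#' @param batch_size Rows per insert transaction.
#' @return A `magdb_link_report`.
#' @export
assemble_genomes_and_contigs <- function(db, assembly_id,
                                         fasta_file_ids = NULL,
                                         cache = NULL, strict = TRUE,
                                         batch_size = 1000) {
  if (is.null(cache)) cache <- magdb_cache()
  if (is.null(fasta_file_ids)) {
    files <- db_tbl(db,
      "SELECT f.fasta_file_id, f.path FROM fasta_file f
       JOIN run r ON f.run_id = r.run_id
       JOIN assembly a ON a.project_id = r.project_id
       WHERE a.assembly_id = ? AND f.file_kind = 'bin'",
      params = list(assembly_id))
  } else {
    files <- db_tbl(db, sprintf(
      "SELECT fasta_file_id, path FROM fasta_file WHERE fasta_file_id IN (%s)",
      paste(as.integer(fasta_file_ids), collapse = ", ")))
  }
  require_stage(nrow(files) > 0, "genomes_contigs", "bin FASTA ingestion")
  files$genome_name <- normalize_genome_name(files$path)
  dup <- files$genome_name[duplicated(files$genome_name)]
  if (length(dup) > 0) {
    magdb_abort(
      paste0("two bin files normalize to the same genome name: ",
             paste(unique(dup), collapse = ", ")),
      "magdb_duplicate_genome"
    )
  }
  genomes <- tibble::tibble(
    assembly_id = assembly_id, name = files$genome_name,
    genome_cluster_id = NA_integer_, fasta_file_id = files$fasta_file_id
  )
  gout <- insert_if_absent(db, "genome", genomes, cache, batch_size)
  files$genome_id <- gout$id

  entries <- db_tbl(db, sprintf(
    "SELECT fasta_entry_id, fasta_file_id, record_id, sequence
     FROM fasta_entry WHERE fasta_file_id IN (%s)",
    paste(files$fasta_file_id, collapse = ", ")))
  empty_files <- setdiff(files$fasta_file_id, entries$fasta_file_id)
  if (length(empty_files) > 0) {
    warning(sprintf("%d bin file(s) contain no FASTA records; genomes created with 0 contigs",
                    length(empty_files)), call. = FALSE)
  }
  n_contigs <- 0L
  if (nrow(entries) > 0) {
    entries <- dplyr::left_join(
      entries, files[, c("fasta_file_id", "genome_id")], by = "fasta_file_id"
    )
    contigs <- tibble::tibble(
      genome_id = entries$genome_id, name = entries$record_id,
      length_bp = nchar(entries$sequence),
      fasta_entry_id = entries$fasta_entry_id
    )
    cout <- insert_if_absent(db, "contig", contigs, cache, batch_size)
    n_contigs <- sum(cout$outcome == "inserted")
  }
  link_report(
    "genomes_contigs",
    c(genome = sum(gout$outcome == "inserted"), contig = n_contigs)
  )
}

#' Assemble gene entities from ingested GFF features
#'
#' Promotes every CDS feature to a gene, linked to the contig whose name
#' matches the feature's seqid within the genome named by the GFF file's
#' stem. The gene identifier is the GFF `ID` attribute, falling back to
#' `locus_tag`. Other feature types (tRNA, rRNA, ...) stay as file
#' entities.
#'
#' @inheritParams assemble_genomes_and_contigs
#' @param gff_file_ids Ids of `gff_file` rows to assemble; by default every
#'   GFF file of the assembly's project.
#' @return A `magdb_link_report`.
#' @export
assemble_genes <- function(db, assembly_id, gff_file_ids = NULL,
                           cache = NULL, strict = TRUE, batch_size = 1000) {
  if (is.null(cache)) cache <- magdb_cache()
  genomes <- assembly_genomes(db, assembly_id)
  require_stage(nrow(genomes) > 0, "genes", "genomes_contigs")
  if (is.null(gff_file_ids)) {
    gff_files <- db_tbl(db,
      "SELECT f.gff_file_id, f.path FROM gff_file f
       JOIN run r ON f.run_id = r.run_id
       JOIN assembly a ON a.project_id = r.project_id
       WHERE a.assembly_id = ?", params = list(assembly_id))
  } else {
    gff_files <- db_tbl(db, sprintf(
      "SELECT gff_file_id, path FROM gff_file WHERE gff_file_id IN (%s)",
      paste(as.integer(gff_file_ids), collapse = ", ")))
  }
  require_stage(nrow(gff_files) > 0, "genes", "GFF ingestion")
  contigs <- assembly_contigs(db, assembly_id)
  contig_key <- stats::setNames(contigs$contig_id,
                                paste(contigs$genome_id, contigs$name))
  contig_len <- stats::setNames(contigs$length_bp,
                                paste(contigs$genome_id, contigs$name))
  genome_key <- stats::setNames(genomes$genome_id, genomes$name)

  unmatched <- character()
  records <- list()
  for (i in seq_len(nrow(gff_files))) {
    gname <- sub("\\.gff3?$", "", basename(gff_files$path[i]))
    gid <- unname(genome_key[gname])
    if (is.na(gid)) {
      unmatched <- c(unmatched, gname)
      next
    }
    feats <- db_tbl(db,
      "SELECT gff_entry_id, seqid, start, \"end\", strand, attributes
       FROM gff_entry WHERE gff_file_id = ? AND feature_type = 'CDS'",
      params = list(gff_files$gff_file_id[i]))
    for (j in seq_len(nrow(feats))) {
      attrs <- parse_gff_attributes(feats$attributes[j])
      identifier <- attrs[["ID"]] %||% attrs[["locus_tag"]] %||% NULL
      if (is.null(identifier)) {
        magdb_abort(
          sprintf("CDS feature (gff_entry %d) lacks both ID and locus_tag",
                  feats$gff_entry_id[j]),
          "magdb_missing_identifier"
        )
      }
      ck <- paste(gid, feats$seqid[j])
      contig_id <- unname(contig_key[ck])
      if (is.na(contig_id)) {
        unmatched <- c(unmatched, feats$seqid[j])
        next
      }
      if (feats$end[j] > contig_len[[ck]]) {
        magdb_abort(
          sprintf("gene '%s' ends at %d beyond contig '%s' length %d",
                  identifier, feats$end[j], feats$seqid[j], contig_len[[ck]]),
          "magdb_validation_error"
        )
      }
      records[[length(records) + 1]] <- list(
        contig_id = contig_id, identifier = identifier,
        start_1based = feats$start[j], end_1based = feats$end[j],
        strand = feats$strand[j], gff_entry_id = feats$gff_entry_id[j]
      )
    }
  }
  unmatched <- unmatched_or_abort(unmatched, "gene contigs (seqid)", strict)
  n <- 0L
  if (length(records) > 0) {
    out <- insert_if_absent(db, "gene", dplyr::bind_rows(purrr::map(records, tibble::as_tibble)),
                            cache, batch_size)
    n <- sum(out$outcome == "inserted")
  }
  link_report("genes", c(gene = n), linked = length(records),
              unmatched_keys = unmatched)
}

#' Assemble protein entities from ingested protein FASTA files
#'
#' One protein per protein-FASTA record whose id equals a gene identifier
#' in the same genome (matched by the protein file's stem). The stored
#' length excludes a trailing `*` stop mark.
#'
#' @inheritParams assemble_genomes_and_contigs
#' @param fasta_file_ids Ids of the protein `fasta_file` rows; by default
#'   every `file_kind = "protein"` file of the assembly's project.
#' @return A `magdb_link_report`.
#' @export
assemble_proteins <- function(db, assembly_id, fasta_file_ids = NULL,
                              cache = NULL, strict = TRUE, batch_size = 1000) {
  if (is.null(cache)) cache <- magdb_cache()
  genes <- assembly_genes(db, assembly_id)
  require_stage(nrow(genes) > 0, "proteins", "genes")
  genomes <- assembly_genomes(db, assembly_id)
  genome_key <- stats::setNames(genomes$genome_id, genomes$name)
  if (is.null(fasta_file_ids)) {
    files <- db_tbl(db,
      "SELECT f.fasta_file_id, f.path FROM fasta_file f
       JOIN run r ON f.run_id = r.run_id
       JOIN assembly a ON a.project_id = r.project_id
       WHERE a.assembly_id = ? AND f.file_kind = 'protein'",
      params = list(assembly_id))
  } else {
    files <- db_tbl(db, sprintf(
      "SELECT fasta_file_id, path FROM fasta_file WHERE fasta_file_id IN (%s)",
      paste(as.integer(fasta_file_ids), collapse = ", ")))
  }
  require_stage(nrow(files) > 0, "proteins", "protein FASTA ingestion")
  gene_key <- stats::setNames(genes$gene_id,
                              paste(genes$genome_id, genes$identifier))
  unmatched <- character()
  records <- list()
  claimed <- new.env(parent = emptyenv())  # gene_id -> protein name, this stage
  for (i in seq_len(nrow(files))) {
    gname <- sub("\\.faa$", "", normalize_genome_name(files$path[i]))
    gid <- unname(genome_key[gname])
    if (is.na(gid)) {
      unmatched <- c(unmatched, gname)
      next
    }
    entries <- db_tbl(db,
      "SELECT fasta_entry_id, record_id, sequence FROM fasta_entry
       WHERE fasta_file_id = ?", params = list(files$fasta_file_id[i]))
    for (j in seq_len(nrow(entries))) {
      gene_id <- unname(gene_key[paste(gid, entries$record_id[j])])
      if (is.na(gene_id)) {
        unmatched <- c(unmatched, entries$record_id[j])
        next
      }
      prev <- claimed[[as.character(gene_id)]]
      if (!is.null(prev) && prev != entries$record_id[j]) {
        magdb_abort(
          sprintf("two protein records ('%s', '%s') map to one gene",
                  prev, entries$record_id[j]),
          "magdb_uniqueness_error"
        )
      }
      claimed[[as.character(gene_id)]] <- entries$record_id[j]
      aa <- sub("\\*$", "", entries$sequence[j])
      records[[length(records) + 1]] <- list(
        gene_id = gene_id, name = entries$record_id[j],
        sequence_length_aa = nchar(aa),
        fasta_entry_id = entries$fasta_entry_id[j]
      )
    }
  }
  unmatched <- unmatched_or_abort(unmatched, "protein genes", strict)
  n <- 0L
  if (length(records) > 0) {
    out <- insert_if_absent(db, "protein",
                            dplyr::bind_rows(purrr::map(records, tibble::as_tibble)),
                            cache, batch_size)
    n <- sum(out$outcome == "inserted")
  }
  link_report("proteins", c(protein = n), linked = length(records),
              unmatched_keys = unmatched)
}

#' Link unified annotations to protein entities
#'
#' Each annotation whose `protein_key` matches a protein name in the
#' assembly becomes one `protein_annotation` row, deduplicated by the
#' record's natural key (protein, tool, type, accession, coordinates).
#'
#' @inheritParams assemble_genomes_and_contigs
#' @param annotations Tibble of unified annotations
#'   ([unified_annotation()]) carrying a `protein_annotation_entry_id`
#'   column pointing at the file-entity row each record came from.
#' @return A `magdb_link_report`.
#' @export
link_protein_annotations <- function(db, assembly_id, annotations,
                                     cache = NULL, strict = TRUE,
                                     batch_size = 1000) {
  if (is.null(cache)) cache <- magdb_cache()
  proteins <- assembly_proteins(db, assembly_id)
  require_stage(nrow(proteins) > 0, "protein_annotations", "proteins")
  if (!"protein_annotation_entry_id" %in% names(annotations)) {
    magdb_abort(
      "annotations must carry a protein_annotation_entry_id column",
      "magdb_validation_error"
    )
  }
  if (nrow(annotations) == 0) {
    return(link_report("protein_annotations", c(protein_annotation = 0L),
                       linked = 0L))
  }
  validate_annotations(annotations)
  protein_key <- stats::setNames(proteins$protein_id, proteins$name)
  hit <- annotations$protein_key %in% names(protein_key)
  unmatched <- unmatched_or_abort(annotations$protein_key[!hit],
                                  "annotation proteins", strict)
  matched <- annotations[hit, , drop = FALSE]
  n <- 0L
  if (nrow(matched) > 0) {
    rows <- tibble::tibble(
      protein_id = unname(protein_key[matched$protein_key]),
      protein_annotation_entry_id = matched$protein_annotation_entry_id,
      source_tool = matched$source_tool,
      annotation_type = matched$annotation_type,
      accession = matched$accession,
      description = matched$description,
      score = matched$score,
      coord_start = matched$coord_start,
      coord_stop = matched$coord_stop
    )
    out <- insert_if_absent(db, "protein_annotation", rows, cache, batch_size)
    n <- sum(out$outcome == "inserted")
  }
  link_report("protein_annotations", c(protein_annotation = n),
              linked = nrow(matched), unmatched_keys = unmatched)
}

#' Assemble genome clusters from dRep rows
#'
#' One `genome_cluster` row per distinct cluster label; every named
#' genome's `genome_cluster_id` is set and the winner (representative)
#' genome is recorded on its cluster.
#'
#' @inheritParams assemble_genomes_and_contigs
#' @param cluster_rows Tibble from [parse_drep_tables()].
#' @return A `magdb_link_report`.
#' @export
assemble_clusters <- function(db, assembly_id, cluster_rows,
                              cache = NULL, strict = TRUE, batch_size = 1000) {
  if (is.null(cache)) cache <- magdb_cache()
  genomes <- assembly_genomes(db, assembly_id)
  require_stage(nrow(genomes) > 0, "clusters", "genomes_contigs")
  if (nrow(cluster_rows) == 0) {
    return(link_report("clusters", c(genome_cluster = 0L), linked = 0L))
  }
  genome_key <- stats::setNames(genomes$genome_id, genomes$name)
  hit <- cluster_rows$genome_name %in% names(genome_key)
  unmatched <- unmatched_or_abort(cluster_rows$genome_name[!hit],
                                  "cluster genomes", strict)
  rows <- cluster_rows[hit, , drop = FALSE]
  labels <- unique(rows$cluster_label)
  cl <- insert_if_absent(
    db, "genome_cluster",
    tibble::tibble(assembly_id = assembly_id, label = labels,
                   representative_genome_id = NA_integer_),
    cache, batch_size
  )
  label_key <- stats::setNames(cl$id, labels)
  con <- db_con(db)
  for (i in seq_len(nrow(rows))) {
    gid <- genome_key[[rows$genome_name[i]]]
    cid <- label_key[[rows$cluster_label[i]]]
    DBI::dbExecute(con,
      "UPDATE genome SET genome_cluster_id = ? WHERE genome_id = ?",
      params = list(cid, gid))
    if (isTRUE(rows$is_winner[i])) {
      DBI::dbExecute(con,
        "UPDATE genome_cluster SET representative_genome_id = ? WHERE genome_cluster_id = ?",
        params = list(gid, cid))
    }
  }
  link_report("clusters",
              c(genome_cluster = sum(cl$outcome == "inserted")),
              linked = nrow(rows), unmatched_keys = unmatched)
}

#' Assemble taxonomy entities from GTDB-Tk rows
#'
#' Creates or reuses a `taxon` row for every assigned rank (unique on
#' rank + name, parent chain wired to the immediately higher rank) and one
#' `taxonomy_assignment` per genome, pointing at its most specific
#' assigned taxon and carrying the novelty flag.
#'
#' @inheritParams assemble_genomes_and_contigs
#' @param taxonomy_rows Tibble from [parse_gtdbtk_summary()], with a
#'   `taxonomy_entry_id` column pointing at the ingested file rows.
#' @return A `magdb_link_report`.
#' @export
assemble_taxonomy <- function(db, assembly_id, taxonomy_rows,
                              cache = NULL, strict = TRUE, batch_size = 1000) {
  if (is.null(cache)) cache <- magdb_cache()
  genomes <- assembly_genomes(db, assembly_id)
  require_stage(nrow(genomes) > 0, "taxonomy", "genomes_contigs")
  if (nrow(taxonomy_rows) == 0) {
    return(link_report("taxonomy", c(taxon = 0L, taxonomy_assignment = 0L),
                       linked = 0L))
  }
  if (!"taxonomy_entry_id" %in% names(taxonomy_rows)) {
    magdb_abort("taxonomy_rows must carry a taxonomy_entry_id column",
                "magdb_validation_error")
  }
  genome_key <- stats::setNames(genomes$genome_id, genomes$name)
  ranks <- taxonomic_ranks()
  names_norm <- normalize_genome_name(taxonomy_rows$user_genome)
  hit <- names_norm %in% names(genome_key)
  unmatched <- unmatched_or_abort(taxonomy_rows$user_genome[!hit],
                                  "taxonomy genomes", strict)
  n_taxa <- 0L
  assignments <- list()
  for (i in which(hit)) {
    lineage <- taxonomy_rows$lineage[[i]]
    last_taxon_id <- NA_integer_
    prev_assigned <- FALSE
    for (r in seq_along(ranks)) {
      nm <- lineage[[ranks[r]]]
      if (is.na(nm)) {
        prev_assigned <- FALSE
        next
      }
      parent_id <- if (prev_assigned) last_taxon_id else NA_integer_
      out <- insert_if_absent(
        db, "taxon",
        tibble::tibble(rank = ranks[r], name = nm, parent_id = parent_id),
        cache, batch_size
      )
      n_taxa <- n_taxa + sum(out$outcome == "inserted")
      last_taxon_id <- out$id[1]
      prev_assigned <- TRUE
    }
    most_specific <- if (is.na(taxonomy_rows$lowest_assigned_rank[i])) {
      NA_integer_
    } else {
      last_taxon_id
    }
    assignments[[length(assignments) + 1]] <- tibble::tibble(
      genome_id = genome_key[[names_norm[i]]],
      taxon_id = most_specific,
      lowest_assigned_rank = taxonomy_rows$lowest_assigned_rank[i],
      is_novel_species = taxonomy_rows$is_novel_species[i],
      taxonomy_entry_id = taxonomy_rows$taxonomy_entry_id[i]
    )
  }
  n_assign <- 0L
  if (length(assignments) > 0) {
    out <- insert_if_absent(db, "taxonomy_assignment",
                            dplyr::bind_rows(assignments), cache, batch_size)
    n_assign <- sum(out$outcome == "inserted")
  }
  link_report("taxonomy",
              c(taxon = n_taxa, taxonomy_assignment = n_assign),
              linked = length(assignments), unmatched_keys = unmatched)
}

#' Assemble genome quality entities from CheckM2 rows
#'
#' @inheritParams assemble_genomes_and_contigs
#' @param quality_rows Tibble from [parse_checkm2_report()], with a
#'   `quality_entry_id` column pointing at the ingested file rows.
#' @return A `magdb_link_report`.
#' @export
assemble_quality <- function(db, assembly_id, quality_rows,
                             cache = NULL, strict = TRUE, batch_size = 1000) {
  if (is.null(cache)) cache <- magdb_cache()
  genomes <- assembly_genomes(db, assembly_id)
  require_stage(nrow(genomes) > 0, "quality", "genomes_contigs")
  if (nrow(quality_rows) == 0) {
    return(link_report("quality", c(genome_quality = 0L), linked = 0L))
  }
  if (!"quality_entry_id" %in% names(quality_rows)) {
    magdb_abort("quality_rows must carry a quality_entry_id column",
                "magdb_validation_error")
  }
  genome_key <- stats::setNames(genomes$genome_id, genomes$name)
  names_norm <- normalize_genome_name(quality_rows$genome_name)
  hit <- names_norm %in% names(genome_key)
  unmatched <- unmatched_or_abort(quality_rows$genome_name[!hit],
                                  "quality genomes", strict)
  rows <- tibble::tibble(
    genome_id = unname(genome_key[names_norm[hit]]),
    completeness_pct = quality_rows$completeness_pct[hit],
    contamination_pct = quality_rows$contamination_pct[hit],
    quality_entry_id = quality_rows$quality_entry_id[hit]
  )
  n <- 0L
  if (nrow(rows) > 0) {
    out <- insert_if_absent(db, "genome_quality", rows, cache, batch_size)
    n <- sum(out$outcome == "inserted")
  }
  link_report("quality", c(genome_quality = n), linked = nrow(rows),
              unmatched_keys = unmatched)
}
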