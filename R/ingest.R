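# Configuration loading and the end-to-end population pipeline: file
# ingestion, run/tool/source bookkeeping, entity assembly in fixed stage
# order, with checksum audit. Population is idempotent end to end.

#' SHA-256 digest of a file
#'
#' @param path Path to a readable file.
#' @return Lower-case hex digest of the file's bytes.
#' @export
#' @examples
#' f <- tempfile(); file.create(f)
#' file_checksum(f)  # digest of empty input
file_checksum <- function(path) {
  check_readable(path)
  digest::digest(path, algo = "sha256", file = TRUE)
}

config_abort <- function(key, why) {
  magdb_abort(sprintf("configuration key '%s': %s", key, why),
              "magdb_config_error")
}

resolve_path <- function(p, config_dir, key) {
  full <- if (grepl("^/", p)) p else file.path(config_dir, p)
  if (!file.exists(full)) config_abort(key, paste0("path does not exist: ", p))
  normalizePath(full)
}

#' Load and validate a project configuration
#'
#' Reads the TOML configuration that drives population: the project name,
#' one or more assemblies (bin/GFF/protein directories plus optional
#' GTDB-Tk, dRep, CheckM2 and plugin annotation inputs), optional upstream
#' tool names/versions, and options. Relative paths are resolved against
#' the configuration file's directory and must exist at load time; every
#' named plugin must be discovered and enabled.
#'
#' @param path Path to a TOML configuration file.
#' @return A validated `magdb_config` list with defaults applied
#'   (`strict = TRUE`, `batch_size = 1000`).
#' @export
load_config <- function(path) {
  check_readable(path)
  raw <- tryCatch(RcppTOML::parseTOML(path),
                  error = function(e) {
                    magdb_abort(paste0("not valid TOML: ", conditionMessage(e)),
                                "magdb_config_error")
                  })
  config_dir <- dirname(normalizePath(path))
  project <- raw$project
  if (is.null(project$name) || !nzchar(project$name)) {
    config_abort("project.name", "must be a non-empty string")
  }
  options <- raw$options %||% list()
  options$strict <- options$strict %||% TRUE
  options$batch_size <- as.integer(options$batch_size %||% 1000L)
  if (is.na(options$batch_size) || options$batch_size < 1) {
    config_abort("options.batch_size", "must be a positive integer")
  }
  options$database_target <- options$database_target %||%
    file.path(config_dir, "magdb.sqlite")
  if (!grepl("^/", options$database_target) &&
      options$database_target != ":memory:") {
    options$database_target <- file.path(config_dir, options$database_target)
  }

  disabled <- raw$plugins$disabled %||% character()
  for (nm in disabled) plugin_set_enabled(nm, FALSE)
  descriptors <- discover_plugins()

  assemblies <- raw$assemblies
  if (is.null(assemblies) || length(assemblies) == 0) {
    config_abort("assemblies", "at least one assembly is required")
  }
  assemblies <- lapply(seq_along(assemblies), function(i) {
    a <- assemblies[[i]]
    keybase <- sprintf("assemblies[%s]", i)
    if (is.null(a$name) || !nzchar(a$name)) {
      config_abort(paste0(keybase, ".name"), "must be a non-empty string")
    }
    if (is.null(a$bins_dir)) {
      config_abort(paste0(keybase, ".bins_dir"), "is required")
    }
    out <- list(name = a$name)
    dirs <- c("bins_dir", "gff_dir", "proteins_dir")
    opt_files <- c("gtdbtk_summary", "drep_cluster_table",
                   "drep_winners_table", "checkm2_report")
    for (k in c(dirs, opt_files)) {
      if (!is.null(a[[k]])) {
        out[[k]] <- resolve_path(a[[k]], config_dir, paste0(keybase, ".", k))
        out[[paste0(k, "_label")]] <- a[[k]]
      }
    }
    anns <- a$annotations %||% list()
    out$annotations <- lapply(seq_along(anns), function(j) {
      ann <- anns[[j]]
      akey <- sprintf("%s.annotations[%s]", keybase, j)
      if (is.null(ann$plugin_name)) {
        config_abort(paste0(akey, ".plugin_name"), "is required")
      }
      hit <- descriptors[descriptors$name == ann$plugin_name, ]
      if (nrow(hit) == 0) {
        config_abort(paste0(akey, ".plugin_name"),
                     paste0("unknown plugin '", ann$plugin_name, "'"))
      }
      if (!hit$enabled) {
        config_abort(paste0(akey, ".plugin_name"),
                     paste0("plugin '", ann$plugin_name, "' is disabled"))
      }
      if (is.null(ann$path)) config_abort(paste0(akey, ".path"), "is required")
      list(
        plugin_name = ann$plugin_name,
        path = resolve_path(ann$path, config_dir, paste0(akey, ".path")),
        label = ann$path
      )
    })
    out
  })

  tools <- raw$tools %||% list()
  structure(
    list(
      project_name = project$name,
      samples = as.character(project$samples %||% character()),
      options = options,
      tools = tools,
      plugins_disabled = as.character(disabled),
      assemblies = assemblies,
      config_dir = config_dir
    ),
    class = "magdb_config"
  )
}

# Tool identity for a pipeline role ("bins", "genes", "dereplication",
# "taxonomy", "quality"): taken from the config when supplied, otherwise
# recorded as unknown.
role_tool <- function(config, role) {
  t <- config$tools[[role]]
  list(name = t$name %||% "unknown", version = t$version %||% "unknown")
}

populate_stages <- function() {
  c("bins", "genomes_contigs", "gff", "genes", "proteins", "annotations",
    "clusters", "taxonomy", "quality")
}

#' Populate the database from a validated configuration
#'
#' Executes, per assembly and in fixed order: ingest bin FASTA and GFF
#' file entities, assemble genomes/contigs, genes and proteins, run the
#' enabled annotation plugins and link their records, then clusters,
#' taxonomy and quality. One `run` row is recorded per (tool, input
#' source). The whole pipeline is idempotent: a second call over the same
#' configuration changes no row counts.
#'
#' @param config A `magdb_config` from [load_config()].
#' @param db Optional open `magdb` connection; by default the
#'   configuration's `database_target` is opened (and closed again).
#' @param fail_after_stage Internal testing hook: abort after the named
#'   stage (see `populate_stages`) completes, leaving a partial but
#'   referentially closed database.
#' @return A `magdb_ingest_report`: per-stage link reports, a per-file
#'   audit (path, SHA-256 digest, rows ingested) and timestamps.
#' @export
populate <- function(config, db = NULL, fail_after_stage = NULL) {
  stopifnot(inherits(config, "magdb_config"))
  own_db <- is.null(db)
  if (own_db) {
    db <- magdb_connect(config$options$database_target)
    on.exit(magdb_disconnect(db), add = TRUE)
  }
  initialize_schema(db)
  cache <- magdb_cache()
  strict <- isTRUE(config$options$strict)
  batch <- config$options$batch_size
  started_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  audit <- list()
  stages <- list()

  maybe_fail <- function(stage) {
    if (!is.null(fail_after_stage) && identical(stage, fail_after_stage)) {
      magdb_abort(paste0("injected failure after stage '", stage, "'"),
                  "magdb_injected_failure")
    }
  }

  ins1 <- function(table, record) {
    insert_if_absent(db, table, tibble::as_tibble(record), cache, batch)$id[1]
  }

  project_id <- ins1("project", list(name = config$project_name))
  for (s in config$samples) {
    ins1("sample", list(project_id = project_id, name = s))
  }
  # Register every discovered plugin with its current enabled state.
  desc <- discover_plugins()
  for (i in seq_len(nrow(desc))) {
    ins1("plugin_registration", list(
      name = desc$name[i], target_tool = desc$target_tool[i],
      version = desc$version[i], enabled = desc$enabled[i]
    ))
  }

  new_run <- function(role_or_tool, source_label) {
    tool <- if (is.list(role_or_tool)) role_or_tool else role_tool(config, role_or_tool)
    tool_id <- ins1("tool", list(name = tool$name, version = tool$version))
    source_id <- ins1("source", list(label = source_label))
    ins1("run", list(project_id = project_id, tool_id = tool_id,
                     source_id = source_id, started_at = started_at))
  }

  # Ingest one physical file as a file-entity row, auditing its digest.
  # A path already present with a different digest is treated as a new
  # file version, which v1 refuses in strict mode.
  ingest_file <- function(table, run_id, path, extra = list(), rows = 0L) {
    sha <- file_checksum(path)
    existing <- db_tbl(db, sprintf(
      "SELECT %s AS id, sha256 FROM %s WHERE path = ?",
      quote_id(magdb_schema()[[table]]$pk), quote_id(table)),
      params = list(path))
    if (nrow(existing) > 0 && existing$sha256[1] != sha) {
      if (strict) {
        magdb_abort(
          paste0("file changed on disk since first ingest: ", path),
          "magdb_file_changed"
        )
      }
      warning(paste0("file changed on disk, keeping first version: ", path),
              call. = FALSE)
    }
    id <- ins1(table, c(list(run_id = run_id, path = path, sha256 = sha), extra))
    audit[[length(audit) + 1]] <<- tibble::tibble(
      path = path, sha256 = sha, rows_ingested = rows
    )
    id
  }

  for (assembly in config$assemblies) {
    assembly_id <- ins1("assembly",
                        list(project_id = project_id, name = assembly$name))

    # -- stage: bin FASTA ingestion ------------------------------------
    bin_paths <- sort(list.files(assembly$bins_dir, "\\.(fa|fasta|fna)$",
                                 full.names = TRUE, ignore.case = TRUE))
    if (length(bin_paths) == 0) {
      magdb_abort(paste0("no bin FASTA files in ", assembly$bins_dir),
                  "magdb_config_error")
    }
    bins_run <- new_run("bins", assembly$bins_dir_label %||% assembly$bins_dir)
    bin_file_ids <- integer()
    for (p in bin_paths) {
      recs <- read_fasta(p)
      fid <- ingest_file("fasta_file", bins_run, p,
                         list(file_kind = "bin"), nrow(recs))
      if (nrow(recs) > 0) {
        insert_if_absent(db, "fasta_entry", tibble::tibble(
          fasta_file_id = fid, record_id = recs$id,
          description = dplyr::na_if(recs$description, ""),
          sequence = recs$sequence
        ), cache, batch)
      }
      bin_file_ids <- c(bin_file_ids, fid)
    }
    maybe_fail("bins")

    stages[[length(stages) + 1]] <- assemble_genomes_and_contigs(
      db, assembly_id, fasta_file_ids = bin_file_ids,
      cache = cache, strict = strict, batch_size = batch
    )
    maybe_fail("genomes_contigs")

    # -- stage: GFF ingestion + genes ----------------------------------
    gff_file_ids <- integer()
    if (!is.null(assembly$gff_dir)) {
      gff_paths <- sort(list.files(assembly$gff_dir, "\\.gff3?$",
                                   full.names = TRUE, ignore.case = TRUE))
      gff_run <- new_run("genes", assembly$gff_dir_label %||% assembly$gff_dir)
      for (p in gff_paths) {
        feats <- read_gff3(p)
        fid <- ingest_file("gff_file", gff_run, p, rows = nrow(feats))
        if (nrow(feats) > 0) {
          insert_if_absent(db, "gff_entry", tibble::tibble(
            gff_file_id = fid, line_number = feats$line_number,
            seqid = feats$seqid, source = feats$source,
            feature_type = feats$feature_type,
            start = feats$start, end = feats$end, score = feats$score,
            strand = feats$strand, frame = feats$frame,
            attributes = feats$attributes_text
          ), cache, batch)
        }
        gff_file_ids <- c(gff_file_ids, fid)
      }
      maybe_fail("gff")
      stages[[length(stages) + 1]] <- assemble_genes(
        db, assembly_id, gff_file_ids = gff_file_ids,
        cache = cache, strict = strict, batch_size = batch
      )
    }
    maybe_fail("genes")

    # -- stage: protein FASTA ingestion + proteins ---------------------
    protein_file_ids <- integer()
    if (!is.null(assembly$proteins_dir)) {
      faa_paths <- sort(list.files(assembly$proteins_dir, "\\.faa$",
                                   full.names = TRUE, ignore.case = TRUE))
      prot_run <- new_run("genes",
                          assembly$proteins_dir_label %||% assembly$proteins_dir)
      for (p in faa_paths) {
        recs <- read_fasta(p)
        fid <- ingest_file("fasta_file", prot_run, p,
                           list(file_kind = "protein"), nrow(recs))
        if (nrow(recs) > 0) {
          insert_if_absent(db, "fasta_entry", tibble::tibble(
            fasta_file_id = fid, record_id = recs$id,
            description = dplyr::na_if(recs$description, ""),
            sequence = recs$sequence
          ), cache, batch)
        }
        protein_file_ids <- c(protein_file_ids, fid)
      }
      stages[[length(stages) + 1]] <- assemble_proteins(
        db, assembly_id, fasta_file_ids = protein_file_ids,
        cache = cache, strict = strict, batch_size = batch
      )
    }
    maybe_fail("proteins")

    # -- stage: annotation plugins -------------------------------------
    for (ann in assembly$annotations) {
      entry <- plugin_entry(ann$plugin_name)
      ann_run <- new_run(list(name = entry$target_tool, version = entry$version),
                         ann$label)
      lines <- readLines(ann$path, warn = FALSE)
      fid <- ingest_file("protein_annotation_file", ann_run, ann$path,
                         list(plugin_name = ann$plugin_name), length(lines))
      entry_ids <- integer()
      if (length(lines) > 0) {
        eout <- insert_if_absent(db, "protein_annotation_entry", tibble::tibble(
          protein_annotation_file_id = fid,
          line_number = seq_along(lines), raw_line = lines
        ), cache, batch)
        entry_ids <- eout$id
      }
      annotations <- entry$parser(ann$path)
      if (nrow(annotations) > 0) {
        annotations$protein_annotation_entry_id <-
          entry_ids[annotations$line_number]
        annotations$line_number <- NULL
        stages[[length(stages) + 1]] <- link_protein_annotations(
          db, assembly_id, annotations,
          cache = cache, strict = strict, batch_size = batch
        )
      }
    }
    maybe_fail("annotations")

    # -- stage: dereplication clusters ---------------------------------
    if (!is.null(assembly$drep_cluster_table)) {
      drep_run <- new_run("dereplication",
                          assembly$drep_cluster_table_label %||%
                            assembly$drep_cluster_table)
      rows <- parse_drep_tables(assembly$drep_cluster_table,
                                assembly$drep_winners_table)
      cfid <- ingest_file("dereplication_file", drep_run,
                          assembly$drep_cluster_table,
                          list(table_role = "clusters"), nrow(rows))
      insert_if_absent(db, "dereplication_entry", tibble::tibble(
        dereplication_file_id = cfid, genome_name = rows$genome_name,
        cluster_label = rows$cluster_label, is_winner = rows$is_winner
      ), cache, batch)
      if (!is.null(assembly$drep_winners_table)) {
        ingest_file("dereplication_file", drep_run,
                    assembly$drep_winners_table,
                    list(table_role = "winners"), sum(rows$is_winner))
      }
      stages[[length(stages) + 1]] <- assemble_clusters(
        db, assembly_id, rows, cache = cache, strict = strict,
        batch_size = batch
      )
    }
    maybe_fail("clusters")

    # -- stage: taxonomy -----------------------------------------------
    if (!is.null(assembly$gtdbtk_summary)) {
      tax_run <- new_run("taxonomy",
                         assembly$gtdbtk_summary_label %||% assembly$gtdbtk_summary)
      rows <- parse_gtdbtk_summary(assembly$gtdbtk_summary)
      tfid <- ingest_file("taxonomy_file", tax_run, assembly$gtdbtk_summary,
                          rows = nrow(rows))
      raw <- readr::read_tsv(assembly$gtdbtk_summary, show_col_types = FALSE,
                             col_types = readr::cols(.default = readr::col_character()))
      eout <- insert_if_absent(db, "taxonomy_entry", tibble::tibble(
        taxonomy_file_id = tfid, user_genome = raw$user_genome,
        classification = raw$classification
      ), cache, batch)
      rows$taxonomy_entry_id <-
        eout$id[match(rows$user_genome, raw$user_genome)]
      stages[[length(stages) + 1]] <- assemble_taxonomy(
        db, assembly_id, rows, cache = cache, strict = strict,
        batch_size = batch
      )
    }
    maybe_fail("taxonomy")

    # -- stage: quality ------------------------------------------------
    if (!is.null(assembly$checkm2_report)) {
      q_run <- new_run("quality",
                       assembly$checkm2_report_label %||% assembly$checkm2_report)
      rows <- parse_checkm2_report(assembly$checkm2_report)
      qfid <- ingest_file("quality_file", q_run, assembly$checkm2_report,
                          rows = nrow(rows))
      eout <- insert_if_absent(db, "quality_entry", tibble::tibble(
        quality_file_id = qfid, genome_name = rows$genome_name,
        completeness_pct = rows$completeness_pct,
        contamination_pct = rows$contamination_pct
      ), cache, batch)
      rows$quality_entry_id <- eout$id
      stages[[length(stages) + 1]] <- assemble_quality(
        db, assembly_id, rows, cache = cache, strict = strict,
        batch_size = batch
      )
    }
    maybe_fail("quality")
  }

  structure(
    list(
      project_name = config$project_name,
      stages = stages,
      files = if (length(audit) > 0) dplyr::bind_rows(audit)
              else tibble::tibble(path = character(), sha256 = character(),
                                  rows_ingested = integer()),
      table_counts = table_counts(db),
      started_at = started_at,
      finished_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
    ),
    class = "magdb_ingest_report"
  )
}

#' @export
print.magdb_ingest_report <- function(x, ...) {
  cat("Ingest of project '", x$project_name, "' (",
      x$started_at, " .. ", x$finished_at, ")\n", sep = "")
  cat("  files ingested:", nrow(x$files), "\n")
  for (s in x$stages) print(s)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-stage summary of an ingest report
#'
#' @param x A `magdb_ingest_report`.
#' @param ... Unused.
#' @return A tibble with one row per (stage, entity): `stage`, `entity`,
#'   `created`, `linked`, `n_unmatched`.
#' @export
tidy.magdb_ingest_report <- function(x, ...) {
  purrr::map_dfr(x$stages, function(s) {
    tibble::tibble(
      stage = s$stage, entity = names(s$created),
      created = unname(s$created), linked = s$linked,
      n_unmatched = length(s$unmatched_keys)
    )
  })
}

#' One-row summary of an ingest report
#'
#' @param x A `magdb_ingest_report`.
#' @param ... Unused.
#' @return A one-row tibble: files, rows created, unmatched keys, total
#'   rows across all tables.
#' @export
glance.magdb_ingest_report <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_files = nrow(x$files),
    n_stages = length(x$stages),
    rows_created = sum(td$created),
    n_unmatched = sum(td$n_unmatched),
    total_rows = sum(x$table_counts$n_rows)
  )
}
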