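# Plugin contract for protein-annotation parsers and the four reference
# plugins: dbCAN, InterProScan, CLEAN, ProteInfer. A plugin is a parser
# (path -> tibble of unified annotations) plus a descriptor; plugins only
# ever populate existing tables, never touch the schema.

plugin_state <- new.env(parent = emptyenv())

#' Construct unified protein annotations
#'
#' The tool-agnostic record every annotation parser emits: a protein key
#' (matching a protein FASTA record id), the emitting tool, an annotation
#' type, an accession, and optional description, score and coordinates.
#'
#' @param protein_key,source_tool,annotation_type,accession Character.
#' @param description,score,coord_start,coord_stop Optional.
#' @return A validated tibble with one row per annotation.
#' @export
unified_annotation <- function(protein_key, source_tool, annotation_type,
                               accession, description = NA_character_,
                               score = NA_real_, coord_start = NA_integer_,
                               coord_stop = NA_integer_) {
  out <- tibble::tibble(
    protein_key = as.character(protein_key),
    source_tool = as.character(source_tool),
    annotation_type = as.character(annotation_type),
    accession = as.character(accession),
    description = as.character(description),
    score = as.numeric(score),
    coord_start = as.integer(coord_start),
    coord_stop = as.integer(coord_stop)
  )
  validate_annotations(out)
}

#' Validate a tibble of unified annotations
#'
#' @param annotations Tibble in the [unified_annotation()] layout.
#' @return The input, invisibly unchanged, or a validation error.
#' @export
validate_annotations <- function(annotations) {
  a <- annotations
  if (any(is.na(a$protein_key) | !nzchar(a$protein_key))) {
    magdb_abort("annotation protein_key must be non-empty",
                "magdb_validation_error")
  }
  if (any(is.na(a$accession) | !nzchar(a$accession))) {
    magdb_abort("annotation accession must be non-empty",
                "magdb_validation_error")
  }
  bad_type <- setdiff(unique(a$annotation_type), annotation_types())
  if (length(bad_type) > 0) {
    magdb_abort(
      paste0("unknown annotation_type: ", paste(bad_type, collapse = ", ")),
      "magdb_validation_error"
    )
  }
  both <- !is.na(a$coord_start) & !is.na(a$coord_stop)
  if (any(both & a$coord_start > a$coord_stop)) {
    magdb_abort("coord_start must be <= coord_stop", "magdb_validation_error")
  }
  if (any(!is.na(a$coord_start) & a$coord_start < 1)) {
    magdb_abort("coord_start must be >= 1", "magdb_validation_error")
  }
  a
}

empty_annotations <- function() {
  tibble::tibble(
    protein_key = character(), source_tool = character(),
    annotation_type = character(), accession = character(),
    description = character(), score = numeric(),
    coord_start = integer(), coord_stop = integer(),
    line_number = integer()
  )
}

builtin_plugins <- function() {
  list(
    dbcan = list(
      name = "dbcan", target_tool = "dbCAN", version = "1.0.0",
      parser = parse_dbcan_overview
    ),
    interpro = list(
      name = "interpro", target_tool = "InterProScan", version = "1.0.0",
      parser = parse_interproscan_tsv
    ),
    clean = list(
      name = "clean", target_tool = "CLEAN", version = "1.0.0",
      parser = parse_clean_output
    ),
    proteinfer = list(
      name = "proteinfer", target_tool = "ProteInfer", version = "1.0.0",
      parser = parse_proteinfer_output
    )
  )
}

#' Discover annotation plugins
#'
#' Returns every available plugin: the four built-in reference plugins
#' (always present unless `include_builtins = FALSE`) plus any installed
#' R package following the `magdb.plugin.<name>` naming convention and
#' exporting a `magdb_plugin()` entry point returning
#' `list(name, target_tool, version, parser)`.
#'
#' @param include_builtins Include the built-in reference plugins
#'   (default `TRUE`).
#' @return A tibble of descriptors: `name`, `target_tool`, `version`,
#'   `enabled`.
#' @export
#' @examples
#' discover_plugins()
discover_plugins <- function(include_builtins = TRUE) {
  plugins <- if (include_builtins) builtin_plugins() else list()
  pkgs <- grep("^magdb\\.plugin\\.", rownames(utils::installed.packages()),
               value = TRUE)
  for (pkg in pkgs) {
    entry <- tryCatch(getExportedValue(pkg, "magdb_plugin")(),
                      error = function(e) NULL)
    if (is.null(entry)) next
    if (entry$name %in% names(plugins)) {
      magdb_abort(
        paste0("two plugins share the name '", entry$name, "'"),
        "magdb_plugin_ambiguity"
      )
    }
    plugins[[entry$name]] <- entry
  }
  tibble::tibble(
    name = purrr::map_chr(plugins, "name"),
    target_tool = purrr::map_chr(plugins, "target_tool"),
    version = purrr::map_chr(plugins, "version"),
    enabled = purrr::map_lgl(plugins, function(p) {
      !isFALSE(plugin_state[[p$name]])
    })
  )
}

#' Enable or disable a plugin
#'
#' @param name Plugin name as listed by [discover_plugins()].
#' @param enabled Logical.
#' @return Invisibly, the updated descriptor tibble.
#' @export
plugin_set_enabled <- function(name, enabled) {
  known <- discover_plugins()$name
  if (!name %in% known) {
    magdb_abort(
      paste0("unknown plugin '", name, "'; known plugins: ",
             paste(known, collapse = ", ")),
      "magdb_plugin_error"
    )
  }
  plugin_state[[name]] <- isTRUE(enabled)
  invisible(discover_plugins())
}

plugin_entry <- function(name) {
  plugins <- builtin_plugins()
  if (name %in% names(plugins)) return(plugins[[name]])
  pkg <- paste0("magdb.plugin.", name)
  entry <- tryCatch(getExportedValue(pkg, "magdb_plugin")(),
                    error = function(e) NULL)
  if (is.null(entry)) {
    magdb_abort(paste0("unknown plugin '", name, "'"), "magdb_plugin_error")
  }
  entry
}

# -- dbCAN -------------------------------------------------------------------

# A consensus unit looks like "GH5", "GH5_2(31-330)" or "CBM3(5-90)".
parse_dbcan_unit <- function(unit) {
  m <- regmatches(unit, regexec(
    "^([A-Za-z]+)([0-9]+)((?:_[A-Za-z0-9]+)?)(?:\\((\\d+)-(\\d+)\\))?$", unit
  ))[[1]]
  if (length(m) == 0 || !m[2] %in% cazyme_classes()) return(NULL)
  list(
    family = paste0(m[2], m[3]),
    subfamily = if (nzchar(m[4])) paste0(m[2], m[3], m[4]) else NA_character_,
    coord_start = if (nzchar(m[5])) as.integer(m[5]) else NA_integer_,
    coord_stop = if (nzchar(m[6])) as.integer(m[6]) else NA_integer_
  )
}

#' Parse a dbCAN overview table into unified annotations
#'
#' Header-driven reader for the dbCAN `overview.txt` dialect: requires a
#' `Gene ID` and a `#ofTools` column; the consensus prediction column is
#' `Recommend Results` when present, otherwise the `HMMER` column. The
#' consensus is split on `+` into units such as `GH5` or `GH5_2(31-330)`;
#' each unit yields a family annotation (with coordinates when given) and,
#' when a subfamily suffix is present, an additional subfamily annotation.
#' The per-row tool-agreement count is carried as the score. Rows whose
#' family token does not start with a CAZy class code (GH, GT, PL, CE, AA,
#' CBM) are skipped with a warning; the skipped-row count is attached as
#' attribute `"skipped_rows"`.
#'
#' @param path Path to a dbCAN overview TSV.
#' @return A tibble of unified annotations (`source_tool = "dbcan"`).
#' @export
parse_dbcan_overview <- function(path) {
  check_readable(path)
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  for (need in c("Gene ID", "#ofTools")) {
    if (!need %in% names(tab)) {
      magdb_abort(
        paste0("dbCAN overview is missing required column '", need, "': ", path),
        "magdb_format_error"
      )
    }
  }
  cons_col <- if ("Recommend Results" %in% names(tab)) "Recommend Results" else "HMMER"
  if (!cons_col %in% names(tab)) {
    magdb_abort("dbCAN overview has no consensus prediction column",
                "magdb_format_error")
  }
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(tab))) {
    cons <- tab[[cons_col]][i]
    if (is.na(cons) || cons %in% c("-", "")) next
    units <- strsplit(cons, "+", fixed = TRUE)[[1]]
    parsed <- purrr::map(units, parse_dbcan_unit)
    if (any(purrr::map_lgl(parsed, is.null))) {
      skipped <- skipped + 1L
      next
    }
    ntools <- suppressWarnings(as.numeric(tab[["#ofTools"]][i]))
    for (u in parsed) {
      out[[length(out) + 1]] <- tibble::tibble(
        protein_key = tab[["Gene ID"]][i], source_tool = "dbcan",
        annotation_type = "family", accession = u$family,
        description = NA_character_, score = ntools,
        coord_start = u$coord_start, coord_stop = u$coord_stop,
        line_number = i + 1L
      )
      if (!is.na(u$subfamily)) {
        out[[length(out) + 1]] <- tibble::tibble(
          protein_key = tab[["Gene ID"]][i], source_tool = "dbcan",
          annotation_type = "subfamily", accession = u$subfamily,
          description = NA_character_, score = NA_real_,
          coord_start = NA_integer_, coord_stop = NA_integer_,
          line_number = i + 1L
        )
      }
    }
  }
  if (skipped > 0) {
    warning(sprintf("parse_dbcan_overview: skipped %d row(s) with malformed family tokens in %s",
                    skipped, path), call. = FALSE)
  }
  res <- if (length(out) == 0) empty_annotations() else
    validate_annotations(dplyr::bind_rows(out))
  attr(res, "skipped_rows") <- skipped
  res
}

# -- InterProScan ------------------------------------------------------------

#' Parse an InterProScan TSV into unified annotations
#'
#' Headerless tab-separated lines with at least 11 columns per the
#' InterProScan output convention (protein accession, MD5, length,
#' analysis, signature accession, signature description, start, stop,
#' e-value, status, date, then optional InterPro accession/description, GO
#' terms, pathways). Each line yields a domain annotation for the member
#' database signature (source `interproscan:<analysis>`, e-value as score,
#' coordinates); the InterPro accession in column 12 (when present and not
#' `-`) yields an extra domain annotation, and each GO id in column 14 a
#' go_term annotation.
#'
#' @param path Path to an InterProScan TSV.
#' @return A tibble of unified annotations.
#' @export
parse_interproscan_tsv <- function(path) {
  check_readable(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in seq_along(lines)) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 11) {
      magdb_abort(
        sprintf("malformed InterProScan line %d of %s: expected >= 11 columns, got %d",
                ln, path, length(fields)),
        "magdb_format_error"
      )
    }
    get <- function(i) if (length(fields) >= i) fields[i] else NA_character_
    evalue <- suppressWarnings(as.numeric(get(9)))
    out[[length(out) + 1]] <- tibble::tibble(
      protein_key = fields[1],
      source_tool = paste0("interproscan:", fields[4]),
      annotation_type = "domain", accession = fields[5],
      description = if (nzchar(fields[6]) && fields[6] != "-") fields[6]
                    else NA_character_,
      score = evalue,
      coord_start = suppressWarnings(as.integer(get(7))),
      coord_stop = suppressWarnings(as.integer(get(8))),
      line_number = ln
    )
    ipr <- get(12)
    if (!is.na(ipr) && nzchar(ipr) && ipr != "-") {
      out[[length(out) + 1]] <- tibble::tibble(
        protein_key = fields[1], source_tool = "interproscan",
        annotation_type = "domain", accession = ipr,
        description = {
          d <- get(13)
          if (!is.na(d) && nzchar(d) && d != "-") d else NA_character_
        },
        score = NA_real_, coord_start = NA_integer_, coord_stop = NA_integer_,
        line_number = ln
      )
    }
    go <- get(14)
    if (!is.na(go) && nzchar(go) && go != "-") {
      for (gid in strsplit(go, "|", fixed = TRUE)[[1]]) {
        # GTDB-era InterProScan suffixes GO ids with "(source)"; strip it.
        gid <- sub("\\(.*\\)$", "", gid)
        out[[length(out) + 1]] <- tibble::tibble(
          protein_key = fields[1], source_tool = "interproscan",
          annotation_type = "go_term", accession = gid,
          description = NA_character_, score = NA_real_,
          coord_start = NA_integer_, coord_stop = NA_integer_,
          line_number = ln
        )
      }
    }
  }
  if (length(out) == 0) return(empty_annotations())
  validate_annotations(dplyr::bind_rows(out))
}

# -- CLEAN -------------------------------------------------------------------

#' Parse CLEAN enzyme-commission predictions into unified annotations
#'
#' CSV dialect: each line is a protein id followed by one or more
#' `EC:a.b.c.d/score` terms separated by `;`. Scores are not
#' range-constrained.
#'
#' @param path Path to a CLEAN CSV.
#' @return A tibble of ec_number annotations (`source_tool = "clean"`).
#' @export
parse_clean_output <- function(path) {
  check_readable(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in seq_along(lines)) {
    protein <- sub(",.*$", "", lines[ln])
    rest <- sub("^[^,]*,", "", lines[ln])
    terms <- trimws(strsplit(rest, ";", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    for (term in terms) {
      if (!grepl("/", term, fixed = TRUE)) {
        magdb_abort(
          sprintf("malformed CLEAN term '%s' on line %d of %s (missing '/')",
                  term, ln, path),
          "magdb_format_error"
        )
      }
      acc <- sub("/.*$", "", term)
      acc <- sub("^EC:", "", acc)
      score <- suppressWarnings(as.numeric(sub("^.*/", "", term)))
      out[[length(out) + 1]] <- tibble::tibble(
        protein_key = protein, source_tool = "clean",
        annotation_type = "ec_number", accession = acc,
        description = NA_character_, score = score,
        coord_start = NA_integer_, coord_stop = NA_integer_,
        line_number = ln
      )
    }
  }
  if (length(out) == 0) return(empty_annotations())
  validate_annotations(dplyr::bind_rows(out))
}

# -- ProteInfer --------------------------------------------------------------

#' Parse ProteInfer predictions into unified annotations
#'
#' TSV dialect with header `sequence_name`, `predicted_label`,
#' `confidence`. Labels starting `GO:` become go_term annotations, labels
#' matching `EC:` become ec_number annotations, anything else a description
#' annotation; confidence is carried as the score.
#'
#' @param path Path to a ProteInfer TSV.
#' @return A tibble of unified annotations (`source_tool = "proteinfer"`).
#' @export
parse_proteinfer_output <- function(path) {
  check_readable(path)
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  for (need in c("sequence_name", "predicted_label", "confidence")) {
    if (!need %in% names(tab)) {
      magdb_abort(
        paste0("ProteInfer output is missing required column '", need, "': ", path),
        "magdb_format_error"
      )
    }
  }
  if (nrow(tab) == 0) return(empty_annotations())
  conf <- suppressWarnings(as.numeric(tab$confidence))
  if (any(is.na(conf))) {
    magdb_abort("ProteInfer confidence values must be numeric",
                "magdb_format_error")
  }
  label <- tab$predicted_label
  type <- dplyr::case_when(
    startsWith(label, "GO:") ~ "go_term",
    grepl("^EC:", label) ~ "ec_number",
    TRUE ~ "description"
  )
  accession <- ifelse(type == "ec_number", sub("^EC:", "", label), label)
  validate_annotations(tibble::tibble(
    protein_key = tab$sequence_name, source_tool = "proteinfer",
    annotation_type = type, accession = accession,
    description = NA_character_, score = conf,
    coord_start = NA_integer_, coord_stop = NA_integer_,
    line_number = seq_len(nrow(tab)) + 1L
  ))
}
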