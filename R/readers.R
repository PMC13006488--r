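# Streaming readers for the standard workflow-output formats: FASTA, GFF3,
# GTDB-Tk summary TSV, dRep cluster CSV, CheckM2 quality TSV.

check_readable <- function(path) {
  if (!file.exists(path)) {
    magdb_abort(paste0("file not found: ", path), "magdb_io_error")
  }
  invisible(path)
}

#' Read a FASTA file
#'
#' One record per `>` header, in file order. The id is the token before the
#' first whitespace of the header; the rest is the description. Sequence
#' lines are concatenated, stripped of whitespace and uppercased; the
#' alphabet is permissive (any letter plus `*` and `-`), since Prokka
#' protein FASTAs carry `*` stop marks.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `sequence`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 circular", "ACGT", "acgt"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  check_readable(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(id = character(), description = character(),
                          sequence = character()))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    magdb_abort(
      paste0("malformed FASTA (sequence data before first header): ", path),
      "magdb_malformed_fasta"
    )
  }
  rec_idx <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) {
    magdb_abort(
      paste0("malformed FASTA (empty record id): ", path),
      "magdb_malformed_fasta"
    )
  }
  descriptions <- ifelse(
    grepl("\\s", headers),
    trimws(sub("^\\S+\\s+", "", headers)),
    ""
  )
  seq_lines <- split(lines[!is_header], factor(rec_idx[!is_header],
                                              levels = seq_along(headers)))
  sequences <- purrr::map_chr(seq_lines, function(x) {
    toupper(gsub("\\s", "", paste(x, collapse = "")))
  })
  tibble::tibble(id = ids, description = descriptions,
                 sequence = unname(sequences))
}

#' Write records to a FASTA file
#'
#' Inverse of [read_fasta()]: writes `>id description` headers and wraps
#' sequences at `width` columns, so that read-then-write round-trips on
#' (id, description, sequence).
#'
#' @param records Tibble with columns `id`, `description`, `sequence`.
#' @param path Output path.
#' @param width Sequence line width (default 80).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 80) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- records$description[i]
    header <- if (nzchar(desc)) paste0(">", records$id[i], " ", desc)
              else paste0(">", records$id[i])
    writeLines(header, con)
    s <- records$sequence[i]
    if (nchar(s) > 0) {
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
    }
  }
  invisible(path)
}

decode_gff_value <- function(x) {
  # Percent-decoding per the GFF3 attribute escaping rules.
  if (!grepl("%", x, fixed = TRUE)) return(x)
  tryCatch(utils::URLdecode(x), error = function(e) x)
}

parse_gff_attributes <- function(text) {
  if (is.na(text) || !nzchar(text) || text == ".") {
    return(stats::setNames(character(), character()))
  }
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  keys <- sub("=.*$", "", parts)
  values <- ifelse(grepl("=", parts, fixed = TRUE), sub("^[^=]*=", "", parts), "")
  values <- purrr::map_chr(values, decode_gff_value)
  stats::setNames(values, keys)
}

#' Read a GFF3 annotation file
#'
#' One feature per 9-column tab-separated line. `#`-prefixed lines are
#' skipped and everything after a `##FASTA` directive is ignored. `.` in
#' the score and frame columns maps to `NA`; attribute values are
#' percent-decoded. Coordinates are kept exactly as GFF3 states them:
#' 1-based, inclusive, on the forward axis of the landing sequence.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `seqid`, `source`, `feature_type`,
#'   `start`, `end`, `score`, `strand`, `frame`, `attributes` (list column
#'   of named character vectors, order preserved), `attributes_text`
#'   (column 9 verbatim) and `line_number`.
#' @export
read_gff3 <- function(path) {
  check_readable(path)
  lines <- readLines(path, warn = FALSE)
  empty <- tibble::tibble(
    seqid = character(), source = character(), feature_type = character(),
    start = integer(), end = integer(), score = numeric(),
    strand = character(), frame = integer(),
    attributes = list(), attributes_text = character(), line_number = integer()
  )
  if (length(lines) == 0) return(empty)
  fasta_at <- which(startsWith(lines, "##FASTA"))
  if (length(fasta_at) > 0) lines <- utils::head(lines, fasta_at[1] - 1)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(keep) == 0) return(empty)
  rows <- lapply(keep, function(ln) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9) {
      magdb_abort(
        sprintf("malformed GFF line %d of %s: expected 9 tab-separated columns, got %d",
                ln, path, length(fields)),
        "magdb_malformed_gff"
      )
    }
    start <- suppressWarnings(as.integer(fields[4]))
    end <- suppressWarnings(as.integer(fields[5]))
    if (is.na(start) || is.na(end) || start < 1 || start > end) {
      magdb_abort(
        sprintf("malformed GFF line %d of %s: invalid coordinates '%s'..'%s'",
                ln, path, fields[4], fields[5]),
        "magdb_malformed_gff"
      )
    }
    if (!fields[7] %in% strand_values()) {
      magdb_abort(
        sprintf("malformed GFF line %d of %s: invalid strand '%s'",
                ln, path, fields[7]),
        "magdb_malformed_gff"
      )
    }
    list(
      seqid = fields[1], source = fields[2], feature_type = fields[3],
      start = start, end = end,
      score = if (fields[6] == ".") NA_real_
              else suppressWarnings(as.numeric(fields[6])),
      strand = fields[7],
      frame = if (fields[8] == ".") NA_integer_
              else suppressWarnings(as.integer(fields[8])),
      attributes_text = fields[9],
      line_number = ln
    )
  })
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  out$attributes <- purrr::map(out$attributes_text, parse_gff_attributes)
  dplyr::relocate(out, "attributes", .before = "attributes_text")
}

rank_prefixes <- function() {
  stats::setNames(c("d__", "p__", "c__", "o__", "f__", "g__", "s__"),
                  taxonomic_ranks())
}

split_lineage <- function(classification) {
  ranks <- taxonomic_ranks()
  prefixes <- rank_prefixes()
  lineage <- stats::setNames(rep(NA_character_, 7), ranks)
  if (is.na(classification) || !nzchar(trimws(classification)) ||
      !grepl("__", classification, fixed = TRUE)) {
    # "Unclassified" and friends: every rank unassigned.
    return(lineage)
  }
  fields <- trimws(strsplit(classification, ";", fixed = TRUE)[[1]])
  fields <- fields[nzchar(fields)]
  if (length(fields) > 7) {
    magdb_abort(
      paste0("classification has more than 7 rank fields: ", classification),
      "magdb_format_error"
    )
  }
  for (i in seq_along(fields)) {
    if (!startsWith(fields[i], prefixes[[i]])) {
      magdb_abort(
        sprintf("rank prefix out of canonical order at position %d: '%s'",
                i, fields[i]),
        "magdb_format_error"
      )
    }
    name <- substring(fields[i], 4)
    if (nzchar(name)) lineage[[ranks[i]]] <- name
  }
  lineage
}

#' Parse a GTDB-Tk classification summary
#'
#' Splits each genome's `classification` string on `;` into the seven
#' canonical ranks (`d__` ... `s__`). A slot whose text after the prefix is
#' empty is unassigned; `"Unclassified"` or truncated strings leave all
#' missing ranks unassigned. A genome whose species slot is unassigned is
#' flagged as a taxonomic novelty.
#'
#' @param path Path to a tab-separated summary with columns `user_genome`
#'   and `classification`.
#' @return A tibble with columns `user_genome`, `lineage` (list column of
#'   named rank->name vectors, `NA` = unassigned), `lowest_assigned_rank`
#'   (`NA` when nothing is assigned) and `is_novel_species`.
#' @export
parse_gtdbtk_summary <- function(path) {
  check_readable(path)
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  for (need in c("user_genome", "classification")) {
    if (!need %in% names(tab)) {
      magdb_abort(
        paste0("GTDB-Tk summary is missing required column '", need, "': ", path),
        "magdb_format_error"
      )
    }
  }
  ranks <- taxonomic_ranks()
  lineage <- purrr::map(tab$classification, split_lineage)
  lowest <- purrr::map_chr(lineage, function(l) {
    assigned <- ranks[!is.na(l)]
    if (length(assigned) == 0) NA_character_ else assigned[length(assigned)]
  })
  tibble::tibble(
    user_genome = tab$user_genome,
    lineage = lineage,
    lowest_assigned_rank = lowest,
    is_novel_species = purrr::map_lgl(lineage, ~ is.na(.x[["species"]]))
  )
}

#' Normalize a genome file name to its bin stem
#'
#' Strips one recognized FASTA extension (`.fa`, `.fasta`, `.fna`),
#' preserving the rest of the stem verbatim. All cross-file joins use the
#' normalized stem.
#'
#' @param x Character vector of file names or paths.
#' @return Character vector of stems.
#' @export
#' @examples
#' normalize_genome_name(c("bin_01.fa", "bin.v2.fasta", "plain"))
normalize_genome_name <- function(x) {
  sub("\\.(fa|fasta|fna)$", "", basename(x), ignore.case = TRUE)
}

#' Parse dRep dereplication tables
#'
#' Reads the cluster table (columns `genome`, `secondary_cluster`) and, when
#' given, the winners table (column `genome`) that lists each cluster's
#' representative. Genome file names are normalized to bin stems.
#'
#' @param cluster_csv_path Path to the cluster CSV.
#' @param winner_csv_path Optional path to the winners CSV.
#' @return A tibble with columns `genome_name`, `cluster_label`,
#'   `is_winner`.
#' @export
parse_drep_tables <- function(cluster_csv_path, winner_csv_path = NULL) {
  check_readable(cluster_csv_path)
  clusters <- readr::read_csv(cluster_csv_path, show_col_types = FALSE,
                              col_types = readr::cols(.default = readr::col_character()))
  for (need in c("genome", "secondary_cluster")) {
    if (!need %in% names(clusters)) {
      magdb_abort(
        paste0("dRep cluster table is missing required column '", need, "'"),
        "magdb_format_error"
      )
    }
  }
  out <- tibble::tibble(
    genome_name = normalize_genome_name(clusters$genome),
    cluster_label = clusters$secondary_cluster,
    is_winner = FALSE
  )
  if (any(is.na(out$cluster_label) | !nzchar(out$cluster_label))) {
    magdb_abort("dRep cluster table has empty cluster labels",
                "magdb_format_error")
  }
  if (!is.null(winner_csv_path)) {
    check_readable(winner_csv_path)
    winners <- readr::read_csv(winner_csv_path, show_col_types = FALSE,
                               col_types = readr::cols(.default = readr::col_character()))
    if (!"genome" %in% names(winners)) {
      magdb_abort("dRep winners table is missing required column 'genome'",
                  "magdb_format_error")
    }
    wnames <- normalize_genome_name(winners$genome)
    missing <- setdiff(wnames, out$genome_name)
    if (length(missing) > 0) {
      magdb_abort(
        paste0("winner genome(s) absent from cluster table: ",
               paste(missing, collapse = ", ")),
        "magdb_crossfile_error"
      )
    }
    out$is_winner <- out$genome_name %in% wnames
  }
  out
}

#' Parse a CheckM2 quality report
#'
#' @param path Path to a tab-separated report with columns `Name`,
#'   `Completeness` and `Contamination`.
#' @return A tibble with columns `genome_name`, `completeness_pct`,
#'   `contamination_pct`.
#' @export
parse_checkm2_report <- function(path) {
  check_readable(path)
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  for (need in c("Name", "Completeness", "Contamination")) {
    if (!need %in% names(tab)) {
      magdb_abort(
        paste0("CheckM2 report is missing required column '", need, "': ", path),
        "magdb_format_error"
      )
    }
  }
  comp <- suppressWarnings(as.numeric(tab$Completeness))
  cont <- suppressWarnings(as.numeric(tab$Contamination))
  if (any(is.na(comp)) || any(is.na(cont))) {
    magdb_abort("CheckM2 report has non-numeric quality values",
                "magdb_format_error")
  }
  if (any(comp < 0 | comp > 100)) {
    magdb_abort("CheckM2 completeness outside [0, 100]",
                "magdb_validation_error")
  }
  if (any(cont < 0)) {
    magdb_abort("CheckM2 contamination below 0", "magdb_validation_error")
  }
  tibble::tibble(
    genome_name = tab$Name,
    completeness_pct = comp,
    contamination_pct = cont
  )
}
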