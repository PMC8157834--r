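#' Read a feature table from TSV or CSV
#'
#' The first column of the file holds feature identifiers and the header row
#' holds sample identifiers. The first header cell is ignored whatever its
#' content (`""`, `"#OTU ID"`, `"#NAME"`, ... all accepted), following the
#' tolerant-reader principle. Cells must be non-negative integers; anything
#' else is a format error naming the offending feature and sample.
#'
#' @param path Path to the table file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param samples_as_rows If `TRUE` the file is transposed on load (samples
#'   in rows, features in columns).
#' @return A feature table tibble (see [feature_table()]).
#' @export
read_feature_table <- function(path, dialect = c("tsv", "csv"),
                               samples_as_rows = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_io(sprintf("table file not found: '%s'", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_format(sprintf("table file '%s' is empty", path))
  delim <- if (dialect == "tsv") "\t" else ","
  split_row <- function(line) {
    if (dialect == "tsv") {
      strsplit(line, "\t", fixed = TRUE)[[1]]
    } else {
      scan(text = line, what = character(), sep = ",", quote = '"',
           quiet = TRUE, strip.white = FALSE)
    }
  }
  header <- split_row(lines[1])
  col_ids <- header[-1]
  if (length(lines) > 1) {
    rows <- lapply(lines[-1], split_row)
    nf <- lengths(rows)
    if (any(nf != length(header))) {
      stop_format(sprintf("row %d of '%s' has %d fields, expected %d",
                          which(nf != length(header))[1] + 1L, path,
                          nf[nf != length(header)][1], length(header)))
    }
    row_ids <- vapply(rows, `[[`, character(1), 1)
    cells <- matrix("", nrow = length(rows), ncol = length(col_ids))
    for (i in seq_along(rows)) cells[i, ] <- rows[[i]][-1]
  } else {
    row_ids <- character()
    cells <- matrix("", nrow = 0, ncol = length(col_ids))
  }
  if (samples_as_rows) {
    cells <- t(cells)
    tmp <- row_ids; row_ids <- col_ids; col_ids <- tmp
  }
  bad <- !grepl("^[0-9]+$", cells)
  dim(bad) <- dim(cells)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop_format(sprintf(
      "count at feature '%s', sample '%s' in '%s' is not a non-negative integer: '%s'",
      row_ids[idx[1]], col_ids[idx[2]], path, cells[idx[1], idx[2]]))
  }
  counts <- matrix(as.integer(cells), nrow = length(row_ids),
                   ncol = length(col_ids),
                   dimnames = list(row_ids, col_ids))
  if (anyNA(counts)) stop_format(sprintf("count overflow in '%s'", path))
  feature_table(counts)
}

#' Write a feature table to TSV or CSV
#'
#' @param tbl Feature table tibble.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param first_cell Content of the ignored first header cell.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tbl, path, dialect = c("tsv", "csv"),
                                first_cell = "#OTU ID") {
  dialect <- match.arg(dialect)
  tbl <- validate_feature_table(tbl)
  ids <- c(first_cell, ft_sample_ids(tbl))
  if (dialect == "tsv") {
    if (any(grepl("\t", unlist(c(ids, tbl$feature_id)), fixed = TRUE))) {
      stop_format("identifiers must not contain tab characters in tsv output")
    }
    header <- paste(ids, collapse = "\t")
    body <- apply(cbind(tbl$feature_id, format_counts(tbl)), 1,
                  paste, collapse = "\t")
  } else {
    header <- paste(csv_field(ids), collapse = ",")
    body <- apply(cbind(csv_field(tbl$feature_id), format_counts(tbl)), 1,
                  paste, collapse = ",")
  }
  write_lines_utf8(c(header, if (nrow(tbl)) body), path)
}

format_counts <- function(tbl) {
  m <- ft_counts(tbl)
  matrix(as.character(m), nrow = nrow(m))
}

#' Read representative ASV sequences from FASTA
#'
#' Sequences are uppercased; IUPAC ambiguity characters outside
#' `{A,C,G,T,N}` are mapped to `N` with a warning, because downstream merge
#' logic only distinguishes `N`. Duplicate identifiers are a hard error:
#' silently keeping one would corrupt the counts-to-sequence pairing.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `feature_id` and `sequence`.
#' @export
read_asv_fasta <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("FASTA file not found: '%s'", path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop_format(sprintf("duplicate FASTA ids: %s",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  if (any(grepl("[^ACGTN]", seqs))) {
    warn("characters outside {A,C,G,T,N} mapped to N")
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  if (any(!nzchar(seqs))) stop_format("empty sequence in FASTA")
  tibble(feature_id = ids, sequence = unname(seqs))
}

#' Write ASV sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs Tibble with `feature_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asv_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(setNames(seqs$sequence, seqs$feature_id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a taxonomy table
#'
#' First column holds feature identifiers, remaining columns the ranked
#' lineage (default seven ranks, Kingdom through Species). Empty strings are
#' allowed at any rank.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return Tibble with `feature_id` plus one column per rank.
#' @export
read_taxonomy <- function(path, dialect = c("tsv", "csv")) {
  read_id_table(path, match.arg(dialect), "feature_id")
}

#' Read sample metadata
#'
#' First column holds sample identifiers; remaining columns are free-form
#' string attributes.
#'
#' @inheritParams read_taxonomy
#' @return Tibble with `sample_id` plus one column per attribute.
#' @export
read_sample_metadata <- function(path, dialect = c("tsv", "csv")) {
  read_id_table(path, match.arg(dialect), "sample_id")
}

read_id_table <- function(path, dialect, id_col) {
  if (!file.exists(path)) stop_io(sprintf("file not found: '%s'", path))
  df <- if (dialect == "csv") {
    read.csv(path, check.names = FALSE, colClasses = "character")
  } else {
    read.csv(path, sep = "\t", quote = "", check.names = FALSE,
             colClasses = "character")
  }
  if (ncol(df) < 1) stop_format(sprintf("'%s' has no columns", path))
  names(df)[1] <- id_col
  if (anyDuplicated(df[[1]])) {
    stop_format(sprintf("duplicate ids in '%s'", path))
  }
  if (anyDuplicated(names(df))) {
    stop_format(sprintf("duplicate column names in '%s'", path))
  }
  as_tibble(df)
}

write_id_table <- function(df, path, dialect, first_cell = names(df)[1]) {
  hdr <- c(first_cell, names(df)[-1])
  if (nrow(df)) {
    body <- vapply(df, as.character, character(nrow(df)))
    if (nrow(df) == 1) body <- matrix(body, nrow = 1)
    fields <- rbind(hdr, body)
  } else {
    fields <- matrix(hdr, nrow = 1)
  }
  if (dialect == "csv") {
    lines <- apply(fields, 1, function(r) paste(csv_field(r), collapse = ","))
  } else {
    if (any(grepl("\t", fields, fixed = TRUE))) {
      stop_format("fields must not contain tab characters in tsv output")
    }
    lines <- apply(fields, 1, paste, collapse = "\t")
  }
  write_lines_utf8(lines, path)
}

#' Load a cross-validated amplicon dataset
#'
#' Reads the feature table plus any of: representative sequences (FASTA),
#' taxonomy and sample metadata, and checks they are mutually consistent.
#' Sequence ids must equal the table's feature ids as sets; taxonomy must
#' cover every feature; metadata must cover every sample. Extra taxonomy or
#' metadata rows are dropped with a warning.
#'
#' @param table_path Path to the feature table.
#' @param fasta_path,taxonomy_path,metadata_path Optional component paths.
#' @param dialect `"tsv"` or `"csv"` for the tabular components.
#' @param samples_as_rows Transpose the feature table on load.
#' @return An `asv_dataset`: a list with elements `table`, `sequences`,
#'   `taxonomy`, `metadata` (tibbles or `NULL`).
#' @export
load_dataset <- function(table_path, fasta_path = NULL, taxonomy_path = NULL,
                         metadata_path = NULL, dialect = c("tsv", "csv"),
                         samples_as_rows = FALSE) {
  dialect <- match.arg(dialect)
  table <- read_feature_table(table_path, dialect, samples_as_rows)
  sequences <- if (!is.null(fasta_path)) read_asv_fasta(fasta_path)
  taxonomy <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path, dialect)
  metadata <- if (!is.null(metadata_path)) read_sample_metadata(metadata_path, dialect)
  asv_dataset(table, sequences, taxonomy, metadata)
}

#' Assemble and validate an amplicon dataset
#'
#' @param table Feature table tibble.
#' @param sequences Optional tibble (`feature_id`, `sequence`).
#' @param taxonomy Optional tibble (`feature_id` + rank columns).
#' @param metadata Optional tibble (`sample_id` + attribute columns).
#' @return An `asv_dataset` list.
#' @export
asv_dataset <- function(table, sequences = NULL, taxonomy = NULL,
                        metadata = NULL) {
  table <- validate_feature_table(table)
  fids <- table$feature_id
  sids <- ft_sample_ids(table)
  if (!is.null(sequences)) {
    extra <- setdiff(sequences$feature_id, fids)
    missing <- setdiff(fids, sequences$feature_id)
    if (length(extra) || length(missing)) {
      stop_consistency(sprintf(
        "sequence ids do not match table feature ids (only in FASTA: %s; only in table: %s)",
        paste(head(extra, 5), collapse = ", "),
        paste(head(missing, 5), collapse = ", ")))
    }
    sequences <- sequences[match(fids, sequences$feature_id), ]
  }
  if (!is.null(taxonomy)) {
    missing <- setdiff(fids, taxonomy$feature_id)
    if (length(missing)) {
      stop_consistency(sprintf("features without taxonomy: %s",
                               paste(head(missing, 5), collapse = ", ")))
    }
    if (length(setdiff(taxonomy$feature_id, fids))) {
      warn("dropping taxonomy rows for features absent from the table")
    }
    taxonomy <- taxonomy[match(fids, taxonomy$feature_id), ]
  }
  if (!is.null(metadata)) {
    missing <- setdiff(sids, metadata$sample_id)
    if (length(missing)) {
      stop_consistency(sprintf("samples without metadata: %s",
                               paste(head(missing, 5), collapse = ", ")))
    }
    if (length(setdiff(metadata$sample_id, sids))) {
      warn("dropping metadata rows for samples absent from the table")
    }
    metadata <- metadata[match(sids, metadata$sample_id), ]
  }
  structure(list(table = table, sequences = sequences, taxonomy = taxonomy,
                 metadata = metadata),
            class = "asv_dataset")
}

#' @export
print.asv_dataset <- function(x, ...) {
  cat(sprintf("<asv_dataset> %d features x %d samples\n",
              nrow(x$table), length(ft_sample_ids(x$table))))
  cat(sprintf("  sequences: %s  taxonomy: %s  metadata: %s\n",
              if (is.null(x$sequences)) "absent" else "present",
              if (is.null(x$taxonomy)) "absent" else "present",
              if (is.null(x$metadata)) "absent" else "present"))
  invisible(x)
}

#' Save a dataset to a directory
#'
#' Writes the feature table and any optional components so that
#' [load_dataset()] on the result reproduces the dataset exactly
#' (round-trip identity).
#'
#' @param ds An `asv_dataset`.
#' @param outdir Output directory, created if needed.
#' @param dialect `"tsv"` or `"csv"`.
#' @return Tibble with columns `role` and `path` listing written files.
#' @export
save_dataset <- function(ds, outdir, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ds, "asv_dataset"))
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop_io(sprintf("cannot create output directory '%s'", outdir))
  ext <- dialect
  files <- list(table = file.path(outdir, paste0("feature_table.", ext)))
  write_feature_table(ds$table, files$table, dialect)
  if (!is.null(ds$sequences)) {
    files$sequences <- file.path(outdir, "asvs.fasta")
    write_asv_fasta(ds$sequences, files$sequences)
  }
  if (!is.null(ds$taxonomy)) {
    files$taxonomy <- file.path(outdir, paste0("taxonomy.", ext))
    write_id_table(ds$taxonomy, files$taxonomy, dialect)
  }
  if (!is.null(ds$metadata)) {
    files$metadata <- file.path(outdir, paste0("metadata.", ext))
    write_id_table(ds$metadata, files$metadata, dialect)
  }
  tibble(role = names(files), path = unlist(files, use.names = FALSE))
}
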