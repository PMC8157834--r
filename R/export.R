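#' Export a dataset as a MicrobiomeAnalyst input bundle
#'
#' Writes the comma-separated files the MicrobiomeAnalyst web portal imports
#' directly: an abundance file whose first header cell is exactly `#NAME`,
#' a taxonomy file headed `#TAXONOMY` (when taxonomy is present) and a
#' metadata file headed `#NAME` (when metadata is present). Counts, feature
#' order and sample order are preserved byte-exactly; identifiers containing
#' the delimiter are quoted.
#'
#' @param ds An [asv_dataset()].
#' @param outdir Output directory, created if needed.
#' @return An `asv_export_bundle`: tibble with columns `role` and `path`,
#'   with the target recorded in attribute `target`.
#' @export
export_microbiomeanalyst <- function(ds, outdir) {
  stopifnot(inherits(ds, "asv_dataset"))
  if (length(ft_sample_ids(ds$table)) < 1) {
    stop_precondition("dataset has no samples to export")
  }
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop_io(sprintf("cannot create output directory '%s'", outdir))

  files <- list()
  files$abundance <- file.path(outdir, "abundance.csv")
  header <- paste(csv_field(c("#NAME", ft_sample_ids(ds$table))), collapse = ",")
  body <- if (nrow(ds$table)) {
    apply(cbind(csv_field(ds$table$feature_id), format_counts(ds$table)),
          1, paste, collapse = ",")
  }
  write_lines_utf8(c(header, body), files$abundance)

  if (!is.null(ds$taxonomy)) {
    files$taxonomy <- file.path(outdir, "taxonomy.csv")
    write_id_table(ds$taxonomy, files$taxonomy, "csv", first_cell = "#TAXONOMY")
  }
  if (!is.null(ds$metadata)) {
    files$metadata <- file.path(outdir, "metadata.csv")
    write_id_table(ds$metadata, files$metadata, "csv", first_cell = "#NAME")
  }
  bundle(files, "microbiomeanalyst")
}

#' Export a dataset as a Rhea input table
#'
#' Writes the single tab-separated OTU table the Rhea scripts consume: first
#' header cell exactly `#OTUId`, one column per sample, and — when taxonomy
#' is present — a final `taxonomy` column holding the lineage joined with
#' `";"` (empty ranks are kept, so a lineage ending in an empty species
#' yields a trailing semicolon). Rhea has no quoting convention, so
#' identifiers containing a tab are rejected.
#'
#' @param ds An [asv_dataset()].
#' @param outpath Output file path (conventionally `otutable_rhea.tab`).
#' @return An `asv_export_bundle` tibble.
#' @export
export_rhea <- function(ds, outpath) {
  stopifnot(inherits(ds, "asv_dataset"))
  sids <- ft_sample_ids(ds$table)
  if (length(sids) < 1) stop_precondition("dataset has no samples to export")
  ids <- c(sids, ds$table$feature_id)
  if (any(grepl("\t", ids, fixed = TRUE))) {
    stop_format("identifiers containing tab cannot be exported for Rhea")
  }
  header <- c("#OTUId", sids)
  cells <- cbind(ds$table$feature_id, format_counts(ds$table))
  if (!is.null(ds$taxonomy)) {
    header <- c(header, "taxonomy")
    ranks <- as.matrix(ds$taxonomy[, -1, drop = FALSE])
    lineage <- if (nrow(ranks)) apply(ranks, 1, paste, collapse = ";") else character(0)
    cells <- cbind(cells, lineage)
  }
  lines <- c(paste(header, collapse = "\t"),
             if (nrow(cells)) apply(cells, 1, paste, collapse = "\t"))
  write_lines_utf8(lines, outpath)
  bundle(list(otu_table = outpath), "rhea")
}

bundle <- function(files, target) {
  out <- tibble(role = names(files), path = unlist(files, use.names = FALSE))
  attr(out, "target") <- target
  class(out) <- c("asv_export_bundle", class(out))
  out
}
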