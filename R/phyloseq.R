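#' Assemble a dataset into a phyloseq object
#'
#' Bridges the post-denoising artifacts into the interactive R ecosystem:
#' the count matrix becomes an `otu_table` (taxa as rows), taxonomy a
#' `tax_table`, metadata `sample_data`, and an optional newick tree (read
#' verbatim with \pkg{ape}) the phylogeny. Counts in the built object equal
#' the dataset's table exactly; component consistency is already enforced by
#' [asv_dataset()].
#'
#' @param ds An [asv_dataset()].
#' @param tree_path Optional path to a newick tree whose tip labels match
#'   the feature ids.
#' @return A `phyloseq::phyloseq` object.
#' @export
build_phyloseq <- function(ds, tree_path = NULL) {
  stopifnot(inherits(ds, "asv_dataset"))
  if (!requireNamespace("phyloseq", quietly = TRUE)) {
    stop_precondition("the 'phyloseq' package is required for build_phyloseq()")
  }
  parts <- list(phyloseq::otu_table(ft_counts(ds$table), taxa_are_rows = TRUE))
  if (!is.null(ds$taxonomy)) {
    ranks <- as.matrix(ds$taxonomy[, -1, drop = FALSE])
    rownames(ranks) <- ds$taxonomy$feature_id
    parts <- c(parts, list(phyloseq::tax_table(ranks)))
  }
  if (!is.null(ds$metadata)) {
    sam <- as.data.frame(ds$metadata[, -1, drop = FALSE])
    rownames(sam) <- ds$metadata$sample_id
    parts <- c(parts, list(phyloseq::sample_data(sam)))
  }
  if (!is.null(tree_path)) {
    if (!file.exists(tree_path)) {
      stop_io(sprintf("tree file not found: '%s'", tree_path))
    }
    tree <- tryCatch(ape::read.tree(tree_path), error = function(e) NULL)
    if (is.null(tree)) stop_format(sprintf("malformed newick tree: '%s'", tree_path))
    missing <- setdiff(ds$table$feature_id, tree$tip.label)
    if (length(missing)) {
      stop_consistency(sprintf("tree '%s' lacks tips for features: %s",
                               tree_path, paste(head(missing, 5), collapse = ", ")))
    }
    parts <- c(parts, list(phyloseq::phy_tree(tree)))
  }
  do.call(phyloseq::phyloseq, parts)
}

#' Alpha-diversity summary macro for a phyloseq object
#'
#' A small example of a command-line macro over the hand-off object:
#' observed richness plus Shannon and Simpson indices per sample, as a
#' tibble.
#'
#' @param physeq A `phyloseq::phyloseq` object.
#' @return Tibble with `sample_id` and one column per diversity measure.
#' @export
macro_alpha_diversity <- function(physeq) {
  if (!requireNamespace("phyloseq", quietly = TRUE)) {
    stop_precondition("the 'phyloseq' package is required for macros")
  }
  rich <- phyloseq::estimate_richness(
    physeq, measures = c("Observed", "Shannon", "Simpson"))
  out <- as_tibble(rich)
  out$sample_id <- phyloseq::sample_names(physeq)
  out[, c("sample_id", setdiff(names(out), "sample_id"))]
}
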