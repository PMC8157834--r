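# Fixture builders and independent oracles shared across tests.

# Random sparse count table with a crosstalk-like mixture of magnitudes:
# zeros, low counts (candidate leaks) and high counts (true abundances).
random_table <- function(n_features, n_samples, seed = NULL) {
  gen <- function() {
    n <- n_features * n_samples
    kind <- sample(c("zero", "low", "high"), n, replace = TRUE,
                   prob = c(0.45, 0.3, 0.25))
    v <- integer(n)
    v[kind == "low"] <- sample.int(5L, sum(kind == "low"), replace = TRUE)
    v[kind == "high"] <- sample.int(5000L, sum(kind == "high"), replace = TRUE) + 50L
    feature_table(matrix(v, nrow = n_features, ncol = n_samples,
                         dimnames = list(if (n_features) sprintf("f%03d", seq_len(n_features)),
                                         sprintf("s%02d", seq_len(n_samples)))))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Brute-force crosstalk filter: evaluates the expected-leak model
# entry-by-entry with explicit loops, independent of the package's
# vectorized implementation.
oracle_remove_crosstalk <- function(tbl, gamma = 0.01, tau = 1 / 3,
                                    max_row_loss = 0.1, min_total = 1L) {
  m <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  n <- ncol(m)
  for (i in seq_len(nrow(m))) {
    total <- 0L
    for (j in seq_len(n)) total <- total + m[i, j]
    if (total == 0L || total < min_total) next
    e <- gamma * total / n
    flag <- logical(n)
    loss <- 0L
    for (j in seq_len(n)) {
      x <- m[i, j]
      if (x > 0L && e / (e + x) >= tau) {
        flag[j] <- TRUE
        loss <- loss + x
      }
    }
    if (loss > max_row_loss * total) next
    for (j in seq_len(n)) if (flag[j]) m[i, j] <- 0L
  }
  out <- tbl
  for (j in seq_len(n)) out[[j + 1]] <- unname(m[, j])
  out
}

# Bit-length log2 floor: repeated integer halving, no floating point.
oracle_log2_bin <- function(count) {
  k <- -1L
  while (count >= 1L) {
    count <- count %/% 2L
    k <- k + 1L
  }
  k
}

# Small three-feature dataset with taxonomy and metadata.
tiny_dataset <- function() {
  tbl <- feature_table(matrix(c(10L, 0L, 3L, 5L, 2L, 7L), 3,
                              dimnames = list(c("asv1", "asv2", "asv3"),
                                              c("S1", "S2"))))
  seqs <- tibble::tibble(feature_id = c("asv1", "asv2", "asv3"),
                         sequence = c("ACGTACGTAA", "TTGGCCAATT", "GGGTTTAAAC"))
  tax <- tibble::tibble(
    feature_id = c("asv1", "asv2", "asv3"),
    Kingdom = "Bacteria", Phylum = "Firmicutes", Class = "Bacilli",
    Order = "Lactobacillales", Family = "Lactobacillaceae",
    Genus = c("Lactobacillus", "Pediococcus", ""),
    Species = c("", "acidilactici", ""))
  meta <- tibble::tibble(sample_id = c("S1", "S2"),
                         group = c("treatment", "control"))
  asv_dataset(tbl, seqs, tax, meta)
}

cli_script <- function() {
  system.file("scripts", "asvpost.R", package = "asvpost")
}

# Subprocesses must see the library this package is installed in.
cli_status <- function(args) {
  suppressWarnings(system2(
    "Rscript", c(cli_script(), args), stdout = FALSE, stderr = FALSE,
    env = paste0("R_LIBS=", shQuote(paste(.libPaths(), collapse = ":")))))
}
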