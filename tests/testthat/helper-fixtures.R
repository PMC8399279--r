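# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_env <- new.env()

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# The reference study-condition dataset: compositional bias 3 on R/Y/G/K,
# 200 peptides per class, generator seed 7.
study_dataset <- function() {
  memo("ds200", generate_dataset(n_pos = 200, n_neg = 200, seed = 7))
}

study_features <- function() {
  memo("feats200", featurize_all(study_dataset()))
}

study_labels <- function() {
  ifelse(study_features()$labels == "positive", 1L, 0L)
}

# A small trained bundle for the application-module tests.
small_bundle <- function() {
  memo("bundle60", {
    ds <- generate_dataset(n_pos = 60, n_neg = 60, seed = 3)
    suppressMessages(
      b3pp_pipeline(ds, C = 0.01, top_k = 10, model = "rf", seed = 1))$bundle
  })
}

# Brute-force k-mer counting oracle: enumerate every window with substring.
oracle_kmer <- function(seq, k) {
  L <- nchar(seq)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  kmers <- do.call(paste0, rev(expand.grid(rep(list(aa), k),
                                           stringsAsFactors = FALSE)))
  v <- stats::setNames(numeric(length(kmers)), kmers)
  if (L < k) return(v)
  wins <- substring(seq, 1:(L - k + 1), k:L)
  tab <- table(wins)
  v[names(tab)] <- as.numeric(tab) / (L - k + 1) * 100
  v
}

random_peptide <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
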