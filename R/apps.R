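## apps: the three application modules (predict, design, scan) plus the
## compositional and positional (two-sample-logo) analyses.

bundle_scores <- function(bundle, records) {
  if (length(bundle$features) == 0) return(rep(0.5, nrow(records)))
  feats <- featurize_all(records, bundle$feature_config)
  predict(bundle$model, feats$values[, bundle$features, drop = FALSE])
}

#' Score peptides with a trained bundle
#'
#' One row per input record, input order preserved; scores are
#' deterministic given the bundle. Peptides outside the model's 6-30
#' residue training regime are still scored, with a warning.
#'
#' @param bundle a `b3pp_bundle` (from [b3pp_pipeline()]).
#' @param records peptide set data.frame (or a FASTA path).
#' @param threshold optional threshold override (default: the bundle's).
#' @return data.frame(id, seq, score, label) with label = "positive" iff
#'   score >= threshold.
#' @export
predict_peptides <- function(bundle, records, threshold = NULL) {
  if (is.character(records) && length(records) == 1 && file.exists(records)) {
    records <- read_fasta(records)
  }
  thr <- if (is.null(threshold)) bundle$threshold else threshold
  L <- nchar(records$seq)
  if (any(L < 6 | L > 30)) {
    warning(sum(L < 6 | L > 30), " peptide(s) outside the 6-30 residue ",
            "training regime; scores may be unreliable")
  }
  score <- bundle_scores(bundle, records)
  data.frame(id = records$id, seq = records$seq, score = score,
             label = ifelse(score >= thr, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' @export
predict.b3pp_bundle <- function(object, records, threshold = NULL, ...) {
  predict_peptides(object, records, threshold)
}

#' Exhaustive single-residue mutagenesis (design module)
#'
#' Emits the parent peptide plus every single-position substitution to
#' each of the 19 alternative residues - exactly 19L + 1 rows - scored
#' with the bundle and sorted by decreasing score (ties broken by
#' position, then residue, so the order is stable). The parent row
#' carries position 0.
#'
#' @param parent parent peptide sequence.
#' @param bundle a `b3pp_bundle`.
#' @return data.frame(analog, position, residue, score), best first.
#' @export
design_analogs <- function(parent, bundle) {
  parent <- peptide_set("parent", parent)$seq
  L <- nchar(parent)
  ch <- strsplit(parent, "")[[1]]
  pos <- integer(0); res <- character(0); seqs <- character(0)
  for (i in seq_len(L)) {
    for (a in setdiff(AA20, ch[i])) {
      s <- ch; s[i] <- a
      pos <- c(pos, i); res <- c(res, a)
      seqs <- c(seqs, paste(s, collapse = ""))
    }
  }
  tab <- data.frame(analog = c(parent, seqs),
                    position = c(0L, pos),
                    residue = c(substr(parent, 1, 1)[NA], res),
                    score = NA_real_, stringsAsFactors = FALSE)
  tab$residue[1] <- NA_character_
  recs <- peptide_set(paste0("analog", seq_len(nrow(tab))), tab$analog)
  tab$score <- bundle_scores(bundle, recs)
  tab[order(-tab$score, tab$position, tab$residue), , drop = FALSE]
}

#' Sliding-window scan of a protein (scan module)
#'
#' Scores every overlapping window of width `w` (step 1), covering start
#' positions 1..L-w+1; coordinates are 1-based inclusive.
#'
#' @param protein protein sequence (or single-record peptide set).
#' @param bundle a `b3pp_bundle`.
#' @param w window width (default 15, >= 6); must not exceed the protein
#'   length.
#' @param id parent protein identifier for the output.
#' @return data.frame(parent, start, end, window, score).
#' @export
scan_protein <- function(protein, bundle, w = 15, id = "protein") {
  if (is.data.frame(protein)) {
    id <- protein$id[1]
    protein <- protein$seq[1]
  }
  protein <- peptide_set(id, protein)$seq
  L <- nchar(protein)
  stopifnot(w >= 6)
  if (w > L) stop("window (", w, ") exceeds protein length (", L, ")")
  starts <- seq_len(L - w + 1)
  windows <- substring(protein, starts, starts + w - 1)
  recs <- peptide_set(paste0(id, "_", starts), windows)
  data.frame(parent = id, start = starts, end = starts + w - 1L,
             window = windows, score = bundle_scores(bundle, recs),
             stringsAsFactors = FALSE)
}

#' Mean amino-acid composition per peptide set
#'
#' For each named set, the arithmetic mean of the per-peptide AAC
#' vectors; each column sums to 100. Suitable for a grouped composition
#' bar chart comparing, e.g., B3PPs, CPPs and random peptides.
#'
#' @param sets named list of peptide set data.frames.
#' @return data.frame: 20 rows (residue) x one column per set.
#' @export
composition_compare <- function(sets) {
  stopifnot(length(names(sets)) == length(sets), all(nzchar(names(sets))))
  out <- vapply(sets, function(records) {
    stopifnot(nrow(records) > 0)
    rowMeans(vapply(records$seq, aac, numeric(20)))
  }, numeric(20))
  data.frame(residue = AA20, out, row.names = NULL)
}

#' Terminal 10-mers for two-sample-logo analysis
#'
#' Concatenates the first five and last five residues of each peptide
#' (overlap permitted for lengths 5-9), giving a fixed-length 10-mer per
#' record. Records shorter than five residues are an error.
#'
#' @param records peptide set data.frame.
#' @return character vector of 10-mers.
#' @export
tsl_prepare <- function(records) {
  L <- nchar(records$seq)
  if (any(L < 5)) {
    stop("tsl_prepare: record(s) shorter than 5 residues: ",
         paste(records$id[L < 5], collapse = ", "))
  }
  paste0(substr(records$seq, 1, 5),
         substr(records$seq, L - 4, L))
}

#' Positional residue enrichment between two 10-mer sets
#'
#' Per position (1-10) and residue, compares the positive-set and
#' negative-set frequencies with a two-proportion test (pooled chi-square
#' without continuity correction, or Fisher's exact test when any
#' expected count is below 5). Cells with p < alpha are flagged
#' "enriched" (positive difference) or "depleted" (negative difference).
#'
#' @param pos,neg character vectors of 10-mers (from [tsl_prepare()]).
#' @param alpha significance level (default 0.05).
#' @param bonferroni apply Bonferroni correction over the 200 cells.
#' @return data.frame(position, residue, freq_pos, freq_neg, enrichment,
#'   p_value, flag).
#' @export
tsl_enrichment <- function(pos, neg, alpha = 0.05, bonferroni = FALSE) {
  stopifnot(length(pos) > 0, length(neg) > 0,
            all(nchar(c(pos, neg)) == 10))
  n1 <- length(pos); n2 <- length(neg)
  out <- expand.grid(position = 1:10, residue = AA20,
                     stringsAsFactors = FALSE)
  out <- out[order(out$position, out$residue), ]
  rownames(out) <- NULL
  k1 <- k2 <- pval <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    a1 <- sum(substr(pos, out$position[i], out$position[i]) == out$residue[i])
    a2 <- sum(substr(neg, out$position[i], out$position[i]) == out$residue[i])
    k1[i] <- a1; k2[i] <- a2
    m <- matrix(c(a1, n1 - a1, a2, n2 - a2), 2)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    pval[i] <- if (any(expected < 5)) {
      stats::fisher.test(m)$p.value
    } else {
      suppressWarnings(
        stats::prop.test(c(a1, a2), c(n1, n2), correct = FALSE)$p.value)
    }
  }
  out$freq_pos <- k1 / n1
  out$freq_neg <- k2 / n2
  out$enrichment <- out$freq_pos - out$freq_neg
  out$p_value <- pval
  cut <- if (bonferroni) alpha / nrow(out) else alpha
  out$flag <- ifelse(out$p_value < cut & out$enrichment != 0,
                     ifelse(out$enrichment > 0, "enriched", "depleted"),
                     "none")
  out
}
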