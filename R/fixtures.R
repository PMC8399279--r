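## fixtures: synthetic labelled peptide datasets with the compositional
## signal structure reported for real B3PPs (enrichment of R, Y, G, K in
## the positive class), so that every pipeline stage is testable without
## any external download.

#' Generate a synthetic labelled peptide dataset
#'
#' Positives are drawn i.i.d. per residue from a 20-way distribution in
#' which `bias_residues` are up-weighted by `bias_strength` (then
#' renormalized); negatives are uniform over the 20 residues. Lengths are
#' uniform on `length_range` (default 6-30). Sequences are unique within
#' and across classes (rejection sampling, at most 100 retries per
#' peptide) and generation is a pure function of the configuration,
#' including the seed. With `bias_strength = 1` the two classes are
#' exchangeable (a permutation null). The optional positional mode
#' additionally plants a fixed R/Y/G motif at the three N-terminal
#' positions of the positives, to exercise the positional-enrichment
#' analysis.
#'
#' @param n_pos,n_neg class sizes (>= 1).
#' @param seed integer seed.
#' @param bias_residues residues enriched in positives (default R, Y, G, K).
#' @param bias_strength relative sampling weight multiplier (>= 1;
#'   default 3).
#' @param length_range inclusive length bounds (default c(6, 30)).
#' @param positional_motif plant an N-terminal "RYG" motif in positives.
#' @param name dataset name.
#' @return a `b3pp_dataset`.
#' @export
generate_dataset <- function(n_pos, n_neg, seed = 7,
                             bias_residues = c("R", "Y", "G", "K"),
                             bias_strength = 3, length_range = c(6, 30),
                             positional_motif = FALSE, name = "synthetic") {
  stopifnot(n_pos >= 1, n_neg >= 1, bias_strength >= 1,
            length_range[1] >= 1, length_range[2] >= length_range[1],
            all(bias_residues %in% AA20))
  w_pos <- rep(1, 20)
  w_pos[match(bias_residues, AA20)] <- bias_strength
  w_pos <- w_pos / sum(w_pos)
  w_neg <- rep(1 / 20, 20)
  with_seed(seed, {
    seen <- character(0)
    draw <- function(n, w, motif) {
      out <- character(n)
      for (i in seq_len(n)) {
        for (try in seq_len(100)) {
          L <- sample(length_range[1]:length_range[2], 1)
          s <- paste(sample(AA20, L, replace = TRUE, prob = w),
                     collapse = "")
          if (motif) s <- paste0("RYG", substr(s, 4, L))
          if (!(s %in% seen)) break
          if (try == 100) stop("could not generate a unique peptide")
        }
        seen <<- c(seen, s)
        out[i] <- s
      }
      out
    }
    pos <- draw(n_pos, w_pos, positional_motif)
    neg <- draw(n_neg, w_neg, FALSE)
  })
  structure(list(
    positives = peptide_set(paste0("pos", seq_len(n_pos)), pos, "positive"),
    negatives = peptide_set(paste0("neg", seq_len(n_neg)), neg, "negative"),
    name = name,
    ratio = n_neg / n_pos),
    class = "b3pp_dataset")
}
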