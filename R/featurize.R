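## featurize: the fifteen composition-based descriptor families making up
## the pinned 9,189-dimensional feature vector.
##
## Family block sizes under the default configuration:
##   AAC 20, DPC 400, TPC 8000, ABC 9, RRI 20, DDOR 20, SE 1, SER 20,
##   SEP 25, CTD 343, CeTD 147, PAAC 24, APAAC 28, QSO 86, SOCN 46
## which sum to 9,189. The manifest (feature_manifest) is the contract:
## descriptor order never changes within a manifest version. The
## per-family numeric cores live in featurize_internal.R.

MANIFEST_VERSION <- "1.0"

#' Descriptor configuration
#'
#' Houses the lag/weight parameters of the order-aware families. The
#' defaults (lambda = 4 for PAAC/APAAC, lag 23 for QSO/SOCN) pin the total
#' manifest length at exactly 9,189 descriptors. Lags or lambdas that
#' exceed a peptide's length contribute exact zeros.
#'
#' @param paac_lambda,apaac_lambda number of pseudo-composition lags.
#' @param paac_weight weight w of the sequence-order terms (PAAC/APAAC).
#' @param qso_lag,socn_lag maximum coupling lag for QSO and SOCN.
#' @param qso_weight weight w of the QSO coupling terms.
#' @param scale_percent report AAC/DPC/TPC (and CeTD) as percentages.
#' @return list of class `b3pp_feature_config`.
#' @export
feature_config <- function(paac_lambda = 4, apaac_lambda = 4,
                           paac_weight = 0.05, qso_lag = 23,
                           qso_weight = 0.1, socn_lag = 23,
                           scale_percent = TRUE) {
  stopifnot(paac_lambda >= 0, apaac_lambda >= 0, paac_weight > 0,
            qso_lag >= 1, socn_lag >= 1, qso_weight > 0)
  structure(list(paac_lambda = paac_lambda, apaac_lambda = apaac_lambda,
                 paac_weight = paac_weight, qso_lag = qso_lag,
                 qso_weight = qso_weight, socn_lag = socn_lag,
                 scale_percent = scale_percent),
            class = "b3pp_feature_config")
}

seq_to_idx <- function(seq) {
  idx <- match(strsplit(seq, "")[[1]], AA20)
  if (anyNA(idx)) stop("sequence contains non-standard residues: ", seq)
  idx
}

check_seq <- function(seq, fn) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq)) {
    stop(fn, ": need one non-empty sequence")
  }
  seq_to_idx(seq)
}

#' Amino-acid composition (percent)
#'
#' Component i is the count of residue i divided by the total number of
#' residues, times 100; components sum to 100.
#'
#' @param seq a peptide sequence (length >= 1).
#' @return named 20-vector (residues in order ACDEFGHIKLMNPQRSTVWY).
#' @export
aac <- function(seq) {
  idx <- check_seq(seq, "aac")
  stats::setNames(tabulate(idx, 20) / length(idx) * 100,
                  paste0("AAC_", AA20))
}

#' k-mer (dipeptide/tripeptide) composition (percent)
#'
#' Overlapping k-mer counts divided by L-k+1, times 100; k-mers are ordered
#' lexicographically over the alphabetical residue order. Sequences shorter
#' than k yield an all-zero vector with a warning.
#'
#' @param seq a peptide sequence.
#' @param k 2 (dipeptide, 400 columns) or 3 (tripeptide, 8000 columns).
#' @return named 20^k vector.
#' @export
kmer_composition <- function(seq, k) {
  stopifnot(k %in% c(2, 3))
  fam <- if (k == 2) "DPC" else "TPC"
  idx <- check_seq(seq, "kmer_composition")
  if (length(idx) < k) {
    warning("kmer_composition: sequence shorter than k; returning zeros")
  }
  stats::setNames(kmer_raw(idx, k), paste0(fam, "_", kmer_names(k)))
}

#' Atom and bond composition
#'
#' Atom components are the fractions of C, H, N, O and S atoms summed over
#' a fixed per-residue atom table (free amino-acid formulae); they sum to 1.
#' Bond components are the total-bond density (bonds per atom) and the
#' single/double/aromatic fractions of total bonds.
#'
#' @param seq a peptide sequence (length >= 1).
#' @return named 9-vector.
#' @export
abc <- function(seq) {
  idx <- check_seq(seq, "abc")
  stats::setNames(abc_raw(idx),
                  paste0("ABC_", c("atom_C", "atom_H", "atom_N", "atom_O",
                                   "atom_S", "bond_total", "bond_single",
                                   "bond_double", "bond_aromatic")))
}

#' Residue-repeat information
#'
#' For residue type i with maximal runs of lengths r1..rm,
#' RRI_i = sum(r_j^2) / L; 0 when i is absent.
#'
#' @param seq a peptide sequence (length >= 1).
#' @return named 20-vector.
#' @export
rri <- function(seq) {
  idx <- check_seq(seq, "rri")
  stats::setNames(rri_raw(idx), paste0("RRI_", AA20))
}

#' Distance distribution of residues
#'
#' For residue i at 1-based positions p1 < ... < pk,
#' DDOR_i = sum of squared successive gaps / k; 0 when k < 2.
#'
#' @param seq a peptide sequence (length >= 1).
#' @return named 20-vector.
#' @export
ddor <- function(seq) {
  idx <- check_seq(seq, "ddor")
  stats::setNames(ddor_raw(idx), paste0("DDOR_", AA20))
}

#' Shannon entropy families (SE, SER, SEP)
#'
#' SE is the Shannon entropy (bits) of the residue frequency distribution;
#' SER_i = -p_i log2 p_i per residue type; SEP_t is the binary entropy of
#' the fraction of residues holding physicochemical property t, for the 25
#' shipped binary properties.
#'
#' @param seq a peptide sequence (length >= 1).
#' @return named 46-vector: SE, 20 SER components, 25 SEP components.
#' @export
entropy_features <- function(seq) {
  idx <- check_seq(seq, "entropy_features")
  stats::setNames(entropy_raw(idx),
                  c("SE", paste0("SER_", AA20),
                    paste0("SEP_", colnames(sep_membership()))))
}

triad_class_map <- function() {
  tab <- b3pp_table("triad")
  cls <- integer(20)
  names(cls) <- AA20
  for (i in seq_len(nrow(tab))) {
    cls[strsplit(tab$residues[i], "")[[1]]] <- tab$class[i]
  }
  cls
}

#' Conjoint-triad composition
#'
#' Residues are mapped to the 7-class conjoint-triad alphabet
#' ({AGV},{ILFP},{YMTS},{HNQW},{RK},{DE},{C}); the component for class
#' triad (a,b,c) is the count of overlapping class triads divided by L-2.
#' Ordering is row-major over class indices. Sequences shorter than 3
#' yield zeros with a warning.
#'
#' @param seq a peptide sequence.
#' @return named 343-vector.
#' @export
ctd_triad <- function(seq) {
  idx <- check_seq(seq, "ctd_triad")
  if (length(idx) < 3) {
    warning("ctd_triad: sequence shorter than 3; returning zeros")
  }
  grid <- expand.grid(c = 1:7, b = 1:7, a = 1:7)
  stats::setNames(ctd_raw(idx), paste0("CTD_", grid$a, grid$b, grid$c))
}

#' Composition/transition/distribution descriptors
#'
#' Classic three-class CTD over seven physicochemical attributes
#' (hydrophobicity, van der Waals volume, polarity, polarizability, charge,
#' secondary structure, solvent accessibility). Per attribute: 3 class
#' compositions (percent), 3 adjacent unordered class-pair transition
#' frequencies (percent of L-1 adjacent pairs) and, for each class, the
#' percent sequence position of its first, 25\%, 50\%, 75\% and last
#' occurrence (0 when the class is absent) - 21 values per attribute,
#' 147 in total, all in [0, 100].
#'
#' @param seq a peptide sequence (length >= 1; transitions are 0 for
#'   single-residue input).
#' @return named 147-vector.
#' @export
cetd <- function(seq) {
  idx <- check_seq(seq, "cetd")
  nm <- unlist(lapply(names(cetd_classes()), function(attr)
    paste0("CeTD_", attr, "_",
           c(paste0("C", 1:3), paste0("T", c("12", "13", "23")),
             paste0("D", rep(1:3, each = 5), "_p",
                    rep(c(0, 25, 50, 75, 100), 3))))))
  stats::setNames(cetd_raw(idx), nm)
}

paac_theta <- function(idx, lambda, pairwise) {
  # pairwise: 20 x 20 matrix of residue-pair correlation values
  L <- length(idx)
  vapply(seq_len(lambda), function(d) {
    if (d >= L) return(0)
    mean(pairwise[cbind(idx[1:(L - d)], idx[(1 + d):L])])
  }, numeric(1))
}

#' Pseudo amino-acid composition (Chou)
#'
#' First 20 components f_i / (1 + w * sum(theta)); last lambda components
#' w * theta_d / (1 + w * sum(theta)), where theta_d is the mean over
#' residue pairs at lag d of the mean squared difference of three
#' standardized property scales (hydrophobicity, hydrophilicity,
#' side-chain mass). The vector sums to 1. Lags >= L contribute 0.
#'
#' @param seq a peptide sequence (length >= 1).
#' @param lambda number of lags (default 4).
#' @param w sequence-order weight (default 0.05).
#' @return named (20 + lambda)-vector.
#' @export
paac <- function(seq, lambda = 4, w = 0.05) {
  idx <- check_seq(seq, "paac")
  stats::setNames(paac_raw(idx, lambda, w),
                  c(paste0("PAAC_", AA20),
                    if (lambda > 0) paste0("PAAC_lam", seq_len(lambda))))
}

#' Amphiphilic pseudo amino-acid composition
#'
#' As [paac()], but with two correlation terms per lag: the mean product of
#' standardized hydrophobicity values and of standardized hydrophilicity
#' values at lag d. The vector sums to 1.
#'
#' @inheritParams paac
#' @return named (20 + 2*lambda)-vector.
#' @export
apaac <- function(seq, lambda = 4, w = 0.05) {
  idx <- check_seq(seq, "apaac")
  stats::setNames(apaac_raw(idx, lambda, w),
                  c(paste0("APAAC_", AA20),
                    if (lambda > 0)
                      paste0("APAAC_", rep(c("hb", "hl"), lambda),
                             rep(seq_len(lambda), each = 2))))
}

#' Sequence-order coupling numbers
#'
#' SOCN component d (d = 1..g) is the sum over positions t of the squared
#' inter-residue distance dist(r_t, r_{t+d}), computed once for each of the
#' two shipped distance matrices (package physicochemical "PC" and
#' Grantham "G", both max-normalized). Lags >= L contribute exact zeros;
#' homopolymers give the zero vector.
#'
#' @param seq a peptide sequence (length >= 1).
#' @param g maximum lag (default 23).
#' @return named 2g-vector.
#' @export
socn <- function(seq, g = 23) {
  idx <- check_seq(seq, "socn")
  stats::setNames(socn_raw(idx, g),
                  unlist(lapply(c("PC", "G"), function(x)
                    paste0("SOCN_", x, "_", seq_len(g)))))
}

#' Quasi-sequence-order descriptors
#'
#' Per distance matrix: 20 residue terms f_i / (1 + w * sum(tau)) followed
#' by g coupling terms w * tau_d / (1 + w * sum(tau)), with tau_d the
#' sequence-order coupling numbers of [socn()].
#'
#' @param seq a peptide sequence (length >= 1).
#' @param g maximum lag (default 23).
#' @param w coupling weight (default 0.1).
#' @return named 2(20+g)-vector.
#' @export
qso <- function(seq, g = 23, w = 0.1) {
  idx <- check_seq(seq, "qso")
  stats::setNames(qso_raw(idx, g, w),
                  unlist(lapply(c("PC", "G"), function(x)
                    c(paste0("QSO_", x, "_", AA20),
                      paste0("QSO_", x, "_lag", seq_len(g))))))
}

#' The ordered descriptor manifest
#'
#' Enumerates every descriptor name with its family, in the fixed
#' concatenation order used by [featurize_all()]. Under the default
#' configuration the manifest has exactly 9,189 entries.
#'
#' @param config a [feature_config()].
#' @return data.frame with columns index, name, family; attribute
#'   `version` carries the manifest version.
#' @export
feature_manifest <- function(config = feature_config()) {
  mn <- manifest_names(config)
  m <- data.frame(index = seq_along(mn$names), name = mn$names,
                  family = mn$family, stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(m$name))
  attr(m, "version") <- MANIFEST_VERSION
  m
}

feature_vector <- function(seq, config = feature_config()) {
  idx <- seq_to_idx(seq)
  ent <- entropy_raw(idx)
  socn_v <- socn_raw(idx, config$socn_lag)
  qso_tau <- if (config$qso_lag == config$socn_lag) socn_v else NULL
  pct <- if (config$scale_percent) 1 else 1 / 100
  v <- c(tabulate(idx, 20) / length(idx) * 100 * pct,
         kmer_raw(idx, 2) * pct,
         kmer_raw(idx, 3) * pct,
         abc_raw(idx),
         rri_raw(idx),
         ddor_raw(idx),
         ent,
         ctd_raw(idx),
         cetd_raw(idx) * pct,
         paac_raw(idx, config$paac_lambda, config$paac_weight),
         apaac_raw(idx, config$apaac_lambda, config$paac_weight),
         qso_raw(idx, config$qso_lag, config$qso_weight, qso_tau),
         socn_v)
  names(v) <- manifest_names(config)$names
  v
}

#' Compute the full descriptor matrix for a peptide set
#'
#' Concatenates all fifteen family blocks in manifest order; deterministic
#' (the same input yields bit-identical output) and row order follows input
#' order. Under the default configuration each row has exactly 9,189
#' finite values.
#'
#' @param records peptide set data.frame (or a `b3pp_dataset`).
#' @param config a [feature_config()].
#' @return object of class `b3pp_features`: list(values = numeric matrix
#'   peptides x descriptors with rownames = ids, manifest, config, ids,
#'   labels).
#' @export
featurize_all <- function(records, config = feature_config()) {
  if (inherits(records, "b3pp_dataset")) records <- dataset_records(records)
  manifest <- feature_manifest(config)
  vals <- matrix(0, nrow(records), nrow(manifest),
                 dimnames = list(records$id, manifest$name))
  for (i in seq_len(nrow(records))) {
    v <- tryCatch(feature_vector(records$seq[i], config),
                  error = function(e) {
                    stop("featurize failed for '", records$id[i], "': ",
                         conditionMessage(e))
                  })
    vals[i, ] <- v
  }
  stopifnot(all(is.finite(vals)))
  structure(list(values = vals, manifest = manifest, config = config,
                 ids = records$id, labels = records$label),
            class = "b3pp_features")
}

#' @export
print.b3pp_features <- function(x, ...) {
  cat("b3pp_features: ", nrow(x$values), " peptides x ", ncol(x$values),
      " descriptors (manifest v", attr(x$manifest, "version"), ")\n", sep = "")
  invisible(x)
}
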