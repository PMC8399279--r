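## Internal fast paths for featurize: unnamed per-family cores operating on
## residue index vectors, with all static lookup tables cached. The
## exported family functions wrap these cores and attach descriptor names;
## feature_vector() assembles the raw cores and names the result once from
## the cached manifest.

kmer_names <- function(k) {
  key <- paste0("kmer_names_", k)
  if (is.null(.b3pp_env[[key]])) {
    .b3pp_env[[key]] <- do.call(paste0, rev(expand.grid(
      rep(list(AA20), k), stringsAsFactors = FALSE)))
  }
  .b3pp_env[[key]]
}

kmer_raw <- function(idx, k) {
  n <- length(idx) - k + 1
  if (n < 1) return(numeric(20^k))
  code <- idx[1:n]
  for (j in 2:k) code <- (code - 1L) * 20L + idx[j:(n + j - 1)]
  tabulate(code, 20^k) / n * 100
}

atom_bond_cache <- function() {
  if (is.null(.b3pp_env$atom_bond_mat)) {
    .b3pp_env$atom_bond_mat <- as.matrix(b3pp_table("atom_bond")[AA20, ])
  }
  .b3pp_env$atom_bond_mat
}

abc_raw <- function(idx) {
  counts <- colSums(atom_bond_cache()[idx, , drop = FALSE])
  atoms <- counts[1:5]
  unname(c(atoms / sum(atoms), counts["bonds_total"] / sum(atoms),
           counts[c("bonds_single", "bonds_double", "bonds_aromatic")] /
             counts["bonds_total"]))
}

rri_raw <- function(idx) {
  v <- numeric(20)
  r <- rle(idx)
  for (i in seq_along(r$values)) {
    v[r$values[i]] <- v[r$values[i]] + r$lengths[i]^2
  }
  v / length(idx)
}

ddor_raw <- function(idx) {
  v <- numeric(20)
  for (a in unique(idx)) {
    p <- which(idx == a)
    if (length(p) >= 2) v[a] <- sum(diff(p)^2) / length(p)
  }
  v
}

sep_membership <- function() {
  if (is.null(.b3pp_env$sep_mat)) {
    props <- b3pp_table("sep_properties")
    m <- vapply(strsplit(props$residues, ""),
                function(set) AA20 %in% set, logical(20))
    dimnames(m) <- list(AA20, props$property)
    .b3pp_env$sep_mat <- m
  }
  .b3pp_env$sep_mat
}

entropy_raw <- function(idx) {
  plogp <- function(p) ifelse(p > 0, -p * log2(p), 0)
  p <- tabulate(idx, 20) / length(idx)
  ser <- plogp(p)
  q <- colMeans(sep_membership()[idx, , drop = FALSE])
  c(sum(ser), ser, plogp(q) + plogp(1 - q))
}

ctd_raw <- function(idx) {
  if (length(idx) < 3) return(numeric(343))
  cls <- triad_class_cache()[idx]
  n <- length(idx) - 2
  code <- (cls[1:n] - 1L) * 49L + (cls[2:(n + 1)] - 1L) * 7L + cls[3:(n + 2)]
  tabulate(code, 343) / n
}

triad_class_cache <- function() {
  if (is.null(.b3pp_env$triad_cls)) .b3pp_env$triad_cls <- triad_class_map()
  .b3pp_env$triad_cls
}

cetd_classes <- function() {
  if (is.null(.b3pp_env$cetd_cls)) {
    tab <- b3pp_table("cetd")
    attrs <- unique(tab$attribute)
    .b3pp_env$cetd_cls <- lapply(attrs, function(attr) {
      sub <- tab[tab$attribute == attr, ]
      cls <- integer(20)
      for (i in seq_len(nrow(sub))) {
        cls[match(strsplit(sub$residues[i], "")[[1]], AA20)] <- sub$class[i]
      }
      cls
    })
    names(.b3pp_env$cetd_cls) <- attrs
  }
  .b3pp_env$cetd_cls
}

cetd_raw <- function(idx) {
  L <- length(idx)
  qprobs <- c(1e-9, 0.25, 0.5, 0.75, 1)
  out <- numeric(147)
  o <- 0L
  for (cls in cetd_classes()) {
    a <- cls[idx]
    out[o + 1:3] <- tabulate(a, 3) / L * 100
    if (L >= 2) {
      lo <- pmin(a[-L], a[-1]); hi <- pmax(a[-L], a[-1])
      out[o + 4] <- sum(lo == 1 & hi == 2)
      out[o + 5] <- sum(lo == 1 & hi == 3)
      out[o + 6] <- sum(lo == 2 & hi == 3)
      out[o + 4:6] <- out[o + 4:6] / (L - 1) * 100
    }
    for (cl in 1:3) {
      p <- which(a == cl)
      if (length(p) > 0) {
        qi <- pmax(1, ceiling(qprobs * length(p)))
        out[o + 6 + (cl - 1) * 5 + 1:5] <- p[qi] / L * 100
      }
    }
    o <- o + 21L
  }
  out
}

paac_pairwise <- function() {
  if (is.null(.b3pp_env$paac_pair)) {
    sc <- b3pp_table("paac_scales")[AA20, ]
    z <- vapply(sc, chou_standardize, numeric(20))
    .b3pp_env$paac_pair <- list(
      theta = Reduce(`+`, lapply(1:3, function(k)
        outer(z[, k], z[, k], "-")^2)) / 3,
      hb = outer(z[, 1], z[, 1]),
      hl = outer(z[, 2], z[, 2]))
  }
  .b3pp_env$paac_pair
}

paac_raw <- function(idx, lambda, w) {
  theta <- if (lambda > 0) paac_theta(idx, lambda, paac_pairwise()$theta)
           else numeric(0)
  f <- tabulate(idx, 20) / length(idx)
  denom <- 1 + w * sum(theta)
  c(f / denom, w * theta / denom)
}

apaac_raw <- function(idx, lambda, w) {
  tau <- numeric(2 * lambda)
  if (lambda > 0) {
    pw <- paac_pairwise()
    tau[seq(1, by = 2, length.out = lambda)] <- paac_theta(idx, lambda, pw$hb)
    tau[seq(2, by = 2, length.out = lambda)] <- paac_theta(idx, lambda, pw$hl)
  }
  f <- tabulate(idx, 20) / length(idx)
  denom <- 1 + w * sum(tau)
  c(f / denom, w * tau / denom)
}

qso_cache <- function() {
  if (is.null(.b3pp_env$qso_mats)) .b3pp_env$qso_mats <- qso_matrices()
  .b3pp_env$qso_mats
}

socn_raw <- function(idx, g) {
  L <- length(idx)
  mats <- qso_cache()
  unlist(lapply(mats, function(m) {
    vapply(seq_len(g), function(d) {
      if (d >= L) return(0)
      sum(m[cbind(idx[1:(L - d)], idx[(1 + d):L])]^2)
    }, numeric(1))
  }), use.names = FALSE)
}

qso_raw <- function(idx, g, w, tau_all = NULL) {
  if (is.null(tau_all)) tau_all <- socn_raw(idx, g)
  f <- tabulate(idx, 20) / length(idx)
  unlist(lapply(1:2, function(i) {
    tau <- tau_all[(i - 1) * g + seq_len(g)]
    denom <- 1 + w * sum(tau)
    c(f / denom, w * tau / denom)
  }), use.names = FALSE)
}

manifest_names <- function(config) {
  key <- paste0("manifest_", config$paac_lambda, "_", config$apaac_lambda,
                "_", config$qso_lag, "_", config$socn_lag)
  if (is.null(.b3pp_env[[key]])) {
    cetd_attrs <- names(cetd_classes())
    grid <- expand.grid(c = 1:7, b = 1:7, a = 1:7)[, 3:1]
    nm <- list(
      AAC = paste0("AAC_", AA20),
      DPC = paste0("DPC_", kmer_names(2)),
      TPC = paste0("TPC_", kmer_names(3)),
      ABC = paste0("ABC_", c("atom_C", "atom_H", "atom_N", "atom_O",
                             "atom_S", "bond_total", "bond_single",
                             "bond_double", "bond_aromatic")),
      RRI = paste0("RRI_", AA20),
      DDOR = paste0("DDOR_", AA20),
      SE = "SE",
      SER = paste0("SER_", AA20),
      SEP = paste0("SEP_", colnames(sep_membership())),
      CTD = paste0("CTD_", grid$a, grid$b, grid$c),
      CeTD = unlist(lapply(cetd_attrs, function(attr)
        paste0("CeTD_", attr, "_",
               c(paste0("C", 1:3), paste0("T", c("12", "13", "23")),
                 paste0("D", rep(1:3, each = 5), "_p",
                        rep(c(0, 25, 50, 75, 100), 3)))))),
      PAAC = c(paste0("PAAC_", AA20),
               if (config$paac_lambda > 0)
                 paste0("PAAC_lam", seq_len(config$paac_lambda))),
      APAAC = c(paste0("APAAC_", AA20),
                if (config$apaac_lambda > 0)
                  paste0("APAAC_", rep(c("hb", "hl"), config$apaac_lambda),
                         rep(seq_len(config$apaac_lambda), each = 2))),
      QSO = unlist(lapply(c("PC", "G"), function(x)
        c(paste0("QSO_", x, "_", AA20),
          paste0("QSO_", x, "_lag", seq_len(config$qso_lag))))),
      SOCN = unlist(lapply(c("PC", "G"), function(x)
        paste0("SOCN_", x, "_", seq_len(config$socn_lag))))
    )
    .b3pp_env[[key]] <- list(names = unlist(nm, use.names = FALSE),
                             family = rep(names(nm), lengths(nm)))
  }
  .b3pp_env[[key]]
}
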