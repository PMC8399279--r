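AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

test_that("amino-acid composition matches hand counts and sums to 100", {
  v <- aac("AAAAAA")
  expect_equal(unname(v["AAC_A"]), 100)
  expect_equal(sum(v), 100)

  v6 <- aac("ACDEFG")
  expect_equal(unname(v6[paste0("AAC_", c("A", "C", "D", "E", "F", "G"))]),
               rep(100 / 6, 6))
  expect_equal(sum(v6), 100, tolerance = 1e-9)

  expect_error(aac(""), "non-empty")
})

test_that("k-mer composition matches hand-counted examples", {
  v <- kmer_composition("AAA", 2)
  expect_equal(unname(v["DPC_AA"]), 100)
  expect_equal(sum(v != 0), 1)

  v2 <- kmer_composition("ARA", 2)
  expect_equal(unname(v2[c("DPC_AR", "DPC_RA")]), c(50, 50))

  v3 <- kmer_composition("ACDACD", 3)
  expect_equal(unname(v3[c("TPC_ACD", "TPC_CDA", "TPC_DAC")]), c(50, 25, 25))

  expect_warning(short <- kmer_composition("A", 2), "shorter than k")
  expect_true(all(short == 0))
})

test_that("AAC/DPC/TPC agree exactly with a brute-force window oracle", {
  set.seed(101)
  for (i in 1:40) {
    s <- random_peptide(sample(6:30, 1))
    expect_identical(unname(kmer_composition(s, 2)), unname(oracle_kmer(s, 2)))
    expect_identical(unname(kmer_composition(s, 3)), unname(oracle_kmer(s, 3)))
    counts <- table(factor(strsplit(s, "")[[1]], levels = AA))
    expect_equal(unname(aac(s)), as.numeric(counts) / nchar(s) * 100)
  }
})

test_that("atom/bond composition is scale-invariant and chemically sane", {
  expect_equal(abc("GGGG"), abc("G"))
  v <- abc("ACDEFG")
  expect_equal(sum(v[1:5]), 1, tolerance = 1e-12)
  expect_true(all(v[c("ABC_bond_single", "ABC_bond_double",
                      "ABC_bond_aromatic")] <= 1))
  expect_gt(abc("CCCC")["ABC_atom_S"], 0)
  expect_equal(unname(abc("AAAA")["ABC_atom_S"]), 0)
})

test_that("residue-repeat information follows the squared-run formula", {
  expect_equal(unname(rri("AAAA")["RRI_A"]), 4)      # one run of 4: 16/4
  v <- rri("ARAR")                                   # two unit runs each
  expect_equal(unname(v[c("RRI_A", "RRI_R")]), c(0.5, 0.5))
  expect_equal(unname(rri("ACACA")["RRI_W"]), 0)
})

test_that("residue distance distribution follows the squared-gap formula", {
  expect_equal(unname(ddor("ACCA")["DDOR_A"]), 4.5)  # gap 3, k = 2
  expect_equal(unname(ddor("AAAA")["DDOR_A"]), 0.75) # three unit gaps, k = 4
  expect_equal(unname(ddor("ACDEFG")["DDOR_C"]), 0)  # single occurrence
})

test_that("entropy families obey closed forms and bounds", {
  hom <- entropy_features("KKKKKK")
  expect_true(all(hom == 0))

  v <- entropy_features("ACDEFG")
  expect_equal(unname(v["SE"]), log2(6), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    e <- entropy_features(random_peptide(sample(6:30, 1)))
    expect_gte(unname(e["SE"]), 0)
    expect_lte(unname(e["SE"]), log2(20))
    expect_true(all(e >= 0))
  }
})

test_that("conjoint-triad composition uses the 7-class alphabet", {
  v <- ctd_triad("AAAAAA")        # A is class 1
  expect_equal(unname(v["CTD_111"]), 1)
  expect_equal(sum(v), 1)

  v2 <- ctd_triad("RKRKRK")       # R and K share class 5
  expect_equal(unname(v2["CTD_555"]), 1)

  set.seed(8)
  s <- random_peptide(20)
  expect_equal(sum(ctd_triad(s)), 1, tolerance = 1e-12)
})

test_that("CeTD distribution and transition blocks behave as defined", {
  # "AD" under the charge attribute: A neutral (class 2), D negative (3)
  v <- cetd("AD")
  expect_equal(unname(v["CeTD_charge_C2"]), 50)
  expect_equal(unname(v["CeTD_charge_C3"]), 50)
  expect_equal(unname(v["CeTD_charge_T23"]), 100)
  expect_equal(unname(v["CeTD_charge_T12"]), 0)

  hom <- cetd("AAAAAAAA")   # single class per attribute
  expect_true(all(hom >= 0 & hom <= 100))
  expect_equal(unname(hom["CeTD_charge_C2"]), 100)
  expect_equal(unname(hom["CeTD_charge_T12"]), 0)
  expect_equal(unname(hom["CeTD_charge_D2_p100"]), 100)

  set.seed(9)
  for (i in 1:15) {
    x <- cetd(random_peptide(sample(6:30, 1)))
    expect_true(all(x >= 0 & x <= 100))
    # distribution 5-tuples are non-decreasing within each class
    dvals <- matrix(x[grep("_D[123]_p", names(x))], nrow = 5)
    expect_true(all(apply(dvals, 2, function(col) all(diff(col) >= 0))))
  }
})

test_that("pseudo amino-acid composition is a unit-sum vector", {
  hom <- paac("AAAAAA")
  expect_equal(unname(hom["PAAC_A"]), 1)
  expect_true(all(hom[paste0("PAAC_lam", 1:4)] == 0))

  set.seed(10)
  for (i in 1:20) {
    s <- random_peptide(sample(6:30, 1))
    expect_equal(sum(paac(s)), 1, tolerance = 1e-9)
    expect_equal(sum(apaac(s)), 1, tolerance = 1e-9)
    expect_true(all(paac(s) >= 0))
  }

  # lambda = 0 reduces PAAC to AAC/100
  s <- "ACDEFGHIK"
  expect_equal(unname(paac(s, lambda = 0)), unname(aac(s)) / 100,
               tolerance = 1e-12)
})

test_that("sequence-order coupling matches a direct distance-table oracle", {
  # homopolymer: all self-distances are zero
  expect_true(all(socn("AAAAAA") == 0))
  expect_equal(unname(qso("AAAAAA")["QSO_PC_A"]), 1)

  # lags beyond the sequence length are exact zeros
  v <- socn("ACDEFG")
  expect_true(all(v[paste0("SOCN_PC_", 6:23)] == 0))
  expect_true(all(v[paste0("SOCN_G_", 6:23)] == 0))

  # single-pair oracle recomputed from the shipped property tables
  gp <- read.delim(system.file("extdata", "grantham_properties.tsv",
                               package = "b3ppkit"), row.names = 1)
  gd <- function(a, b) {
    50.723 * sqrt(1.833 * (gp[a, 1] - gp[b, 1])^2 +
                  0.1018 * (gp[a, 2] - gp[b, 2])^2 +
                  0.000399 * (gp[a, 3] - gp[b, 3])^2)
  }
  gmax <- max(outer(AA, AA, Vectorize(gd)))
  expect_equal(unname(socn("AR")["SOCN_G_1"]), (gd("A", "R") / gmax)^2,
               tolerance = 1e-12)

  ps <- read.delim(system.file("extdata", "paac_scales.tsv",
                               package = "b3ppkit"), row.names = 1)[AA, ]
  z <- apply(ps, 2, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
  pcd <- as.matrix(dist(z))
  pcd <- pcd / max(pcd)
  expect_equal(unname(socn("AR")["SOCN_PC_1"]), pcd["A", "R"]^2,
               tolerance = 1e-12)
})

test_that("the manifest pins 9,189 descriptors with the stated block sizes", {
  m <- feature_manifest()
  expect_equal(nrow(m), 9189)
  sizes <- table(m$family)
  expected <- c(AAC = 20, DPC = 400, TPC = 8000, ABC = 9, RRI = 20,
                DDOR = 20, SE = 1, SER = 20, SEP = 25, CTD = 343,
                CeTD = 147, PAAC = 24, APAAC = 28, QSO = 86, SOCN = 46)
  expect_equal(as.numeric(sizes[names(expected)]), unname(expected))
  expect_equal(sum(expected), 9189)
  expect_false(anyDuplicated(m$name) > 0)
})

test_that("featurize_all is deterministic and permutation-equivariant", {
  set.seed(11)
  recs <- peptide_set(paste0("p", 1:6),
                      vapply(sample(6:30, 6, TRUE), random_peptide, ""))
  f1 <- featurize_all(recs)
  f2 <- featurize_all(recs)
  expect_identical(f1$values, f2$values)
  expect_true(all(is.finite(f1$values)))

  perm <- c(4, 2, 6, 1, 3, 5)
  f3 <- featurize_all(recs[perm, ])
  expect_identical(f3$values, f1$values[perm, ])
})

test_that("featurize_all attaches the failing peptide id to errors", {
  recs <- data.frame(id = "bad1", seq = "ACDEFX", label = "unknown")
  expect_error(featurize_all(recs), "bad1")
})
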