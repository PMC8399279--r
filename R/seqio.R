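## seqio: reading, validating, filtering and assembling peptide sets.
##
## A peptide set is a plain data.frame with columns id, seq and (optionally)
## label in {"positive","negative","unknown"}. All functions preserve input
## order.

#' Construct a validated peptide set
#'
#' Builds the canonical peptide data.frame used throughout the package and
#' enforces the sequence alphabet. Lower-case input is accepted and
#' upper-cased; any character outside the standard 20-letter amino-acid
#' alphabet (including B, J, O, U, X, Z and gap characters) is a hard error,
#' because every descriptor family assumes the 20-letter alphabet.
#'
#' @param id character vector of identifiers (non-empty).
#' @param seq character vector of amino-acid sequences.
#' @param label optional class labels ("positive", "negative", "unknown").
#' @return data.frame with columns id, seq, label.
#' @export
peptide_set <- function(id, seq, label = "unknown") {
  id <- as.character(id)
  seq <- toupper(gsub("[[:space:]]", "", as.character(seq)))
  stopifnot(length(id) == length(seq))
  if (any(!nzchar(id))) stop("peptide ids must be non-empty")
  if (any(!nzchar(seq))) {
    stop("empty sequence for record(s): ",
         paste(id[!nzchar(seq)], collapse = ", "))
  }
  bad <- regmatches(seq, regexpr("[^ACDEFGHIKLMNPQRSTVWY]", seq))
  has_bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", seq)
  if (any(has_bad)) {
    i <- which(has_bad)[1]
    stop("invalid residue '", bad[1], "' in record '", id[i],
         "': only the 20 standard amino acids are allowed")
  }
  label <- rep_len(as.character(label), length(id))
  stopifnot(all(label %in% c("positive", "negative", "unknown")))
  data.frame(id = id, seq = seq, label = label, stringsAsFactors = FALSE)
}

#' Read peptide sequences from a FASTA file
#'
#' Multi-line sequences are supported; record order is preserved and
#' sequences are upper-cased. Records containing residues outside the
#' 20-letter alphabet raise an error naming the record and character.
#'
#' @param path path to a FASTA file.
#' @param label optional class label applied to every record.
#' @return peptide set data.frame (zero rows for an empty file).
#' @export
read_fasta <- function(path, label = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  aas <- Biostrings::readBStringSet(path)
  if (length(aas) == 0) {
    return(data.frame(id = character(), seq = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  ids <- sub("[[:space:]].*$", "", names(aas))
  peptide_set(ids, as.character(aas), label = label)
}

#' Write a peptide set to FASTA
#'
#' @param records peptide set data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_fasta <- function(records, path) {
  writeLines(paste0(">", records$id, "\n", records$seq), path)
  invisible(path)
}

#' Read a labelled two-column CSV (sequence,label)
#'
#' Accepts `positive`/`negative` (or 1/0) labels; ids are generated as
#' `pep1..pepN` unless an `id` column is present.
#'
#' @param path path to a CSV file with header.
#' @return peptide set data.frame.
#' @export
read_labeled_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sequence", "label") %in% names(d)))
  lab <- as.character(d$label)
  lab[lab %in% c("1", "pos")] <- "positive"
  lab[lab %in% c("0", "neg")] <- "negative"
  ids <- if ("id" %in% names(d)) d$id else paste0("pep", seq_len(nrow(d)))
  peptide_set(ids, d$sequence, lab)
}

#' Keep peptides within a length window
#'
#' Training data use the 6-30 residue window, both bounds inclusive; the
#' filter preserves input order and is idempotent.
#'
#' @param records peptide set data.frame.
#' @param min_len,max_len inclusive bounds (defaults 6 and 30).
#' @return the records with min_len <= nchar(seq) <= max_len.
#' @export
filter_by_length <- function(records, min_len = 6, max_len = 30) {
  stopifnot(min_len >= 1, max_len >= min_len)
  L <- nchar(records$seq)
  records[L >= min_len & L <= max_len, , drop = FALSE]
}

#' Drop duplicate sequences, keeping the first occurrence
#'
#' @param records peptide set data.frame.
#' @return deduplicated records in input order; the number dropped is
#'   reported via `message()`.
#' @export
deduplicate <- function(records) {
  keep <- !duplicated(records$seq)
  if (any(!keep)) {
    message("deduplicate: dropped ", sum(!keep), " duplicate sequence(s)")
  }
  records[keep, , drop = FALSE]
}

#' Assemble a labelled positive/negative dataset
#'
#' Validates, removes cross-class duplicates from the negatives, and (when
#' `ratio` is given) subsamples the negatives to `round(ratio * n_pos)`
#' deterministically given `seed`. With 269 positives at ratio 10 this
#' yields exactly 2,690 negatives.
#'
#' @param positives,negatives peptide set data.frames (already length
#'   filtered and deduplicated).
#' @param name dataset name.
#' @param ratio negative:positive ratio, or NULL to keep all negatives.
#' @param seed integer seed for the subsample.
#' @return object of class `b3pp_dataset`: list(positives, negatives, name,
#'   ratio).
#' @export
assemble_dataset <- function(positives, negatives, name = "dataset",
                             ratio = NULL, seed = 1) {
  positives <- filter_by_length(positives)
  negatives <- filter_by_length(negatives)
  cross <- negatives$seq %in% positives$seq
  if (any(cross)) {
    message("assemble_dataset: removed ", sum(cross),
            " negative(s) duplicating positive sequences")
    negatives <- negatives[!cross, , drop = FALSE]
  }
  if (!is.null(ratio)) {
    target <- round(ratio * nrow(positives))
    if (nrow(negatives) < target) {
      stop("not enough negatives: need ", target, ", have ",
           nrow(negatives), " (shortfall ", target - nrow(negatives), ")")
    }
    idx <- with_seed(seed, sample.int(nrow(negatives), target))
    negatives <- negatives[sort(idx), , drop = FALSE]
  }
  positives$label <- "positive"
  negatives$label <- "negative"
  message("assemble_dataset '", name, "': ", nrow(positives),
          " positives, ", nrow(negatives), " negatives")
  structure(list(positives = positives, negatives = negatives,
                 name = name, ratio = ratio),
            class = "b3pp_dataset")
}

#' @export
print.b3pp_dataset <- function(x, ...) {
  cat("b3pp_dataset '", x$name, "': ", nrow(x$positives), " positives, ",
      nrow(x$negatives), " negatives\n", sep = "")
  invisible(x)
}

## Bind a dataset into one records data.frame (positives first).
dataset_records <- function(dataset) {
  rbind(dataset$positives, dataset$negatives)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
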