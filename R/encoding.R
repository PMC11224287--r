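#' @importFrom Biostrings readDNAStringSet DNAStringSet writeXStringSet
NULL

SEQ_LEN <- 140L
BASES <- c("A", "C", "G", "T")
EVENT_TYPES <- c("ES", "Alt3", "Alt5")

#' One-hot encode a 140-nt sequence window
#'
#' Converts a DNA (or RNA; U is mapped to T) sequence into a 140 x 4 binary
#' matrix with fixed channel order A, C, G, T.  Row i is the indicator
#' vector of base i; unknown bases (`N`) become all-zero rows, so row sums
#' are 1 for known bases and 0 for `N`.  Input is uppercased before
#' validation.
#'
#' @param seq A character scalar of length-140 sequence.
#' @param id Optional identifier used in error messages.
#' @return A 140 x 4 numeric matrix with colnames A, C, G, T.
#' @examples
#' m <- one_hot_encode(paste(rep("ACGT", 35), collapse = ""))
#' colSums(m)
#' @export
one_hot_encode <- function(seq, id = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  who <- if (is.null(id)) "sequence" else sprintf("sequence '%s'", id)
  if (nchar(seq) != SEQ_LEN) {
    stop(sprintf("%s has length %d; expected %d", who, nchar(seq), SEQ_LEN),
         call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(BASES, "N"))
  if (length(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N,U}: %s",
                 who, paste(bad, collapse = ", ")), call. = FALSE)
  }
  m <- matrix(0, SEQ_LEN, 4L, dimnames = list(NULL, BASES))
  idx <- match(chars, BASES)
  known <- !is.na(idx)
  m[cbind(which(known), idx[known])] <- 1
  m
}

#' Recover a sequence from a one-hot matrix
#'
#' Inverse of [one_hot_encode()]: all-zero rows decode to `N`.
#'
#' @param m A 140 x 4 one-hot matrix.
#' @return A character scalar.
#' @export
one_hot_decode <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 4L)
  hits <- apply(m, 1L, function(r) {
    j <- which(r == 1)
    if (length(j) == 1L) BASES[j] else "N"
  })
  paste(hits, collapse = "")
}

#' Transform exon/intron length features
#'
#' Nucleotide lengths of the exon and its flanking introns span several
#' orders of magnitude; by default they enter the model as log10 values so
#' the dense layer is not dominated by raw intron lengths.  The transform is
#' monotone in each input.
#'
#' @param lengths Numeric vector of 3 positive lengths (nucleotides).
#' @param transform `"log10"` (default) or `"identity"`.
#' @return Numeric vector of 3 finite values.
#' @examples
#' featurize_lengths(c(100, 1000, 100))
#' @export
featurize_lengths <- function(lengths, transform = c("log10", "identity")) {
  transform <- match.arg(transform)
  if (length(lengths) != 3L) {
    stop("exactly 3 length features are expected", call. = FALSE)
  }
  if (any(!is.finite(lengths)) || any(lengths < 1)) {
    stop("length features must be positive (>= 1 nucleotide)", call. = FALSE)
  }
  switch(transform, log10 = log10(lengths), identity = as.numeric(lengths))
}

#' Encode one splice-event record
#'
#' Produces the model-ready triple for a single event: one-hot matrices for
#' both sequence windows, the transformed length features, and the label.
#' Encoding is label-independent and pure: identical inputs yield identical
#' outputs.
#'
#' @param record A list or one-row data.frame with fields `event_id`,
#'   `seq_a`, `seq_b`, `len_exon`, `len_intron_up`, `len_intron_down`,
#'   `label`.
#' @param length_transform Passed to [featurize_lengths()].
#' @return A list with elements `x1`, `x2` (140 x 4 matrices), `x3`
#'   (3-vector) and `y` (0/1).
#' @export
encode_record <- function(record, length_transform = "log10") {
  record <- as.list(record)
  id <- as.character(record$event_id)
  x1 <- tryCatch(one_hot_encode(record$seq_a, id = paste0(id, " (seq_a)")),
                 error = function(e) stop(conditionMessage(e), call. = FALSE))
  x2 <- tryCatch(one_hot_encode(record$seq_b, id = paste0(id, " (seq_b)")),
                 error = function(e) stop(conditionMessage(e), call. = FALSE))
  lens <- as.numeric(c(record$len_exon, record$len_intron_up,
                       record$len_intron_down))
  x3 <- featurize_lengths(lens, transform = length_transform)
  y <- as.integer(record$label)
  if (!y %in% c(0L, 1L)) {
    stop(sprintf("record '%s': label must be 0 or 1", id), call. = FALSE)
  }
  list(x1 = x1, x2 = x2, x3 = x3, y = y)
}

#' Encode a full set of splice-event records
#'
#' Stacks per-record encodings into the dense arrays the training code
#' consumes.
#'
#' @param records A splice-event data.frame (see [read_dataset()] or
#'   [generate_dataset()]).
#' @param length_transform Passed to [featurize_lengths()].
#' @return An `encoded_dataset`: list with `x1`, `x2` (arrays
#'   `140 x 4 x n`), `x3` (matrix `n x 3`), `y` (integer vector),
#'   `event_id` and `event_type`.
#' @export
encode_dataset <- function(records, length_transform = "log10") {
  records <- validate_records(records)
  n <- nrow(records)
  x1 <- array(0, c(SEQ_LEN, 4L, n))
  x2 <- array(0, c(SEQ_LEN, 4L, n))
  x3 <- matrix(0, n, 3L)
  y <- integer(n)
  for (i in seq_len(n)) {
    e <- encode_record(records[i, ], length_transform = length_transform)
    x1[, , i] <- e$x1
    x2[, , i] <- e$x2
    x3[i, ] <- e$x3
    y[i] <- e$y
  }
  structure(list(x1 = x1, x2 = x2, x3 = x3, y = y,
                 event_id = as.character(records$event_id),
                 event_type = as.character(records$event_type)),
            class = "encoded_dataset")
}

# Subset an encoded dataset by sample index.
subset_encoded <- function(data, idx) {
  structure(list(x1 = data$x1[, , idx, drop = FALSE],
                 x2 = data$x2[, , idx, drop = FALSE],
                 x3 = data$x3[idx, , drop = FALSE],
                 y = data$y[idx],
                 event_id = data$event_id[idx],
                 event_type = data$event_type[idx]),
            class = "encoded_dataset")
}

validate_records <- function(records) {
  required <- c("event_id", "event_type", "seq_a", "seq_b", "len_exon",
                "len_intron_up", "len_intron_down", "label")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("records are missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (anyDuplicated(records$event_id)) {
    dup <- records$event_id[duplicated(records$event_id)][1]
    stop(sprintf("duplicate event_id '%s'", dup), call. = FALSE)
  }
  bad_type <- setdiff(unique(records$event_type), EVENT_TYPES)
  if (length(bad_type)) {
    stop("unknown event_type values: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  records
}

#' Read a splice-event dataset from FASTA + TSV
#'
#' Sequences live in a (possibly line-wrapped) FASTA file with two entries
#' per event, named `<event_id>_A` and `<event_id>_B` for the two 140-nt
#' windows.  Annotations are a tab-separated table with header columns
#' `event_id`, `event_type`, `len_exon`, `len_intron_up`, `len_intron_down`,
#' `label`.  Records are returned in annotation-file order.
#'
#' @param sequences_path Path to the FASTA file.
#' @param annotations_path Path to the TSV annotation table.
#' @return A data.frame of splice-event records with one row per annotation
#'   row.
#' @seealso [write_fixture()] for the inverse operation.
#' @export
read_dataset <- function(sequences_path, annotations_path) {
  ann <- utils::read.delim(annotations_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("event_id", "event_type", "len_exon", "len_intron_up",
                "len_intron_down", "label")
  missing <- setdiff(required, names(ann))
  if (length(missing)) {
    stop("annotation table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(ann) == 0L) {
    empty <- ann[, required]
    empty$seq_a <- character(0)
    empty$seq_b <- character(0)
    return(validate_records(empty[0L, c("event_id", "event_type", "seq_a",
                                        "seq_b", "len_exon", "len_intron_up",
                                        "len_intron_down", "label")]))
  }
  if (anyDuplicated(ann$event_id)) {
    dup <- ann$event_id[duplicated(ann$event_id)][1]
    stop(sprintf("duplicate event_id '%s' in annotation table", dup),
         call. = FALSE)
  }
  fa <- Biostrings::readDNAStringSet(sequences_path)
  seqs <- as.character(fa)
  names(seqs) <- names(fa)
  ids_a <- paste0(ann$event_id, "_A")
  ids_b <- paste0(ann$event_id, "_B")
  absent <- c(setdiff(ids_a, names(seqs)), setdiff(ids_b, names(seqs)))
  if (length(absent)) {
    stop("no FASTA entry for: ", paste(utils::head(absent, 5), collapse = ", "),
         if (length(absent) > 5) sprintf(" (and %d more)", length(absent) - 5)
         else "", call. = FALSE)
  }
  out <- data.frame(
    event_id = as.character(ann$event_id),
    event_type = as.character(ann$event_type),
    seq_a = unname(seqs[ids_a]),
    seq_b = unname(seqs[ids_b]),
    len_exon = as.integer(ann$len_exon),
    len_intron_up = as.integer(ann$len_intron_up),
    len_intron_down = as.integer(ann$len_intron_down),
    label = as.integer(ann$label),
    stringsAsFactors = FALSE
  )
  validate_records(out)
}
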