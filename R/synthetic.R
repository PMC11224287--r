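#' Configuration for the synthetic splice-event generator
#'
#' The generator emulates the structure of a labeled human internal-exon
#' splice-event dataset: paired 140-nt windows around the event, three
#' exon/intron length covariates, a binary inclusion-class label, and three
#' event categories (ES, Alt3, Alt5) whose default proportions follow the
#' relative sizes of the event classes in the emulated dataset
#' (ES : Alt3 : Alt5 = 4952 : 1388 : 1568).
#'
#' High-inclusion (positive) events carry planted splice-site-like motifs:
#' a donor-like consensus (centered on GT) is sampled from `pwm_a` into
#' `seq_a` and an acceptor-like consensus (centered on AG) from `pwm_b`
#' into `seq_b`, each independently with probability `signal_strength`.
#' Everything else is uniform i.i.d. background, so `signal_strength = 0`
#' makes the sequence distributions of the two classes identical.
#'
#' @param n_per_class Events per label class (dataset size is twice this).
#' @param event_type_proportions Named length-3 non-negative vector for
#'   ES/Alt3/Alt5, summing to 1.
#' @param pwm_a,pwm_b Position-weight matrices (4 x width, rows A,C,G,T,
#'   columns summing to 1) planted into `seq_a` / `seq_b` of positives.
#' @param motif_offset 1-based start position of the planted motif within
#'   the 140-nt window (default 68, near-center).
#' @param signal_strength Probability in `[0, 1]` that a positive event's
#'   window carries a motif draw rather than pure background.
#' @param length_params Per-class log-normal parameters for the three
#'   length features: a list with elements `neg` and `pos`, each holding
#'   `meanlog` and `sdlog` 3-vectors (exon, upstream intron, downstream
#'   intron).  The default shifts the positive-class exon length slightly,
#'   making the length features weakly informative.
#' @param seed Integer seed; generation is fully determined by the config.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_per_class = 1000L,
                             event_type_proportions = c(ES = 4952, Alt3 = 1388,
                                                        Alt5 = 1568) / 7908,
                             pwm_a = donor_pwm(),
                             pwm_b = acceptor_pwm(),
                             motif_offset = 68L,
                             signal_strength = 0.9,
                             length_params = default_length_params(),
                             seed = 1L) {
  cfg <- list(n_per_class = as.integer(n_per_class),
              event_type_proportions = event_type_proportions,
              pwm_a = pwm_a, pwm_b = pwm_b,
              motif_offset = as.integer(motif_offset),
              signal_strength = signal_strength,
              length_params = length_params,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_per_class < 1L) stop("`n_per_class` must be >= 1", call. = FALSE)
  p <- cfg$event_type_proportions
  if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("`event_type_proportions` must be 3 non-negative values summing to 1",
         call. = FALSE)
  }
  for (nm in c("pwm_a", "pwm_b")) {
    pwm <- cfg[[nm]]
    if (!is.matrix(pwm) || nrow(pwm) != 4L || any(pwm < 0) ||
        any(abs(colSums(pwm) - 1) > 1e-8)) {
      stop(sprintf("`%s` must be a 4 x width matrix with columns summing to 1",
                   nm), call. = FALSE)
    }
  }
  if (cfg$signal_strength < 0 || cfg$signal_strength > 1) {
    stop("`signal_strength` must lie in [0, 1]", call. = FALSE)
  }
  w <- max(ncol(cfg$pwm_a), ncol(cfg$pwm_b))
  if (cfg$motif_offset < 1L || cfg$motif_offset + w - 1L > 140L) {
    stop("motif does not fit in the 140-nt window at `motif_offset`",
         call. = FALSE)
  }
  cfg
}

consensus_pwm <- function(consensus, dominant = 0.85) {
  bases <- strsplit(consensus, "")[[1]]
  pwm <- matrix((1 - dominant) / 3, nrow = 4L, ncol = length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) pwm[bases[j], j] <- dominant
  pwm
}

#' Donor-like and acceptor-like default motifs
#'
#' Degenerate 9-column position-weight matrices built from the canonical
#' splice-site consensus sequences: `CAGGTAAGT` (exon/intron boundary with
#' the invariant GT) for the donor side and `TTTTCAGGT` (pyrimidine run
#' into the invariant AG) for the acceptor side, with the consensus base at
#' probability 0.85 per column.
#'
#' @param dominant Probability of the consensus base at each column.
#' @return A 4 x 9 matrix with rows A, C, G, T.
#' @export
donor_pwm <- function(dominant = 0.85) consensus_pwm("CAGGTAAGT", dominant)

#' @rdname donor_pwm
#' @export
acceptor_pwm <- function(dominant = 0.85) consensus_pwm("TTTTCAGGT", dominant)

default_length_params <- function() {
  list(neg = list(meanlog = c(log(120), log(1500), log(1500)),
                  sdlog = c(0.40, 0.80, 0.80)),
       pos = list(meanlog = c(log(120) + 0.15, log(1500), log(1500)),
                  sdlog = c(0.40, 0.80, 0.80)))
}

# Largest-remainder apportionment of n among the three event types.
apportion_types <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(proportions))
}

random_windows <- function(n, width = 140L) {
  chars <- sample(c("A", "C", "G", "T"), n * width, replace = TRUE)
  m <- matrix(chars, nrow = width, ncol = n)
  apply(m, 2L, paste, collapse = "")
}

plant_motif <- function(seqs, plant, pwm, offset) {
  w <- ncol(pwm)
  bases <- rownames(pwm)
  for (i in which(plant)) {
    motif <- vapply(seq_len(w),
                    function(j) sample(bases, 1L, prob = pwm[, j]),
                    character(1))
    substr(seqs[i], offset, offset + w - 1L) <- paste(motif, collapse = "")
  }
  seqs
}

#' Generate a labeled synthetic splice-event dataset
#'
#' Produces `2 * n_per_class` records with exactly balanced labels and the
#' class structure described in [synthetic_config()].  Generation is fully
#' determined by the config (including its seed): identical configs yield
#' byte-identical datasets.
#'
#' @param config A [synthetic_config()].
#' @return A splice-event data.frame with columns `event_id`, `event_type`,
#'   `seq_a`, `seq_b`, `len_exon`, `len_intron_up`, `len_intron_down`,
#'   `label`, ready for [encode_dataset()] or [write_fixture()].
#' @examples
#' d <- generate_dataset(synthetic_config(n_per_class = 5, seed = 42))
#' table(d$label)
#' @export
generate_dataset <- function(config = synthetic_config()) {
  config <- validate_synthetic_config(config)
  set.seed(config$seed)
  n <- config$n_per_class
  type_counts <- apportion_types(n, config$event_type_proportions)
  types <- rep(names(type_counts), times = type_counts)

  build_class <- function(label) {
    seq_a <- random_windows(n)
    seq_b <- random_windows(n)
    if (label == 1L) {
      plant_a <- stats::runif(n) < config$signal_strength
      plant_b <- stats::runif(n) < config$signal_strength
      seq_a <- plant_motif(seq_a, plant_a, config$pwm_a, config$motif_offset)
      seq_b <- plant_motif(seq_b, plant_b, config$pwm_b, config$motif_offset)
    }
    lp <- if (label == 1L) config$length_params$pos else
      config$length_params$neg
    lens <- vapply(1:3, function(j) {
      pmax(1L, as.integer(round(stats::rlnorm(n, lp$meanlog[j], lp$sdlog[j]))))
    }, integer(n))
    data.frame(event_type = types,
               seq_a = seq_a, seq_b = seq_b,
               len_exon = lens[, 1], len_intron_up = lens[, 2],
               len_intron_down = lens[, 3],
               label = label, stringsAsFactors = FALSE)
  }

  out <- rbind(build_class(0L), build_class(1L))
  out <- cbind(event_id = sprintf("ev%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  validate_records(out)
}

#' Permute the labels of a dataset
#'
#' Reassigns the existing labels by a seeded permutation, leaving sequences
#' and length features untouched.  The label multiset is conserved, so a
#' balanced dataset stays balanced; any genuine sequence-label association
#' is destroyed, making this the null control for signal-recovery checks.
#'
#' @param records A splice-event data.frame.
#' @param seed Integer seed.
#' @return The records with permuted labels.
#' @export
permute_labels <- function(records, seed = 1L) {
  if (nrow(records) == 0L) stop("`records` must be non-empty", call. = FALSE)
  set.seed(seed)
  records$label <- records$label[sample.int(nrow(records))]
  records
}

#' Write a splice-event dataset as the FASTA + TSV fixture pair
#'
#' Emits `sequences.fasta` (entries `<event_id>_A` / `<event_id>_B`) and
#' `annotations.tsv` in the layout [read_dataset()] consumes;
#' `read_dataset()` on the written files reproduces the input records
#' exactly.
#'
#' @param records A splice-event data.frame.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector with paths `sequences` and `annotations`,
#'   invisibly.
#' @export
write_fixture <- function(records, out_dir) {
  records <- if (nrow(records) > 0L) validate_records(records) else records
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory '%s'", out_dir),
                  call. = FALSE)
  }
  fa_path <- file.path(out_dir, "sequences.fasta")
  ann_path <- file.path(out_dir, "annotations.tsv")
  seqs <- character(0)
  if (nrow(records) > 0L) {
    seqs <- as.character(rbind(records$seq_a, records$seq_b))
    names(seqs) <- as.character(rbind(paste0(records$event_id, "_A"),
                                      paste0(records$event_id, "_B")))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa_path)
  ann <- records[, c("event_id", "event_type", "len_exon", "len_intron_up",
                     "len_intron_down", "label"), drop = FALSE]
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(sequences = fa_path, annotations = ann_path))
}
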