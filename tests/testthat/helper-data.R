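# Shared fixture builders; everything is generated in code.

random_seq <- function(n = 140L, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A minimal valid record list.
toy_record <- function(id = "ev1", label = 1L, seq_a = NULL, seq_b = NULL) {
  list(event_id = id, event_type = "ES",
       seq_a = seq_a %||% strrep("A", 140),
       seq_b = seq_b %||% strrep("C", 140),
       len_exon = 100L, len_intron_up = 1000L, len_intron_down = 500L,
       label = label)
}

# Small planted-signal dataset reused across training tests.
small_signal_records <- function(n_per_class = 150L, seed = 11L) {
  generate_dataset(synthetic_config(n_per_class = n_per_class, seed = seed))
}

# Brute-force pairwise Mann-Whitney AUC: the independent oracle.
auc_pairwise <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
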