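# Shared in-code fixtures: tiny FASTA/TSV writers and toy protein sets.

write_tiny_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(seqs), function(n) {
    c(paste0(">", n), seqs[[n]])
  })), path)
  path
}

write_tiny_annotations <- function(rows, path = tempfile(fileext = ".tsv")) {
  cols <- c("protein_id", "species", "class_label", "kind",
            "start", "end", "source")
  for (cn in setdiff(cols, names(rows))) rows[[cn]] <- NA
  readr::write_tsv(rows[, cols], path, progress = FALSE)
  path
}

# A protein tibble in read_proteins() shape, built directly.
toy_proteins <- function(seqs, annotations = NULL, species = "sp1",
                         class_label = "LRR-VI-2") {
  empty <- tibble::tibble(kind = character(), start = numeric(),
                          end = numeric(), source = character())
  tibble::tibble(
    id = names(seqs),
    species = rep_len(species, length(seqs)),
    class_label = rep_len(class_label, length(seqs)),
    sequence = unname(unlist(seqs)),
    annotations = if (is.null(annotations)) {
      rep(list(empty), length(seqs))
    } else {
      annotations
    })
}

# Random amino-acid strings under a fixed RNG state.
random_sequences <- function(n, len, letters = aa_alphabet()) {
  vapply(seq_len(n), function(i) {
    paste(sample(letters, len, replace = TRUE), collapse = "")
  }, "")
}

# The reference small simulation used by several motif tests (generation
# is deterministic). With `single_class = TRUE` every protein belongs to
# the motif-bearing class; otherwise the motif is planted in one of four
# classes and the other three are motif-free.
planted_trimmed_segments <- function(n = 200, seed = 11,
                                     single_class = TRUE) {
  cm <- nrekit:::default_class_motifs()[1, ]
  if (!single_class) {
    cm <- dplyr::bind_rows(cm, tibble::tibble(
      class_label = c("PERK-2", "LRR-Xb-1", "RLCK-IV"),
      motif = NA_character_,
      phospho_offsets = list(integer(0), integer(0), integer(0))))
  }
  sim <- simulate_rlk_dataset(n_proteins = n, class_motifs = cm,
                              planting_rate = 0.8, substitution_rate = 0.1,
                              seed = seed)
  top <- assign_topology(sim$proteins)
  segs <- extract_nre(sim$proteins, top)
  list(sim = sim, trimmed = strip_cterminal(segs, 14))
}
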