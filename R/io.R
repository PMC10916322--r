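# Readers and writers for the pipeline's external formats: FASTA protein
# sequences, annotation / phosphosite / report TSVs.

#' Read proteins from FASTA plus a feature-annotation table
#'
#' Sequences come from `fasta_path`; per-protein metadata (species, Shiu
#' class label) and domain annotations (transmembrane, kinase_domain, ecd,
#' signal_peptide, other_domain intervals) come from a TSV with columns
#' `protein_id, species, class_label, kind, start, end, source`. Rows with
#' `kind = "none"` (or empty coordinates) carry metadata only. Coordinates
#' are 1-based and inclusive on both ends, in residues, as everywhere in
#' this package.
#'
#' Annotation rows that reference an unknown protein, or whose interval
#' falls outside the sequence, are dropped with a warning and counted in
#' the `qc` attribute (`dropped_rows + kept_rows = input_rows`).
#'
#' @param fasta_path Path to a protein FASTA file.
#' @param annotation_table_path Path to the annotation TSV.
#' @return A tibble with columns `id, species, class_label, sequence` and a
#'   list-column `annotations` (tibble of `kind, start, end, source`, sorted
#'   by `start`), with a `qc` attribute (named counts).
#' @export
read_proteins <- function(fasta_path, annotation_table_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  }
  if (!file.exists(annotation_table_path)) {
    stop("annotation table not found: ", annotation_table_path, call. = FALSE)
  }
  aaset <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(aaset))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- as.character(aaset)
  bad <- !vapply(seqs, aa_valid, TRUE)
  if (any(bad)) {
    stop("sequences with letters outside the alphabet: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }

  ann <- readr::read_tsv(annotation_table_path, show_col_types = FALSE,
                         col_types = readr::cols(
                           protein_id = "c", species = "c", class_label = "c",
                           kind = "c", start = "d", end = "d", source = "c"))
  n_in <- nrow(ann)
  seq_len_of <- stats::setNames(nchar(seqs), ids)

  unmatched <- !ann$protein_id %in% ids
  if (any(unmatched)) {
    warning(sum(unmatched), " annotation row(s) reference unknown proteins",
            call. = FALSE)
  }
  ann_m <- ann[!unmatched, , drop = FALSE]
  is_meta <- is.na(ann_m$start) | is.na(ann_m$end) |
    (!is.na(ann_m$kind) & ann_m$kind == "none")
  iv <- ann_m[!is_meta, , drop = FALSE]
  out_of_range <- iv$start < 1 | iv$start > iv$end |
    iv$end > seq_len_of[iv$protein_id]
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " annotation interval(s) outside the sequence dropped",
            call. = FALSE)
  }
  iv_kept <- iv[!out_of_range, , drop = FALSE]

  meta <- ann_m |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      species = dplyr::first(stats::na.omit(.data$species)),
      class_label = dplyr::first(stats::na.omit(.data$class_label)),
      .groups = "drop")

  ann_nested <- iv_kept |>
    dplyr::select("protein_id", "kind", "start", "end", "source") |>
    dplyr::arrange(.data$protein_id, .data$start, .data$end) |>
    tidyr::nest(annotations = c("kind", "start", "end", "source"))

  empty_ann <- tibble::tibble(kind = character(), start = numeric(),
                              end = numeric(), source = character())
  out <- tibble::tibble(id = ids, sequence = unname(seqs)) |>
    dplyr::left_join(meta, by = c(id = "protein_id")) |>
    dplyr::left_join(ann_nested, by = c(id = "protein_id")) |>
    dplyr::mutate(
      annotations = purrr::map(.data$annotations,
                               ~ if (is.null(.x)) empty_ann else .x)) |>
    dplyr::select("id", "species", "class_label", "sequence", "annotations")

  attr(out, "qc") <- c(
    input_rows = n_in,
    kept_rows = nrow(iv_kept) + sum(is_meta),
    dropped_unmatched = sum(unmatched),
    dropped_out_of_range = sum(out_of_range)
  )
  out
}

#' Read experimentally determined phosphosites
#'
#' Reads a TSV (columns `protein_id, position, residue`, optional `source`)
#' of experimental phosphorylation sites, such as an export from a plant
#' phosphosite database, and validates each site against the protein
#' sequences: sites on unknown proteins, or whose declared residue
#' disagrees with the sequence at that position, are dropped with a warning
#' and counted in the `qc` attribute.
#'
#' @param tsv_path Path to the phosphosite TSV.
#' @param proteins Protein tibble from [read_proteins()].
#' @return Tibble `protein_id, position, residue, source` with a `qc`
#'   attribute.
#' @export
read_phosphosites <- function(tsv_path, proteins) {
  if (!file.exists(tsv_path)) {
    stop("phosphosite table not found: ", tsv_path, call. = FALSE)
  }
  ph <- readr::read_tsv(tsv_path, show_col_types = FALSE)
  stopifnot(all(c("protein_id", "position", "residue") %in% names(ph)))
  if (!"source" %in% names(ph)) ph$source <- NA_character_
  n_in <- nrow(ph)

  seq_of <- stats::setNames(proteins$sequence, proteins$id)
  known <- ph$protein_id %in% names(seq_of)
  if (any(!known)) {
    warning(sum(!known), " phosphosite(s) on unknown proteins dropped",
            call. = FALSE)
  }
  ph <- ph[known, , drop = FALSE]
  in_range <- ph$position >= 1 & ph$position <= nchar(seq_of[ph$protein_id])
  observed <- rep(NA_character_, nrow(ph))
  observed[in_range] <- substr(seq_of[ph$protein_id[in_range]],
                               ph$position[in_range], ph$position[in_range])
  agrees <- in_range & observed == ph$residue
  if (any(!agrees)) {
    warning(sum(!agrees), " phosphosite(s) with residue mismatch dropped",
            call. = FALSE)
  }
  out <- tibble::as_tibble(ph[agrees, c("protein_id", "position",
                                        "residue", "source")])
  attr(out, "qc") <- c(input_rows = n_in, kept_rows = nrow(out),
                       dropped_unknown_protein = sum(!known),
                       dropped_mismatch = sum(!agrees))
  out
}

#' Write a report table deterministically
#'
#' Tab-separated, header line, UTF-8. Rows are sorted by the declared key
#' columns so identical inputs always produce identical bytes.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @param key Character vector of column names to sort by (default: all
#'   columns, left to right).
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, key = names(rows)) {
  stopifnot(is.data.frame(rows), all(key %in% names(rows)))
  if (nrow(rows) > 0) {
    rows <- dplyr::arrange(rows, dplyr::across(dplyr::all_of(key)))
  }
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write NRE segments to FASTA
#'
#' Ids follow the `proteinid|start-end|kind` convention.
#'
#' @param segments Segment tibble (see [extract_nre()]).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_nre_fasta <- function(segments, path) {
  seqs <- Biostrings::AAStringSet(segments$sequence)
  names(seqs) <- sprintf("%s|%d-%d|%s", segments$protein_id,
                         segments$start, segments$end, segments$kind)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
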