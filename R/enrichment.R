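# Class enrichment via the normalized-frequency statistic, species
# presence, phosphosite-motif containment, sequence identity and
# conservation tiers.

#' Per-class segment counts and abundance scores
#'
#' Segments flagged `has_internal_domain` are excluded from the analyzed
#' corpus (the enrichment statistic is defined over domain-free NREs);
#' `Ntotal` is the retained count and the abundance score is
#' `Ac = Nc / Ntotal`.
#'
#' @param segments Segment tibble from [extract_nre()].
#' @return Tibble `class_label, Nc, Ntotal, Ac` with attribute
#'   `excluded_with_domain`.
#' @export
count_classes <- function(segments) {
  kept <- segments[!segments$has_internal_domain, , drop = FALSE]
  out <- kept |>
    dplyr::count(.data$class_label, name = "Nc") |>
    dplyr::mutate(Ntotal = nrow(kept), Ac = .data$Nc / .data$Ntotal)
  attr(out, "excluded_with_domain") <- sum(segments$has_internal_domain)
  out
}

#' Normalized frequency of a motif in a class
#'
#' The class-enrichment statistic `F = Nm^2 * Ntotal / (P * Nc^2)`, where
#' `Nm` is the number of occurrences of the motif in the class, `P` its
#' total occurrences in the corpus, `Nc` the class size and `Ntotal` the
#' corpus size. `F > 1` marks overrepresentation of the motif in the
#' class. The value is verified internally against the equivalent factored
#' form `(Nm / (P * Ac)) * (Nm / Nc)` with `Ac = Nc / Ntotal`.
#'
#' @param Nm,P,Nc,Ntotal Occurrence and class counts (vectorised).
#' @return Numeric vector of normalized frequencies.
#' @export
#' @examples
#' normalized_frequency(Nm = 3532, P = 3532, Nc = 5265, Ntotal = 457685)
normalized_frequency <- function(Nm, P, Nc, Ntotal) {
  if (any(P == 0)) stop("P = 0: the motif has no occurrences", call. = FALSE)
  stopifnot(all(Nm >= 0), all(P >= Nm), all(Nc >= 1), all(Ntotal >= Nc))
  f <- Nm^2 * Ntotal / (P * Nc^2)
  ac <- Nc / Ntotal
  f2 <- (Nm / (P * ac)) * (Nm / Nc)
  stopifnot(all(abs(f - f2) <= 1e-9 * pmax(1, abs(f))))
  f
}

#' Per-(motif, class) enrichment from scan matches
#'
#' Joins matches to their segments' class and species labels, drops
#' matches on domain-bearing segments (excluded from the corpus), and
#' computes `Nm`, `P`, `Nc`, `Ntotal`, the normalized frequency `F` and the
#' number of distinct species with at least one match.
#'
#' @param matches Tibble from [scan_motif()] (`sequence_id` = protein id).
#' @param segments Segment tibble carrying `class_label` and `species`.
#' @return Tibble `motif_id, class_label, Nm, Nc, P, Ntotal, F,
#'   species_count`.
#' @export
motif_enrichment <- function(matches, segments) {
  cc <- count_classes(segments)
  kept <- segments[!segments$has_internal_domain, , drop = FALSE]
  m <- matches |>
    dplyr::inner_join(
      kept[, c("protein_id", "class_label", "species")],
      by = c(sequence_id = "protein_id"))
  per_motif <- m |> dplyr::count(.data$motif_id, name = "P")
  out <- m |>
    dplyr::count(.data$motif_id, .data$class_label, name = "Nm") |>
    dplyr::left_join(per_motif, by = "motif_id") |>
    dplyr::left_join(cc[, c("class_label", "Nc", "Ntotal")],
                     by = "class_label") |>
    dplyr::mutate(F = normalized_frequency(.data$Nm, .data$P, .data$Nc,
                                           .data$Ntotal))
  species <- m |>
    dplyr::distinct(.data$motif_id, .data$species) |>
    dplyr::count(.data$motif_id, name = "species_count")
  out |>
    dplyr::left_join(species, by = "motif_id") |>
    dplyr::arrange(.data$motif_id, .data$class_label)
}

#' Keep overrepresented (motif, class) rows
#'
#' Strictly-greater semantics: rows with `F` exactly at the threshold are
#' dropped.
#'
#' @param results Tibble from [motif_enrichment()].
#' @param threshold Normalized-frequency cutoff.
#' @return The overrepresented subset.
#' @export
filter_overrepresented <- function(results, threshold = 1.0) {
  results[results$F > threshold, , drop = FALSE]
}

#' Distinct species with at least one match, per motif
#'
#' @param matches Tibble from [scan_motif()].
#' @param records Tibble with `protein_id` (or `id`) and `species`.
#' @return Tibble `motif_id, species_count`.
#' @export
species_presence <- function(matches, records) {
  if (!"protein_id" %in% names(records) && "id" %in% names(records)) {
    records <- dplyr::rename(records, protein_id = "id")
  }
  matches |>
    dplyr::inner_join(records[, c("protein_id", "species")],
                      by = c(sequence_id = "protein_id")) |>
    dplyr::distinct(.data$motif_id, .data$species) |>
    dplyr::count(.data$motif_id, name = "species_count")
}

#' Map phosphosites into motif matches
#'
#' A site is contained in a match iff `start <= position <= stop`
#' (inclusive on both boundaries), with site positions and match
#' coordinates both in protein coordinates (see
#' [matches_to_protein_coords()]); the 1-based offset of the site within
#' the motif is recorded.
#'
#' @param matches Match tibble in protein coordinates.
#' @param sites Phosphosite tibble from [read_phosphosites()].
#' @return Tibble `motif_id, protein_id, position, residue, motif_offset,
#'   match_start, match_stop`.
#' @export
map_phosphosites <- function(matches, sites) {
  dplyr::inner_join(matches, sites,
                    by = c(sequence_id = "protein_id"),
                    relationship = "many-to-many") |>
    dplyr::filter(.data$start <= .data$position,
                  .data$position <= .data$stop) |>
    dplyr::transmute(
      motif_id = .data$motif_id, protein_id = .data$sequence_id,
      position = .data$position, residue = .data$residue,
      motif_offset = .data$position - .data$start + 1L,
      match_start = .data$start, match_stop = .data$stop)
}

#' Sequence identity between a motif consensus and a matched subsequence
#'
#' `I = NIm / Nm`: the fraction of positions where the matched residue
#' agrees with the consensus letter, degenerate letters (B, Z, J, X)
#' agreeing with any member of their expansion set. Vectorised over pairs;
#' lengths must agree pairwise.
#'
#' @param motif_consensus Character vector of consensus strings.
#' @param matched_subsequence Character vector of equal-length matches.
#' @return Numeric vector of identities in `[0, 1]`.
#' @export
sequence_identity <- function(motif_consensus, matched_subsequence) {
  mapply(function(cons, obs) {
    if (nchar(cons) != nchar(obs)) {
      stop("consensus and match differ in length", call. = FALSE)
    }
    cl <- strsplit(cons, "")[[1]]
    ol <- strsplit(obs, "")[[1]]
    mean(aa_letters_agree(cl, ol))
  }, motif_consensus, matched_subsequence, USE.NAMES = FALSE)
}

#' Conservation summary of a motif over its matches
#'
#' Mean sequence identity over matches (as a percentage), the conservation
#' tier (`high` when mean SI > 80, `moderate` when 50 <= mean SI <= 80,
#' `low` below 50), and the S/T/Y rule: `sty_ok` is TRUE iff every
#' contained phosphosite falls at a motif offset whose consensus letter is
#' S, T or Y. Motifs failing the rule are excluded from the phospho-motif
#' report by [build_report()].
#'
#' @param motif An `nre_motif`.
#' @param matches Matches of this motif (needs `matched_sequence`).
#' @param contained_sites Tibble from [map_phosphosites()] (this motif's
#'   rows; may be empty).
#' @return One-row tibble `motif_id, n_matches, mean_si, tier,
#'   n_contained_sites, phospho_offsets, sty_ok`, or a 0-row tibble when
#'   the motif has no matches.
#' @export
conservation_summary <- function(motif, matches, contained_sites = NULL) {
  empty <- tibble::tibble(motif_id = character(), n_matches = integer(),
                          mean_si = numeric(), tier = character(),
                          n_contained_sites = integer(),
                          phospho_offsets = character(), sty_ok = logical())
  matches <- matches[matches$motif_id == motif$id, , drop = FALSE]
  if (nrow(matches) == 0) return(empty)
  ident <- sequence_identity(rep(motif$consensus, nrow(matches)),
                             matches$matched_sequence)
  mean_si <- 100 * mean(ident)
  tier <- if (mean_si > 80) "high" else if (mean_si >= 50) "moderate" else "low"
  if (is.null(contained_sites) || nrow(contained_sites) == 0) {
    offs <- integer(0)
  } else {
    cs <- contained_sites[contained_sites$motif_id == motif$id, , drop = FALSE]
    offs <- sort(unique(cs$motif_offset))
  }
  cons_letters <- strsplit(motif$consensus, "")[[1]]
  sty_ok <- length(offs) == 0 ||
    all(cons_letters[offs] %in% c("S", "T", "Y"))
  tibble::tibble(motif_id = motif$id, n_matches = nrow(matches),
                 mean_si = mean_si, tier = tier,
                 n_contained_sites = length(offs),
                 phospho_offsets = paste(offs, collapse = ";"),
                 sty_ok = sty_ok)
}

#' Assemble the per-(motif, class) phospho-motif report
#'
#' One row per (motif, class) joining enrichment, conservation and
#' phosphosite containment, with phospho offsets rendered `"6;9"`-style
#' and rows sorted by mean sequence identity (descending). Motifs failing
#' the S/T/Y rule are excluded and returned in the `exclusions` attribute.
#'
#' @param enrichment Tibble from [motif_enrichment()].
#' @param conservation Row-bound [conservation_summary()] tibbles.
#' @param motifs List of `nre_motif` objects (for consensus strings).
#' @return Tibble `Motif, Class, PhosphoSites, SpeciesCount, MeanSI,
#'   NormalizedFrequency, Nm, Nc, P` with attribute `exclusions`.
#' @export
build_report <- function(enrichment, conservation, motifs) {
  cons_of <- stats::setNames(
    vapply(motifs, function(m) m$consensus, ""),
    vapply(motifs, function(m) m$id, ""))
  joined <- enrichment |>
    dplyr::inner_join(conservation, by = "motif_id")
  excluded <- joined[!joined$sty_ok, , drop = FALSE]
  kept <- joined[joined$sty_ok, , drop = FALSE]
  out <- kept |>
    dplyr::transmute(
      Motif = unname(cons_of[.data$motif_id]),
      Class = .data$class_label,
      PhosphoSites = .data$phospho_offsets,
      SpeciesCount = .data$species_count,
      MeanSI = round(.data$mean_si, 1),
      NormalizedFrequency = round(.data$F, 1),
      Nm = .data$Nm, Nc = .data$Nc, P = .data$P) |>
    dplyr::arrange(dplyr::desc(.data$MeanSI), .data$Motif, .data$Class)
  attr(out, "exclusions") <- excluded
  out
}
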