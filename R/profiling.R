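# NRE profiling: length distributions, position-scaled composition,
# terminal sequence logos, the 14-residue C-terminal consensus / ST motif,
# and LRR-VI-2 type calling.

#' NRE length distribution
#'
#' Counts per length bin, stratified by segment kind and class. A summary
#' (n, mode bin, quartiles) per stratum is attached as the `summary`
#' attribute.
#'
#' @param segments Segment tibble from [extract_nre()].
#' @param bin_width Bin width in residues.
#' @return Tibble `kind, class_label, bin_start, bin_end, count`.
#' @export
length_distribution <- function(segments, bin_width = 2) {
  stopifnot(nrow(segments) >= 1, bin_width >= 1)
  out <- segments |>
    dplyr::mutate(bin_start = (.data$length %/% bin_width) * bin_width) |>
    dplyr::count(.data$kind, .data$class_label, .data$bin_start,
                 name = "count") |>
    dplyr::mutate(bin_end = .data$bin_start + bin_width - 1L, .before = "count")
  summ <- segments |>
    dplyr::group_by(.data$kind, .data$class_label) |>
    dplyr::summarise(
      n = dplyr::n(),
      q25 = stats::quantile(.data$length, 0.25),
      median = stats::median(.data$length),
      q75 = stats::quantile(.data$length, 0.75),
      .groups = "drop")
  modes <- out |>
    dplyr::group_by(.data$kind, .data$class_label) |>
    dplyr::slice_max(.data$count, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("kind", "class_label", mode_bin_start = "bin_start")
  attr(out, "summary") <- dplyr::left_join(summ, modes,
                                           by = c("kind", "class_label"))
  out
}

#' Position-scaled composition profile
#'
#' Segments of any length are aligned onto a common axis of `bins`
#' positions: residue `i` of a length-`L` segment occupies the fractional
#' span `[(i-1)*bins/L, i*bins/L)` and spreads its unit weight over the
#' bins it overlaps, proportionally to the overlap. This conserves mass
#' (total profile weight equals the summed segment lengths under residue
#' weighting) and is unbiased by segment length. With
#' `weighting = "sequence"` each segment contributes total weight 1
#' instead, so long segments do not dominate.
#'
#' @param segments Segment tibble (needs a `sequence` column).
#' @param bins Number of scaled positions.
#' @param weighting `"residue"` (default) or `"sequence"`.
#' @return An object of class `nre_scaled_profile`: list with `freq`
#'   (`bins` x 21 per-bin frequencies over the 20 standard letters plus
#'   `other` for degenerate codes), `weight` (per-bin x letter weights),
#'   `support` (per-bin total weight) and `n` (segments used).
#' @export
scaled_composition <- function(segments, bins = 200,
                               weighting = c("residue", "sequence")) {
  weighting <- match.arg(weighting)
  stopifnot(nrow(segments) >= 1, all(nchar(segments$sequence) >= 1))
  letters21 <- c(aa_alphabet(), "other")
  W <- matrix(0, nrow = bins, ncol = 21,
              dimnames = list(NULL, letters21))
  for (s in segments$sequence) {
    L <- nchar(s)
    enc <- aa_encode(s)
    col <- ifelse(enc <= 20, enc, 21L)
    lo <- (seq_len(L) - 1) * bins / L
    hi <- seq_len(L) * bins / L
    b0 <- floor(lo)
    b1 <- pmin(ceiling(hi - 1e-9) - 1, bins - 1)
    nb <- b1 - b0 + 1L
    bin_idx <- unlist(mapply(seq, b0, b1, SIMPLIFY = FALSE), use.names = FALSE)
    res_rep <- rep(seq_len(L), nb)
    ov <- pmin(bin_idx + 1, hi[res_rep]) - pmax(bin_idx, lo[res_rep])
    w <- ov * L / bins
    if (weighting == "sequence") w <- w / L
    # accumulate (duplicate bin/letter pairs possible across residues)
    key0 <- bin_idx * 21L + (col[res_rep] - 1L)
    acc <- rowsum(w, group = key0)
    keys <- as.integer(rownames(acc))
    at <- cbind(keys %/% 21L + 1L, keys %% 21L + 1L)
    W[at] <- W[at] + acc[, 1]
  }
  support <- rowSums(W)
  freq <- W / ifelse(support > 0, support, 1)
  structure(list(freq = freq, weight = W, support = support,
                 bins = bins, n = nrow(segments), weighting = weighting),
            class = "nre_scaled_profile")
}

#' Terminal sequence logo matrix
#'
#' Per-column letter frequencies over the first (`end = "N"`) or last
#' (`end = "C"`) `window` residues of each segment, with per-column
#' information content `ic = log2(20) - H` in bits (Shannon entropy of the
#' empirical frequencies; no small-sample correction -- `n` is reported so
#' users can judge). Segments shorter than the window are excluded and
#' counted; if none remain this is an error.
#'
#' @param segments Segment tibble.
#' @param window Residues per logo.
#' @param end `"N"` or `"C"` terminus.
#' @return Object of class `nre_logo`: list with `freq` (`window` x 20),
#'   `ic` (bits per column), `n`, `end`, `excluded`.
#' @export
terminal_logo <- function(segments, window = 20, end = c("C", "N")) {
  end <- match.arg(end)
  keep <- nchar(segments$sequence) >= window
  excluded <- sum(!keep)
  if (!any(keep)) {
    stop("all segments shorter than the ", window, "-residue window",
         call. = FALSE)
  }
  seqs <- segments$sequence[keep]
  sub <- if (end == "N") {
    substr(seqs, 1L, window)
  } else {
    substr(seqs, nchar(seqs) - window + 1L, nchar(seqs))
  }
  E <- aa_expansion_matrix() # degenerate letters split uniformly
  counts <- matrix(0, nrow = window, ncol = 20,
                   dimnames = list(NULL, aa_alphabet()))
  encs <- lapply(sub, aa_encode)
  for (k in seq_len(window)) {
    letters_k <- vapply(encs, `[[`, 0L, k)
    tab <- rowsum(rep(1, length(letters_k)), group = letters_k)
    counts[k, ] <- colSums(E[as.integer(rownames(tab)), , drop = FALSE] *
                             as.numeric(tab))
  }
  freq <- counts / rowSums(counts)
  H <- apply(freq, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  structure(list(freq = freq, ic = log2(20) - H, n = length(seqs),
                 end = end, excluded = excluded),
            class = "nre_logo")
}

# The degenerate 14-residue C-terminal consensus as a list of allowed
# letters per position: F S Y E E L E K A T [D/N] N F [S/D].
signature_pattern <- function() {
  pat <- as.list(strsplit("FSYEELEKAT.NF.", "")[[1]])
  pat[[11]] <- c("D", "N")
  pat[[14]] <- c("S", "D")
  pat
}

#' Detect the 14-residue C-terminal consensus and ST motif
#'
#' Scans the last `search_window` residues of a sequence for the best
#' ungapped match to the degenerate consensus `FSYEELEKAT[D/N]NF[S/D]`
#' (degenerate positions agree on either letter). A hit requires at least
#' `min_agree` of 14 positional agreements; ties in agreement go to the
#' match closest to the C-terminus. Independently of the hit position,
#' `st_motif_present` reports whether the segment ends in the helix-capping
#' ST-motif signature T-x-x-F (T at position -5, F at -2, counting -1 as
#' the last residue), and `thr_minus5` whether the residue at -5 is T.
#'
#' @param sequence Amino-acid string (length >= 14).
#' @param min_agree Minimum positional agreements for a hit.
#' @param search_window C-terminal residues scanned.
#' @return Tibble with 0 rows (no hit) or 1 row: `start, end, agreements,
#'   matched (14-character 0/1 string), st_motif_present, thr_minus5`.
#' @export
find_signature <- function(sequence, min_agree = 10, search_window = 40) {
  L <- nchar(sequence)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          agreements = integer(), matched = character(),
                          st_motif_present = logical(),
                          thr_minus5 = logical())
  if (L < 14) return(empty)
  pat <- signature_pattern()
  from <- max(1L, L - search_window + 1L)
  starts <- from:(L - 13L)
  chars <- strsplit(sequence, "")[[1]]
  agree <- vapply(starts, function(s) {
    sum(vapply(1:14, function(k) chars[s + k - 1L] %in% pat[[k]], TRUE))
  }, 0L)
  best <- which(agree == max(agree))
  best <- best[length(best)] # nearest the C-terminus on ties
  if (agree[best] < min_agree) return(empty)
  s <- starts[best]
  matched <- paste(as.integer(
    vapply(1:14, function(k) chars[s + k - 1L] %in% pat[[k]], TRUE)),
    collapse = "")
  st <- L >= 5 && chars[L - 4L] == "T" && chars[L - 1L] == "F"
  tibble::tibble(start = s, end = s + 13L, agreements = agree[best],
                 matched = matched, st_motif_present = st,
                 thr_minus5 = chars[L - 4L] == "T")
}

#' Call LRR-VI-2 NRE types
#'
#' The LRR-VI-2 class splits into two NRE types: type 1 carries
#' experimentally determined phosphosites at positions -28 (S) and -31 (T)
#' from the segment C-terminus and matches the class motif; type 2 does
#' not. A segment is type 1 iff its residue at -28 (counting -1 as the
#' last residue) is serine AND the class motif matches the segment at the
#' configured scan threshold. Segments shorter than 31 residues are type 2
#' with `short = TRUE`.
#'
#' @param segments Segment tibble.
#' @param motif An `nre_motif` (the class motif).
#' @param config An [nre_config()] list (`scan_p` is used).
#' @return Tibble `protein_id, type, s_minus28, motif_match, short`.
#' @export
classify_lrr_vi_2_type <- function(segments, motif, config = nre_config()) {
  matches <- scan_motif(motif, segments, p_threshold = config$scan_p,
                        resolution = config$pvalue_resolution)
  matched_ids <- unique(matches$sequence_id)
  purrr::pmap(
    list(segments$protein_id, segments$sequence),
    function(id, s) {
      L <- nchar(s)
      short <- L < 31
      s28 <- !short && substr(s, L - 27L, L - 27L) == "S"
      mm <- id %in% matched_ids
      tibble::tibble(protein_id = id,
                     type = if (!short && s28 && mm) "type1" else "type2",
                     s_minus28 = s28, motif_match = mm, short = short)
    }) |>
    dplyr::bind_rows()
}

#' Occurrence of NRE topologies by plant group and class
#'
#' Contingency counts of topology categories per plant group x class, plus
#' each group/class's percentage of TM-bearing topologies (RK and
#' RLCK_TM). Zero rows are retained for supplied groups; species missing
#' from the mapping fall into group `"unknown"`.
#'
#' @param proteins Protein tibble.
#' @param topology Topology tibble from [assign_topology()].
#' @param species_groups Optional tibble `species, group`.
#' @return Tibble `group, class_label, category, n, pct_tm_bearing`.
#' @export
summarize_occurrence <- function(proteins, topology, species_groups = NULL) {
  df <- dplyr::left_join(
    proteins[, c("id", "species", "class_label")], topology,
    by = c(id = "protein_id"))
  if (is.null(species_groups)) {
    df$group <- df$species
    groups <- unique(df$group)
  } else {
    df <- dplyr::left_join(df, species_groups, by = "species")
    df$group[is.na(df$group)] <- "unknown"
    groups <- unique(c(species_groups$group, df$group))
  }
  counts <- df |>
    dplyr::count(.data$group, .data$class_label, .data$category, name = "n") |>
    tidyr::complete(group = groups,
                    tidyr::nesting(!!rlang::sym("class_label"),
                                   !!rlang::sym("category")),
                    fill = list(n = 0L))
  counts |>
    dplyr::group_by(.data$group, .data$class_label) |>
    dplyr::mutate(pct_tm_bearing = if (sum(.data$n) > 0) {
      100 * sum(.data$n[.data$category %in% c("RK", "RLCK_TM")]) /
        sum(.data$n)
    } else {
      NA_real_
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$group, .data$class_label, .data$category)
}
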