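# Topology classification: receptor kinases (RK) versus receptor-like
# cytoplasmic kinases with (RLCK_TM) or without (RLCK_noTM) a
# transmembrane helix.

#' Consensus transmembrane intervals across annotation sources
#'
#' Intervals corroborated by at least two sources (pairwise overlap of at
#' least `min_overlap` residues) are reported as the intersection of the
#' corroborating intervals. Intervals with no cross-source support pass
#' through flagged `single_source`; with a single input source everything
#' passes through flagged.
#'
#' @param intervals Tibble with columns `source, start, end` (1-based,
#'   inclusive), zero or more rows.
#' @param min_overlap Minimum pairwise overlap, in residues.
#' @return Tibble `start, end, source, single_source`, sorted by `start`.
#' @export
consensus_tm <- function(intervals, min_overlap = 5) {
  empty <- tibble::tibble(start = integer(), end = integer(),
                          source = character(), single_source = logical())
  if (is.null(intervals) || nrow(intervals) == 0) return(empty)
  iv <- dplyr::arrange(tibble::as_tibble(intervals), .data$start, .data$end)
  n <- nrow(iv)
  # cross-source overlap graph -> connected components
  comp <- seq_len(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && iv$source[i] != iv$source[j]) {
        ov <- min(iv$end[i], iv$end[j]) - max(iv$start[i], iv$start[j]) + 1
        if (ov >= min_overlap) {
          comp[comp == comp[j]] <- comp[i]
        }
      }
    }
  }
  out <- lapply(unique(comp), function(cc) {
    members <- which(comp == cc)
    if (length(unique(iv$source[members])) >= 2) {
      s <- max(iv$start[members]); e <- min(iv$end[members])
      if (s <= e) {
        return(tibble::tibble(start = s, end = e, source = "consensus",
                              single_source = FALSE))
      }
    }
    tibble::tibble(start = iv$start[members], end = iv$end[members],
                   source = iv$source[members], single_source = TRUE)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$end)
}

#' Hydrophobicity fallback transmembrane detector
#'
#' A single-pass Kyte-Doolittle scan used only when no transmembrane
#' annotation is available: positions whose centred `window`-residue mean
#' hydropathy reaches `gravy_threshold` (windows truncate at the sequence
#' termini) are collected into maximal runs,
#' and runs of at least `min_len` positions are reported as candidate TM
#' intervals. Sequences shorter than the window yield no intervals.
#'
#' @param sequence Amino-acid string.
#' @param window Odd window length, at least 11.
#' @param gravy_threshold Mean-hydropathy cutoff.
#' @param min_len Minimum reported run length, residues.
#' @return Tibble `start, end, source` (source = "fallback").
#' @export
detect_tm_fallback <- function(sequence, window = 19, gravy_threshold = 1.6,
                               min_len = 15) {
  stopifnot(window %% 2 == 1, window >= 11)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          source = character())
  L <- nchar(sequence)
  if (L < window) return(empty)
  enc <- aa_encode(sequence)
  # degenerate letters take the mean hydropathy of their expansion set
  exp_m <- aa_expansion_matrix()
  kd_ext <- as.numeric(exp_m %*% kyte_doolittle[aa_alphabet()])
  h <- kd_ext[enc]
  half <- (window - 1) / 2
  # windows truncate at the sequence edges so helices close to a terminus
  # remain detectable
  cs <- cumsum(c(0, h))
  lo <- pmax(seq_len(L) - half, 1)
  hi <- pmin(seq_len(L) + half, L)
  means <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  centers <- which(means >= gravy_threshold)
  if (length(centers) == 0) return(empty)
  breaks <- c(0, which(diff(centers) > 1), length(centers))
  runs <- lapply(seq_len(length(breaks) - 1), function(k) {
    r <- centers[(breaks[k] + 1):breaks[k + 1]]
    tibble::tibble(start = r[1], end = r[length(r)], source = "fallback")
  })
  out <- dplyr::bind_rows(runs)
  out[out$end - out$start + 1 >= min_len, , drop = FALSE]
}

# TM intervals for one protein: annotated intervals (consensus across
# sources) when present, otherwise the fallback detector.
protein_tm_intervals <- function(sequence, annotations, config) {
  ann_tm <- annotations[annotations$kind == "transmembrane", , drop = FALSE]
  if (nrow(ann_tm) > 0) {
    return(consensus_tm(ann_tm[, c("source", "start", "end")]))
  }
  detect_tm_fallback(sequence, window = config$tm_window,
                     gravy_threshold = config$tm_gravy_threshold)
}

#' Assign RK / RLCK topology categories
#'
#' Each protein is assigned exactly one category from the presence of an
#' annotated ectodomain, a transmembrane helix (annotated consensus, or the
#' fallback detector when no annotation exists), and the extracellular
#' length: `RK` when it has both ectodomain and TM; `RLCK_TM` when it has a
#' TM but no ectodomain and fewer than `extracellular_max_len` residues
#' N-terminal of the TM (signal peptide excluded); `RLCK_noTM` when it has
#' no TM; `unclassified` otherwise. With multiple TM intervals the most
#' N-terminal one defines the extracellular length.
#'
#' @param proteins Protein tibble from [read_proteins()].
#' @param config An [nre_config()] list.
#' @return Tibble `protein_id, category, has_ecd, has_tm, extracellular_len,
#'   tm_start, tm_end` (NA TM coordinates when no TM).
#' @export
assign_topology <- function(proteins, config = nre_config()) {
  rows <- purrr::pmap(
    list(proteins$id, proteins$sequence, proteins$annotations),
    function(id, sequence, ann) {
      tm <- protein_tm_intervals(sequence, ann, config)
      has_tm <- nrow(tm) > 0
      has_ecd <- any(ann$kind == "ecd")
      sp_len <- 0
      sp <- ann[ann$kind == "signal_peptide", , drop = FALSE]
      if (nrow(sp) > 0) sp_len <- sum(sp$end - sp$start + 1)
      if (has_tm) {
        first <- which.min(tm$start)
        tm_start <- tm$start[first]; tm_end <- tm$end[first]
        ecl <- max(0L, tm_start - 1L - sp_len)
      } else {
        tm_start <- NA_integer_; tm_end <- NA_integer_; ecl <- 0L
      }
      category <- if (has_ecd && has_tm) {
        "RK"
      } else if (has_tm && !has_ecd && ecl < config$extracellular_max_len) {
        "RLCK_TM"
      } else if (!has_tm) {
        "RLCK_noTM"
      } else {
        "unclassified"
      }
      tibble::tibble(protein_id = id, category = category,
                     has_ecd = has_ecd, has_tm = has_tm,
                     extracellular_len = as.integer(ecl),
                     tm_start = as.integer(tm_start),
                     tm_end = as.integer(tm_end))
    })
  dplyr::bind_rows(rows)
}
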