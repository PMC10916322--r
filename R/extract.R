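# Kinase-domain boundary refinement via the (L/I/V)GXG anchor and NRE
# (juxtamembrane / N-terminal kinase extension) segment extraction.

# Does an [LIV]G.G 4-mer begin at 1-based position p of `sequence`?
anchor_at <- function(sequence, p) {
  if (p < 1 || p + 3 > nchar(sequence)) return(FALSE)
  grepl("^[LIVJ]G.G", substr(sequence, p, p + 3))
}

#' Refine a kinase-domain start with the (L/I/V)GXG anchor
#'
#' Plant RLK kinase domains carry a conserved (L/I/V)GXG 4-mer at positions
#' 5-8. Given an approximate annotated start, the candidate start `d`
#' within `approx_start +/- search_radius` whose positions 5-8 (i.e. the
#' 4-mer beginning at `d + 4`) match `[LIV]G.G` is chosen; among several
#' candidates the one closest to the annotation wins, ties going to the
#' smaller (more N-terminal) start. If no candidate matches, the
#' annotation is kept with `refined = FALSE`.
#'
#' @param sequence Protein sequence.
#' @param approx_start Annotated 1-based kinase-domain start.
#' @param search_radius Residues searched on both sides.
#' @return One-row tibble `domain_start, anchor_start, anchor_offset,
#'   refined` (`anchor_start`/`anchor_offset` NA when unrefined).
#' @export
locate_kinase_start <- function(sequence, approx_start, search_radius = 30) {
  L <- nchar(sequence)
  if (approx_start < 1 || approx_start > L) {
    stop("kinase-domain annotation start ", approx_start,
         " outside the sequence (length ", L, ")", call. = FALSE)
  }
  cand <- seq(max(1L, approx_start - search_radius),
              min(L, approx_start + search_radius))
  hits <- cand[vapply(cand, function(d) anchor_at(sequence, d + 4L), TRUE)]
  if (length(hits) == 0) {
    return(tibble::tibble(domain_start = as.integer(approx_start),
                          anchor_start = NA_integer_,
                          anchor_offset = NA_integer_, refined = FALSE))
  }
  dist <- abs(hits - approx_start)
  best <- hits[order(dist, hits)][1]
  tibble::tibble(domain_start = as.integer(best),
                 anchor_start = as.integer(best + 4L),
                 anchor_offset = 5L, refined = TRUE)
}

# Extract the NRE segment of one protein; stops on boundary conflict.
extract_nre_one <- function(id, sequence, annotations, category,
                            tm_start, tm_end, domain_start) {
  if (category %in% c("RK", "RLCK_TM")) {
    if (is.na(tm_end)) {
      stop("protein ", id, ": TM-bearing topology without a TM interval",
           call. = FALSE)
    }
    if (tm_end >= domain_start) {
      stop("protein ", id, ": boundary conflict, TM end ", tm_end,
           " >= kinase start ", domain_start, call. = FALSE)
    }
    s <- tm_end + 1L
    kind <- "JM"
  } else {
    sp <- annotations[annotations$kind == "signal_peptide", , drop = FALSE]
    s <- if (nrow(sp) > 0) as.integer(max(sp$end) + 1L) else 1L
    kind <- "NKE"
  }
  e <- as.integer(domain_start - 1L)
  if (s > e) return(NULL) # empty segment, counted by the caller
  other <- annotations[annotations$kind == "other_domain", , drop = FALSE]
  has_dom <- nrow(other) > 0 && any(other$start <= e & other$end >= s)
  tibble::tibble(protein_id = id, kind = kind, start = s, end = e,
                 length = e - s + 1L,
                 sequence = substr(sequence, s, e),
                 has_internal_domain = has_dom)
}

#' Extract NRE segments for a dataset
#'
#' For each classified protein the kinase-domain start is refined with
#' [locate_kinase_start()] from its `kinase_domain` annotation, and the NRE
#' is cut: the juxtamembrane segment `[tm_end + 1, domain_start - 1]` for
#' TM-bearing topologies, or the N-terminal kinase extension
#' `[1, domain_start - 1]` (after any annotated signal peptide) for RLCKs
#' without TM. Proteins without a kinase annotation, with an empty segment,
#' or with a TM/kinase boundary conflict produce no segment and are counted
#' in the `qc` attribute.
#'
#' @param proteins Protein tibble from [read_proteins()].
#' @param topology Topology tibble from [assign_topology()].
#' @param config An [nre_config()] list.
#' @param refine_anchor Refine kinase starts with the (L/I/V)GXG anchor
#'   (set `FALSE` to trust annotations verbatim).
#' @return Segment tibble `protein_id, kind, start, end, length, sequence,
#'   has_internal_domain, refined, species, class_label` with a `qc`
#'   attribute.
#' @export
extract_nre <- function(proteins, topology, config = nre_config(),
                        refine_anchor = TRUE) {
  tp <- dplyr::left_join(proteins, topology, by = c(id = "protein_id"))
  qc <- c(no_kinase_annotation = 0L, unclassified = 0L,
          empty_segment = 0L, boundary_conflict = 0L)
  out <- vector("list", nrow(tp))
  for (i in seq_len(nrow(tp))) {
    ann <- tp$annotations[[i]]
    if (tp$category[i] == "unclassified") {
      qc["unclassified"] <- qc["unclassified"] + 1L
      next
    }
    kd <- ann[ann$kind == "kinase_domain", , drop = FALSE]
    if (nrow(kd) == 0) {
      qc["no_kinase_annotation"] <- qc["no_kinase_annotation"] + 1L
      next
    }
    approx <- as.integer(min(kd$start))
    ds <- if (refine_anchor) {
      locate_kinase_start(tp$sequence[i], approx,
                          config$anchor_search_radius)
    } else {
      tibble::tibble(domain_start = approx, refined = FALSE)
    }
    seg <- tryCatch(
      extract_nre_one(tp$id[i], tp$sequence[i], ann, tp$category[i],
                      tp$tm_start[i], tp$tm_end[i], ds$domain_start),
      error = function(e) {
        if (grepl("boundary conflict", conditionMessage(e))) {
          warning(conditionMessage(e), call. = FALSE)
          structure(list(), class = "nre_conflict")
        } else {
          stop(e)
        }
      })
    if (inherits(seg, "nre_conflict")) {
      qc["boundary_conflict"] <- qc["boundary_conflict"] + 1L
    } else if (is.null(seg)) {
      qc["empty_segment"] <- qc["empty_segment"] + 1L
    } else {
      seg$refined <- ds$refined
      seg$species <- tp$species[i]
      seg$class_label <- tp$class_label[i]
      out[[i]] <- seg
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "qc") <- qc
  res
}

#' Strip the C-terminal consensus before motif analysis
#'
#' Removes the last `n` residues of every segment (by default the
#' 14-residue C-terminal consensus region). Segments of length `<= n`
#' yield no trimmed segment and are counted in the `qc` attribute.
#'
#' @param segments Segment tibble from [extract_nre()].
#' @param n Residues to strip.
#' @return Trimmed segment tibble (same columns, updated `end, length,
#'   sequence`) with a `qc` attribute.
#' @export
strip_cterminal <- function(segments, n = 14) {
  stopifnot(n >= 0)
  too_short <- segments$length <= n
  out <- segments[!too_short, , drop = FALSE]
  if (n > 0 && nrow(out) > 0) {
    out$end <- out$end - as.integer(n)
    out$length <- out$length - as.integer(n)
    out$sequence <- substr(out$sequence, 1L, out$length)
  }
  attr(out, "qc") <- c(dropped_short = sum(too_short))
  out
}
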