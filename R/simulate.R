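# Ground-truthed synthetic RLK dataset generator. Each protein is
# assembled as [signal peptide?][ECD (RK only)][TM 21-mer][NRE][kinase
# stub], where the NRE is a basic N-terminal run, a serine-rich middle
# optionally carrying a planted class motif, and the 14-residue C-terminal
# consensus; the kinase stub carries the (L/I/V)GXG anchor at positions
# 5-8 and is rejection-sampled so no second anchor occurs inside the
# search window, making boundary recovery well-posed.

# Default class motifs: published NRE motif consensi with their reported
# phosphosite offsets (1-based within the motif).
default_class_motifs <- function() {
  tibble::tibble(
    class_label = c("LRR-VI-2", "PERK-2", "LRR-Xb-1", "RLCK-IV"),
    motif = c("VGPWKTGLSGQLQKAFVTGVP",
              "SQPKVLRLNLVGSPKKEPEP",
              "KEPLSINVATFEKPL",
              "KVPASPLRVPPSPSRFSMSPKLNR"),
    phospho_offsets = list(c(6L, 9L), 13L, 5L, c(5L, 12L))
  )
}

# Serine-rich middle-NRE letter composition.
mid_background <- function(serine_level = 0.25) {
  ab <- aa_alphabet()
  w <- stats::setNames(rep(1, 20), ab)
  w[c("P", "E", "K", "T", "A", "R", "N", "D", "G", "Q", "V", "L")] <- 1.6
  w["S"] <- 0
  w <- w / sum(w) * (1 - serine_level)
  w["S"] <- serine_level
  w
}

sample_letters <- function(n, probs) {
  if (n <= 0) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# The 14-residue C-terminal consensus with its two degenerate positions.
consensus_tail <- function(p_d, p_s) {
  tail <- strsplit("FSYEELEKATDNFS", "")[[1]]
  tail[11] <- if (stats::runif(1) < p_d) "D" else "N"
  tail[14] <- if (stats::runif(1) < p_s) "S" else "D"
  tail
}

#' Generate a fully annotated synthetic RLK dataset
#'
#' Emits proteins in the same shape [read_proteins()] returns, a
#' phosphosite table in the shape [read_phosphosites()] returns, and a
#' ground-truth table with every planted coordinate, so each pipeline
#' stage can be scored exactly. Deterministic given `seed`.
#'
#' Defaults emulate the large-scale survey conditions: topology mix
#' proportional to the reported RK / RLCK-with-TM / RLCK-without-TM
#' occurrence, NRE lengths from a two-mode mixture (modes 40 and 50), a
#' basic (R/K) N-terminal run, a serine-rich middle, one published motif
#' consensus planted per class at `planting_rate` with per-position
#' substitution noise, and the 14-residue C-terminal consensus with its
#' D/N and S/D variants. Phosphosites are emitted at the planted motif
#' offsets (protected from substitution so the site residue always matches
#' the sequence); `background_site_rate` adds random S/T/Y sites outside
#' motifs to exercise non-containment paths.
#'
#' @param n_proteins Number of proteins.
#' @param class_motifs Tibble `class_label, motif, phospho_offsets`
#'   (list-column of integer offsets); defaults to four published consensi.
#'   A class with `motif = NA` carries no planted motif.
#' @param topology_mix Named fractions for RK, RLCK_TM, RLCK_noTM.
#' @param nre_modes,nre_sds,nre_weights NRE length mixture-of-normals.
#' @param planting_rate Probability a protein of a motif-bearing class
#'   carries its class motif.
#' @param substitution_rate Per-position probability a planted motif
#'   letter is replaced by a random different letter.
#' @param serine_level Serine fraction of the middle-NRE composition.
#' @param basic_run Length of the R/K-rich run at the NRE N-terminus.
#' @param tail_dn_d,tail_sd_s Probabilities of D (vs N) at consensus
#'   position 11 and S (vs D) at position 14.
#' @param n_species Number of species labels.
#' @param signal_peptide_prob Probability an RK gets a 20-residue signal
#'   peptide.
#' @param internal_domain_rate Fraction of NREs annotated with an internal
#'   `other_domain` (exercises the domain-exclusion rule).
#' @param background_site_rate Expected number of random S/T/Y
#'   phosphosites per NRE outside planted motifs.
#' @param seed Integer seed.
#' @return List with elements `proteins`, `phosphosites`, `truth`
#'   (tibbles) and `params`.
#' @export
simulate_rlk_dataset <- function(n_proteins = 300,
                                 class_motifs = default_class_motifs(),
                                 topology_mix = c(RK = 0.614, RLCK_TM = 0.091,
                                                  RLCK_noTM = 0.295),
                                 nre_modes = c(40, 50),
                                 nre_sds = c(8, 8),
                                 nre_weights = c(0.6, 0.4),
                                 planting_rate = 0.8,
                                 substitution_rate = 0.1,
                                 serine_level = 0.25,
                                 basic_run = 8,
                                 tail_dn_d = 0.7,
                                 tail_sd_s = 0.7,
                                 n_species = 5,
                                 signal_peptide_prob = 0.5,
                                 internal_domain_rate = 0,
                                 background_site_rate = 0,
                                 seed = 1L) {
  stopifnot(abs(sum(topology_mix) - 1) < 1e-9,
            planting_rate >= 0, planting_rate <= 1,
            substitution_rate >= 0, substitution_rate <= 1,
            internal_domain_rate >= 0, internal_domain_rate < 1)
  set.seed(as.integer(seed))
  ab <- aa_alphabet()
  midbg <- mid_background(serine_level)
  kd_len <- 80L
  tail_len <- 14L
  species_pool <- sprintf("species_%02d", seq_len(n_species))

  proteins <- vector("list", n_proteins)
  sites <- vector("list", n_proteins)
  truth <- vector("list", n_proteins)

  for (i in seq_len(n_proteins)) {
    id <- sprintf("SYN%05d", i)
    cls <- class_motifs$class_label[(i - 1L) %% nrow(class_motifs) + 1L]
    motif_row <- class_motifs[class_motifs$class_label == cls, ]
    species <- sample(species_pool, 1)
    category <- sample(names(topology_mix), 1, prob = topology_mix)

    for (attempt in 1:20) {
      # --- NRE ---
      comp <- sample(seq_along(nre_modes), 1, prob = nre_weights)
      has_motif <- !is.na(motif_row$motif[[1]])
      motif_letters <- if (has_motif) {
        strsplit(motif_row$motif[[1]], "")[[1]]
      } else {
        character(0)
      }
      mw <- length(motif_letters)
      plant <- has_motif && stats::runif(1) < planting_rate
      min_len <- basic_run + tail_len + (if (plant) mw + 2L else 4L)
      nre_len <- max(min_len,
                     round(stats::rnorm(1, nre_modes[comp], nre_sds[comp])))
      mid_len <- nre_len - basic_run - tail_len
      mid <- sample_letters(mid_len, midbg)
      motif_start_mid <- NA_integer_
      offsets <- integer(0)
      if (plant) {
        motif_start_mid <- sample.int(mid_len - mw + 1L, 1)
        offsets <- motif_row$phospho_offsets[[1]]
        inst <- motif_letters
        # expand degenerate consensus letters
        deg <- aa_degenerate()
        for (k in seq_len(mw)) {
          if (inst[k] %in% names(deg)) inst[k] <- sample(deg[[inst[k]]], 1)
        }
        sub <- stats::runif(mw) < substitution_rate
        sub[offsets] <- FALSE # phosphosite residues are protected
        inst[sub] <- vapply(inst[sub],
                            function(l) sample(setdiff(ab, l), 1), "")
        mid[motif_start_mid:(motif_start_mid + mw - 1L)] <- inst
      }
      nre <- c(sample(c("R", "K"), basic_run, replace = TRUE),
               mid, consensus_tail(tail_dn_d, tail_sd_s))

      # --- flanks ---
      sp_len <- 0L
      ecd_len <- 0L
      tm <- character(0)
      if (category == "RK") {
        if (stats::runif(1) < signal_peptide_prob) sp_len <- 20L
        ecd_len <- sample(80:200, 1)
        tm <- sample(c("L", "I", "V", "F", "A"), 21, replace = TRUE,
                     prob = c(0.35, 0.25, 0.25, 0.1, 0.05))
      } else if (category == "RLCK_TM") {
        ecd_len <- sample(5:40, 1) # short extracellular stretch, no ECD
        tm <- sample(c("L", "I", "V", "F", "A"), 21, replace = TRUE,
                     prob = c(0.35, 0.25, 0.25, 0.1, 0.05))
      }
      sp <- sample_letters(sp_len, midbg)
      ecd <- sample_letters(ecd_len, midbg)

      # --- kinase stub with anchor at positions 5-8 ---
      kd <- sample_letters(kd_len, midbg)
      kd[5:8] <- c(sample(c("L", "I", "V"), 1), "G",
                   sample(ab, 1), "G")

      seq_chars <- c(sp, ecd, tm, nre, kd)
      prefix_len <- sp_len + ecd_len + length(tm)
      nre_start <- prefix_len + 1L
      nre_end <- prefix_len + nre_len
      kinase_start <- nre_end + 1L
      anchor_pos <- kinase_start + 4L

      # enforce anchor uniqueness inside the search window
      win_lo <- max(1L, kinase_start - 26L)
      win_hi <- min(length(seq_chars) - 3L, kinase_start + 34L)
      immutable <- c(anchor_pos:(anchor_pos + 3L),
                     (nre_end - tail_len + 1L):nre_end)
      if (plant) {
        ms <- nre_start + basic_run + motif_start_mid - 1L
        immutable <- c(immutable, ms:(ms + mw - 1L))
      }
      ok <- TRUE
      for (p in win_lo:win_hi) {
        if (p == anchor_pos) next
        while (seq_chars[p] %in% c("L", "I", "V", "J") &&
               seq_chars[p + 1L] == "G" && seq_chars[p + 3L] == "G") {
          fixable <- setdiff(c(p + 1L, p + 3L, p), immutable)
          if (length(fixable) == 0) { ok <- FALSE; break }
          q <- fixable[1]
          seq_chars[q] <- if (q == p) "S" else "T"
        }
        if (!ok) break
      }
      if (ok) break
    }
    if (!ok) stop("could not place a unique kinase anchor for ", id,
                  call. = FALSE)

    sequence <- paste(seq_chars, collapse = "")

    # --- annotations ---
    ann <- list()
    if (sp_len > 0) {
      ann[[length(ann) + 1]] <- tibble::tibble(
        kind = "signal_peptide", start = 1, end = sp_len, source = "truth")
    }
    if (category == "RK") {
      ann[[length(ann) + 1]] <- tibble::tibble(
        kind = "ecd", start = sp_len + 1, end = sp_len + ecd_len,
        source = "truth")
    }
    if (category %in% c("RK", "RLCK_TM")) {
      tm_start <- sp_len + ecd_len + 1L
      tm_end <- tm_start + 20L
      ann[[length(ann) + 1]] <- tibble::tibble(
        kind = "transmembrane", start = rep(tm_start, 2), end = rep(tm_end, 2),
        source = c("tmhmm", "phobius"))
    } else {
      tm_start <- NA_integer_; tm_end <- NA_integer_
    }
    has_internal <- stats::runif(1) < internal_domain_rate
    if (has_internal) {
      dstart <- nre_start + basic_run
      ann[[length(ann) + 1]] <- tibble::tibble(
        kind = "other_domain", start = dstart, end = dstart + 5,
        source = "truth")
    }
    ann[[length(ann) + 1]] <- tibble::tibble(
      kind = "kinase_domain", start = kinase_start,
      end = length(seq_chars), source = "truth")
    annotations <- dplyr::arrange(dplyr::bind_rows(ann), .data$start)

    # --- phosphosites ---
    site_pos <- integer(0)
    motif_start <- NA_integer_; motif_end <- NA_integer_
    if (plant) {
      motif_start <- nre_start + basic_run + motif_start_mid - 1L
      motif_end <- motif_start + mw - 1L
      site_pos <- motif_start + offsets - 1L
    }
    if (background_site_rate > 0) {
      n_bg <- stats::rpois(1, background_site_rate)
      cand <- setdiff(which(seq_chars %in% c("S", "T", "Y")), site_pos)
      cand <- cand[cand >= nre_start & cand <= nre_end]
      if (plant) cand <- cand[cand < motif_start | cand > motif_end]
      if (n_bg > 0 && length(cand) > 0) {
        site_pos <- c(site_pos, sample(cand, min(n_bg, length(cand))))
      }
    }
    if (length(site_pos) > 0) {
      sites[[i]] <- tibble::tibble(
        protein_id = id, position = as.integer(site_pos),
        residue = seq_chars[site_pos], source = "synthetic")
    }

    proteins[[i]] <- tibble::tibble(
      id = id, species = species, class_label = cls, sequence = sequence,
      annotations = list(annotations))
    truth[[i]] <- tibble::tibble(
      protein_id = id, species = species, class_label = cls,
      category = category,
      sp_len = sp_len, tm_start = tm_start, tm_end = tm_end,
      nre_start = nre_start, nre_end = nre_end,
      kinase_start = kinase_start,
      motif_start = motif_start, motif_end = motif_end,
      has_internal_domain = has_internal,
      n_phosphosites = length(site_pos))
  }

  list(proteins = dplyr::bind_rows(proteins),
       phosphosites = dplyr::bind_rows(sites),
       truth = dplyr::bind_rows(truth),
       params = list(n_proteins = n_proteins, topology_mix = topology_mix,
                     planting_rate = planting_rate,
                     substitution_rate = substitution_rate,
                     class_motifs = class_motifs, seed = seed))
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' Emits `proteins.fasta`, `annotations.tsv`, `phosphosites.tsv` and
#' `truth.tsv` under `dir`, exactly the formats [read_proteins()] and
#' [read_phosphosites()] consume.
#'
#' @param sim Result of [simulate_rlk_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "proteins.fasta")
  seqs <- Biostrings::AAStringSet(sim$proteins$sequence)
  names(seqs) <- sim$proteins$id
  Biostrings::writeXStringSet(seqs, fasta)

  ann <- sim$proteins |>
    dplyr::select("id", "species", "class_label", "annotations") |>
    tidyr::unnest("annotations") |>
    dplyr::rename(protein_id = "id")
  ann_path <- file.path(dir, "annotations.tsv")
  write_table(ann, ann_path, key = c("protein_id", "start", "end", "kind"))

  ph_path <- file.path(dir, "phosphosites.tsv")
  ph <- sim$phosphosites
  if (is.null(ph) || nrow(ph) == 0) {
    ph <- tibble::tibble(protein_id = character(), position = integer(),
                         residue = character(), source = character())
  }
  write_table(ph, ph_path, key = c("protein_id", "position"))

  truth_path <- file.path(dir, "truth.tsv")
  write_table(sim$truth, truth_path, key = "protein_id")

  invisible(c(fasta = fasta, annotations = ann_path,
              phosphosites = ph_path, truth = truth_path))
}

#' Perturb annotations to exercise recovery paths
#'
#' Shifts every kinase-domain annotation start by an integer drawn
#' uniformly from `[-jitter, jitter]` (clamped to the sequence) and removes
#' all transmembrane annotations from a `dropout` fraction of proteins
#' (forcing the hydrophobicity fallback detector). Ground truth is
#' untouched.
#'
#' @param sim Result of [simulate_rlk_dataset()].
#' @param jitter Maximum absolute shift, residues (>= 0).
#' @param dropout Fraction of proteins losing TM annotations, in `[0, 1)`.
#' @param seed Integer seed.
#' @return `sim` with perturbed `proteins$annotations`.
#' @export
corrupt_annotations <- function(sim, jitter = 0, dropout = 0, seed = 1L) {
  stopifnot(jitter >= 0, dropout >= 0, dropout < 1)
  set.seed(as.integer(seed))
  n <- nrow(sim$proteins)
  drop_tm <- stats::runif(n) < dropout
  sim$proteins$annotations <- purrr::pmap(
    list(sim$proteins$annotations, sim$proteins$sequence, drop_tm),
    function(ann, sequence, drop) {
      kd <- ann$kind == "kinase_domain"
      if (jitter > 0 && any(kd)) {
        shift <- sample(seq(-jitter, jitter), sum(kd), replace = TRUE)
        ann$start[kd] <- pmin(pmax(ann$start[kd] + shift, 1),
                              nchar(sequence))
      }
      if (drop) ann <- ann[ann$kind != "transmembrane", , drop = FALSE]
      ann
    })
  sim
}
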