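# Position weight matrices: background estimation, PWM construction,
# exact p-values by dynamic programming over the discretised score
# distribution, scanning, and ZOOPS expectation-maximisation discovery.

#' Background letter frequencies of a segment corpus
#'
#' Letter frequencies over all segment sequences with a +1 pseudocount per
#' standard letter; degenerate letters distribute fractionally (uniformly)
#' over their expansion set.
#'
#' @param segments Segment tibble, or a character vector of sequences.
#' @param alphabet Alphabet of the model (default the 20 amino acids).
#' @return Named frequency vector summing to 1.
#' @export
build_background <- function(segments, alphabet = aa_alphabet()) {
  seqs <- if (is.data.frame(segments)) segments$sequence else segments
  stopifnot(length(seqs) >= 1)
  if (identical(alphabet, aa_alphabet())) {
    E <- aa_expansion_matrix()
    counts <- rep(0, 20)
    for (s in seqs) {
      tab <- rowsum(rep(1, nchar(s)), group = aa_encode(s))
      counts <- counts + colSums(E[as.integer(rownames(tab)), , drop = FALSE] *
                                   as.numeric(tab))
    }
  } else {
    chars <- strsplit(paste(seqs, collapse = ""), "")[[1]]
    stopifnot(all(chars %in% alphabet))
    counts <- vapply(alphabet, function(a) sum(chars == a), 0)
  }
  counts <- counts + 1
  stats::setNames(counts / sum(counts), alphabet)
}

# Consensus string from a frequency matrix: argmax letter per column, or
# the matching degenerate code (B/Z/J) when the runner-up is within
# 0.8x of the maximum and the top pair is one of {D,N}, {E,Q}, {I,L}.
consensus_from_freq <- function(freq, alphabet = aa_alphabet()) {
  deg_pairs <- list(B = c("D", "N"), Z = c("E", "Q"), J = c("I", "L"))
  apply(freq, 1, function(p) {
    o <- order(p, decreasing = TRUE)
    top <- alphabet[o[1]]
    if (length(p) > 1 && p[o[2]] >= 0.8 * p[o[1]]) {
      pair <- sort(alphabet[o[1:2]])
      for (d in names(deg_pairs)) {
        if (identical(pair, sort(deg_pairs[[d]]))) return(d)
      }
    }
    top
  }) |> paste(collapse = "")
}

#' Build a position weight matrix from aligned sites
#'
#' Counts get a per-cell pseudocount of `pseudocount * background[a]`, so
#' each column sums to the number of sites plus the total pseudocount;
#' log-odds are `log2(freq / background)`. Degenerate site letters
#' contribute background-proportionally over their expansion set.
#'
#' @param site_sequences Character vector of equal-width sites (>= 2).
#' @param background Background vector from [build_background()].
#' @param pseudocount Total per-column pseudocount.
#' @param id Motif identifier.
#' @return An object of class `nre_motif`.
#' @export
build_pwm <- function(site_sequences, background, pseudocount = 0.1,
                      id = "motif_1") {
  stopifnot(length(site_sequences) >= 2)
  w <- unique(nchar(site_sequences))
  if (length(w) != 1) stop("sites differ in width", call. = FALSE)
  alphabet <- names(background)
  n <- length(site_sequences)
  if (identical(alphabet, aa_alphabet())) {
    E <- aa_expansion_matrix(background)
    counts <- matrix(0, w, 20, dimnames = list(NULL, alphabet))
    encs <- lapply(site_sequences, aa_encode)
    for (k in seq_len(w)) {
      tab <- rowsum(rep(1, n), group = vapply(encs, `[[`, 0L, k))
      counts[k, ] <- colSums(E[as.integer(rownames(tab)), , drop = FALSE] *
                               as.numeric(tab))
    }
  } else {
    counts <- matrix(0, w, length(alphabet), dimnames = list(NULL, alphabet))
    for (s in site_sequences) {
      ch <- strsplit(s, "")[[1]]
      stopifnot(all(ch %in% alphabet))
      counts[cbind(seq_len(w), match(ch, alphabet))] <-
        counts[cbind(seq_len(w), match(ch, alphabet))] + 1
    }
  }
  new_nre_motif(counts, background, pseudocount, id = id, n_sites = n)
}

# Construct an nre_motif from a count matrix.
new_nre_motif <- function(counts, background, pseudocount = 0.1,
                          id = "motif_1", n_sites = NULL,
                          discovery_stat = NULL) {
  alphabet <- names(background)
  pc <- matrix(rep(pseudocount * background, each = nrow(counts)),
               nrow = nrow(counts))
  freq <- (counts + pc) / rowSums(counts + pc)
  log_odds <- log2(sweep(freq, 2, background, "/"))
  structure(list(
    id = id, width = nrow(counts), alphabet = alphabet,
    counts = counts, freq = freq, log_odds = log_odds,
    background = background,
    consensus = consensus_from_freq(freq, alphabet),
    n_sites = if (is.null(n_sites)) max(rowSums(counts)) else n_sites,
    discovery_stat = discovery_stat
  ), class = "nre_motif")
}

#' @export
print.nre_motif <- function(x, ...) {
  cat(sprintf("<nre_motif %s> width %d, %s sites, consensus %s\n",
              x$id, x$width, format(x$n_sites, digits = 4), x$consensus))
  if (!is.null(x$discovery_stat)) {
    cat(sprintf("  discovery LLR %.1f, p = %.3g\n",
                x$discovery_stat$llr, x$discovery_stat$p_value))
  }
  invisible(x)
}

#' Exact p-value table for a PWM
#'
#' Per-position log-odds scores are discretised to integer multiples of
#' `resolution` bits and the exact distribution of the total score of a
#' random width-w word drawn i.i.d. from the background is computed by
#' dynamic programming (convolution over positions). The returned tail
#' probabilities P(score >= s) are exact for the discretised score, hence
#' within `w * resolution / 2` bits of the undiscretised score, and are
#' monotone non-increasing in s. Scanning uses the same discretised
#' scores, so scan p-values are exact.
#'
#' @param motif An `nre_motif`.
#' @param resolution Discretisation step, bits.
#' @return Object of class `nre_pvalue_table`: `int_scores` (w x alphabet
#'   integer matrix), `lo` (minimum total integer score), `tail`
#'   (`tail[k] = P(S >= lo + k - 1)`), `resolution`.
#' @export
pwm_pvalue_table <- function(motif, resolution = 1 / 1000) {
  stopifnot(inherits(motif, "nre_motif"), motif$width >= 1)
  stopifnot(all(is.finite(motif$log_odds)))
  S <- matrix(as.integer(round(motif$log_odds / resolution)),
              nrow = motif$width)
  bg <- as.numeric(motif$background)
  cur <- 1
  cur_lo <- 0L
  for (k in seq_len(motif$width)) {
    smin <- min(S[k, ]); smax <- max(S[k, ])
    nxt_lo <- cur_lo + smin
    nxt <- numeric(length(cur) + smax - smin)
    for (a in seq_along(bg)) {
      off <- S[k, a] - smin
      idx <- (off + 1L):(off + length(cur))
      nxt[idx] <- nxt[idx] + cur * bg[a]
    }
    cur <- nxt
    cur_lo <- nxt_lo
  }
  tail <- rev(cumsum(rev(cur)))
  tail <- pmin(tail, 1)
  structure(list(int_scores = S, lo = cur_lo, tail = tail,
                 resolution = resolution, alphabet = motif$alphabet),
            class = "nre_pvalue_table")
}

# P(score >= s_int) for integer scores (vectorised).
pvalue_lookup <- function(table, s_int) {
  k <- s_int - table$lo + 1L
  p <- numeric(length(k))
  p[k <= 0] <- 1
  inside <- k >= 1 & k <= length(table$tail)
  p[inside] <- table$tail[k[inside]]
  # above the maximum score: probability 0 is impossible for a realised
  # score, but guard with the smallest tail mass
  p[k > length(table$tail)] <- 0
  p
}

# Integer discretised scores of every offset of an encoded sequence.
# Degenerate letters score as the background-weighted mean over their
# expansion set (rounded to the integer grid).
offset_scores <- function(enc, table, background) {
  w <- nrow(table$int_scores)
  m <- length(enc) - w + 1L
  if (m < 1) return(integer(0))
  if (identical(table$alphabet, aa_alphabet())) {
    E <- aa_expansion_matrix(background)
    ext <- round(E %*% t(table$int_scores)) # 24 x w
  } else {
    ext <- t(table$int_scores)
  }
  sc <- integer(m)
  for (k in seq_len(w)) {
    sc <- sc + as.integer(ext[enc[seq_len(m) + k - 1L], k])
  }
  sc
}

#' Scan segments for motif occurrences
#'
#' FIMO-style scan: every offset of every segment is scored against the
#' motif's discretised log-odds, p-values come from the exact tail table,
#' offsets with `p <= p_threshold` are reported, and overlapping matches of
#' the motif within a segment are resolved to the best p per overlap group
#' (ties to the leftmost). Coordinates are 1-based within the segment.
#'
#' @param motif An `nre_motif`.
#' @param segments Segment tibble (columns `protein_id`, `sequence`; other
#'   columns are ignored), or a character vector of sequences.
#' @param p_threshold Report matches with p at or below this.
#' @param pvalue_table Optional precomputed [pwm_pvalue_table()].
#' @param resolution Discretisation step when the table is built here.
#' @return Tibble `motif_id, sequence_id, start, stop, score, p_value,
#'   matched_sequence`.
#' @export
scan_motif <- function(motif, segments, p_threshold = 0.001,
                       pvalue_table = NULL, resolution = 1 / 1000) {
  if (!is.data.frame(segments)) {
    segments <- tibble::tibble(
      protein_id = sprintf("seq_%d", seq_along(segments)),
      sequence = segments)
  }
  if (is.null(pvalue_table)) {
    pvalue_table <- pwm_pvalue_table(motif, resolution)
  }
  w <- motif$width
  out <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    s <- segments$sequence[i]
    if (nchar(s) < w) next
    enc <- if (identical(motif$alphabet, aa_alphabet())) {
      aa_encode(s)
    } else {
      match(strsplit(s, "")[[1]], motif$alphabet)
    }
    sc <- offset_scores(enc, pvalue_table, motif$background)
    p <- pvalue_lookup(pvalue_table, sc)
    hit <- which(p <= p_threshold)
    if (length(hit) == 0) next
    # resolve transitively overlapping hits: best p (= max score), leftmost
    grp <- cumsum(c(1L, diff(hit) >= w))
    keep <- vapply(split(hit, grp), function(h) {
      h[order(-sc[h], h)][1]
    }, 0L)
    out[[i]] <- tibble::tibble(
      motif_id = motif$id, sequence_id = segments$protein_id[i],
      start = as.integer(keep), stop = as.integer(keep + w - 1L),
      score = sc[keep] * pvalue_table$resolution,
      p_value = p[keep],
      matched_sequence = substr(rep(s, length(keep)), keep, keep + w - 1L))
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(motif_id = character(), sequence_id = character(),
                          start = integer(), stop = integer(),
                          score = numeric(), p_value = numeric(),
                          matched_sequence = character())
  }
  res
}

#' Convert scan matches from segment to protein coordinates
#'
#' @param matches Tibble from [scan_motif()] run on NRE segments.
#' @param segments The segment tibble that was scanned (provides each
#'   segment's `start` offset within its protein).
#' @return `matches` with `start`/`stop` shifted to protein coordinates.
#' @export
matches_to_protein_coords <- function(matches, segments) {
  off <- stats::setNames(segments$start, segments$protein_id)
  matches$start <- matches$start + off[matches$sequence_id] - 1L
  matches$stop <- matches$stop + off[matches$sequence_id] - 1L
  matches
}

# ---------------------------------------------------------------------
# ZOOPS expectation-maximisation

# Per-window log-likelihood ratios of a motif model against background.
zoops_llr <- function(enc_all, win_starts, w, f, bg, E = NULL) {
  if (is.null(E)) {
    Smat <- log(f) - matrix(log(bg), nrow = w, ncol = length(bg),
                            byrow = TRUE)
  } else {
    fe <- E %*% t(f)
    Smat <- t(log(fe) - log(as.numeric(E %*% bg)))
  }
  llr <- numeric(length(win_starts))
  for (k in seq_len(w)) {
    llr <- llr + Smat[k, enc_all[win_starts + k - 1L]]
  }
  llr
}

# Shift a frequency matrix by delta columns (sites move right for
# delta > 0); vacated rows are filled with the background.
shift_freq <- function(f, delta, bg) {
  w <- nrow(f)
  out <- matrix(rep(bg, each = w), nrow = w)
  src <- seq_len(w) + delta
  ok <- src >= 1 & src <= w
  out[ok, ] <- f[src[ok], , drop = FALSE]
  out
}

# One EM run for a fixed width from a given initial frequency matrix.
# enc_list: integer-encoded sequences; E: 24x20 expansion matrix (or NULL
# for restricted alphabets); returns list(freq, gamma, ll, z, win_starts).
em_zoops_run <- function(enc_all, seq_of_win, win_starts, seq_lens, w,
                         background, f0, gamma0 = 0.5, max_iter = 200,
                         tol = 1e-6, E = NULL) {
  n_seq <- length(seq_lens)
  m_i <- pmax(seq_lens - w + 1L, 0L)
  win_by_seq <- split(seq_along(win_starts), seq_of_win)
  bg <- as.numeric(background)
  if (is.null(E)) {
    bg_ext <- bg
  } else {
    bg_ext <- as.numeric(E %*% bg)
  }
  lb_letter <- log(bg_ext)
  f <- f0
  gamma <- gamma0
  prev_ll <- -Inf
  prev_obj <- -Inf
  pc_prior <- matrix(rep(0.1 * bg, each = w), nrow = w)
  z <- numeric(length(win_starts))
  for (iter in seq_len(max_iter)) {
    # letter-level log score matrix: w x n_letter_codes
    if (is.null(E)) {
      Smat <- log(f) - matrix(lb_letter, nrow = w, ncol = length(bg),
                              byrow = TRUE)
    } else {
      fe <- E %*% t(f) # 24 x w expected motif prob per letter code
      Smat <- t(log(fe) - lb_letter) # w x 24
    }
    llr <- numeric(length(win_starts))
    for (k in seq_len(w)) {
      llr <- llr + Smat[k, enc_all[win_starts + k - 1L]]
    }
    ll <- 0
    for (i in seq_len(n_seq)) {
      idx <- win_by_seq[[as.character(i)]]
      if (is.null(idx) || m_i[i] == 0) {
        ll <- ll + log(1 - gamma)
        next
      }
      a0 <- log(1 - gamma)
      aj <- log(gamma) - log(m_i[i]) + llr[idx]
      mx <- max(a0, aj)
      lse <- mx + log(exp(a0 - mx) + sum(exp(aj - mx)))
      z[idx] <- exp(aj - lse)
      ll <- ll + lse
    }
    # (background log-prob of the sequences is a constant; omitted from ll)
    # The M-step smooths counts with a Dirichlet pseudocount, so the
    # monotone EM objective is the log-posterior ll + log prior(f).
    obj <- ll + sum(pc_prior * log(f))
    if (obj < prev_obj - 1e-8 * (1 + abs(obj))) {
      stop("ZOOPS EM objective decreased (", prev_obj, " -> ", obj, ")",
           call. = FALSE)
    }
    converged <- is.finite(prev_obj) && (obj - prev_obj) < tol * (1 + abs(obj))
    prev_obj <- obj
    prev_ll <- ll
    # M-step; degenerate letter codes split their weighted count over the
    # expansion set by posterior responsibility E[l, a] f[k, a] / fe[l, k]
    counts <- matrix(0, w, length(bg))
    for (k in seq_len(w)) {
      letters_k <- enc_all[win_starts + k - 1L]
      tab <- rowsum(z, group = letters_k)
      codes <- as.integer(rownames(tab))
      std <- codes <= length(bg)
      counts[k, codes[std]] <- counts[k, codes[std]] + as.numeric(tab[std])
      for (ci in which(!std)) {
        r <- E[codes[ci], ] * f[k, ]
        counts[k, ] <- counts[k, ] + as.numeric(tab[ci]) * r / sum(r)
      }
    }
    f <- (counts + pc_prior) / rowSums(counts + pc_prior)
    q_i <- vapply(split(z, seq_of_win), sum, 0)
    gamma <- min(max(sum(q_i) / n_seq, 1e-4), 1 - 1e-4)
    if (converged) break
  }
  list(freq = f, gamma = gamma, ll = prev_ll, z = z, counts = counts)
}

#' ZOOPS motif discovery by expectation-maximisation
#'
#' Discovers up to `n_motifs` ungapped motifs in trimmed NRE segments
#' under the zero-or-one-occurrence-per-sequence model: the E-step
#' computes per-offset posterior occurrence probabilities against the
#' background, the M-step re-estimates the PWM and the occurrence prior,
#' and the log-likelihood is checked to be non-decreasing at every
#' iteration. For each width, EM runs from `n_starts` k-mer-seeded starts
#' and the best run is kept; models are ranked across widths by the
#' significance of their log-likelihood-ratio statistic (chi-square
#' approximation, df = 19w + 1) and models with `p > p_threshold` are
#' discarded. After a motif is accepted, its sites (posterior > 0.5) are
#' masked before the next motif is sought. Deterministic given `seed`.
#'
#' @param segments Segment tibble or character vector of sequences (>= 10).
#' @param widths Motif widths to try.
#' @param n_motifs Maximum number of motifs.
#' @param p_threshold Discovery p-value threshold.
#' @param seed Integer seed.
#' @param n_starts Seeded EM starts per width.
#' @param max_iter,tol EM iteration cap and relative convergence tolerance.
#' @param background Optional background vector (estimated from the
#'   segments when NULL).
#' @return List of `nre_motif` objects (possibly empty), each carrying
#'   `discovery_stat` (llr, p_value, gamma) and a `sites` tibble
#'   (`sequence_id, start, posterior`).
#' @export
discover_zoops <- function(segments, widths = c(10, 15, 21, 28, 36, 44),
                           n_motifs = 1, p_threshold = 0.005, seed = 1L,
                           n_starts = 5, max_iter = 200, tol = 1e-6,
                           background = NULL) {
  if (!is.data.frame(segments)) {
    segments <- tibble::tibble(
      protein_id = sprintf("seq_%d", seq_along(segments)),
      sequence = segments)
  }
  stopifnot(nrow(segments) >= 10)
  if (is.null(background)) background <- build_background(segments)
  set.seed(as.integer(seed))
  E <- aa_expansion_matrix(background)
  enc_list <- lapply(segments$sequence, aa_encode)
  seq_lens <- lengths(enc_list)
  enc_all <- unlist(enc_list)
  seq_start <- cumsum(c(1L, seq_lens[-length(seq_lens)]))

  found <- list()
  for (im in seq_len(n_motifs)) {
    best <- NULL
    for (w in widths) {
      ok_seq <- which(seq_lens >= w)
      if (length(ok_seq) < 10) next
      win_starts <- unlist(lapply(ok_seq, function(i) {
        seq_start[i] + 0:(seq_lens[i] - w)
      }))
      seq_of_win <- rep(ok_seq, times = seq_lens[ok_seq] - w + 1L)
      # candidate seed k-mers sampled from the data (skip windows with X),
      # scored by a one-pass likelihood so recurring k-mers seed the EM in
      # the right register; scoring is cheap relative to EM, so a wide
      # candidate pool is screened and only the top n_starts run EM
      cand <- sample(seq_along(win_starts),
                     min(length(win_starts), max(100L, n_starts * 20L)))
      cand <- cand[vapply(cand, function(cidx) {
        all(enc_all[win_starts[cidx] + 0:(w - 1L)] <= 20L)
      }, TRUE)]
      if (length(cand) == 0) next
      seed_init <- function(ws) {
        f0 <- matrix(rep(0.4 * background, each = w), nrow = w)
        kmer <- enc_all[ws + 0:(w - 1L)]
        k20 <- pmin(kmer, 20L)
        f0[cbind(seq_len(w), k20)] <- f0[cbind(seq_len(w), k20)] + 0.6
        f0 / rowSums(f0)
      }
      # a seed is promising when OTHER sequences carry windows resembling
      # it: sum the positive per-sequence best log-likelihood ratios,
      # excluding the seed's own sequence (whose self-match is trivial)
      seed_score <- vapply(cand, function(cidx) {
        llr <- zoops_llr(enc_all, win_starts, w,
                         seed_init(win_starts[cidx]), background, E)
        best_per_seq <- vapply(split(llr, seq_of_win), max, 0)
        own <- as.character(seq_of_win[cidx])
        sum(pmax(best_per_seq[names(best_per_seq) != own], 0))
      }, 0)
      seeds <- win_starts[cand[order(-seed_score)][
        seq_len(min(n_starts, length(cand)))]]
      best_w <- NULL
      for (ws in seeds) {
        run <- em_zoops_run(enc_all, seq_of_win, win_starts, seq_lens, w,
                            background, seed_init(ws), max_iter = max_iter,
                            tol = tol, E = E)
        if (is.null(best_w) || run$ll > best_w$ll) best_w <- run
      }
      # column-shift refinement: escape phase-shifted local optima by
      # re-running EM from shifted models while the likelihood improves
      repeat {
        improved <- FALSE
        for (delta in c(-3L, -2L, -1L, 1L, 2L, 3L)) {
          f0 <- shift_freq(best_w$freq, delta, background)
          run <- em_zoops_run(enc_all, seq_of_win, win_starts, seq_lens, w,
                              background, f0, gamma0 = best_w$gamma,
                              max_iter = max_iter, tol = tol, E = E)
          if (run$ll > best_w$ll + 1e-6) {
            best_w <- run
            improved <- TRUE
          }
        }
        if (!improved) break
      }
      # null: gamma -> 0 gives ll = 0 under the omitted-constant
      # parameterisation, so the LLR statistic is simply 2 * ll
      llr_stat <- max(0, 2 * best_w$ll)
      df <- 19L * w + 1L
      p <- stats::pchisq(llr_stat, df = df, lower.tail = FALSE)
      if (is.null(best) || p < best$p ||
          (p == best$p && llr_stat > best$llr)) {
        best <- list(run = best_w, w = w, p = p, llr = llr_stat,
                     win_starts = win_starts, seq_of_win = seq_of_win)
      }
    }
    if (is.null(best) || best$p > p_threshold) break

    run <- best$run
    counts <- run$counts
    colnames(counts) <- names(background)
    motif <- new_nre_motif(
      counts, background, pseudocount = 0.1,
      id = sprintf("motif_%d", im),
      n_sites = sum(run$z),
      discovery_stat = list(llr = best$llr, p_value = best$p,
                            gamma = run$gamma, width = best$w))
    # site table: best window per sequence with posterior > 0.5
    zt <- tibble::tibble(seq = best$seq_of_win, ws = best$win_starts,
                         z = run$z) |>
      dplyr::group_by(.data$seq) |>
      dplyr::slice_max(.data$z, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$z > 0.5)
    motif$sites <- tibble::tibble(
      sequence_id = segments$protein_id[zt$seq],
      start = as.integer(zt$ws - seq_start[zt$seq] + 1L),
      posterior = zt$z)
    found[[im]] <- motif
    # mask accepted sites (replace with X) before the next motif
    if (im < n_motifs && nrow(zt) > 0) {
      for (r in seq_len(nrow(zt))) {
        enc_all[zt$ws[r] + 0:(best$w - 1L)] <- 24L # 'X'
      }
    }
  }
  found
}

# ---------------------------------------------------------------------
# MEME minimal motif format and FIMO-style match tables

#' Write motifs in MEME minimal text format
#'
#' @param motifs List of `nre_motif` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path) {
  stopifnot(length(motifs) >= 1)
  bg <- motifs[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste0("ALPHABET= ", paste(names(bg), collapse = "")), "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", names(bg), bg), collapse = " "),
               ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s %s", m$id, m$consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= %d w= %d nsites= %.1f E= %g",
      length(m$alphabet), m$width, m$n_sites,
      if (is.null(m$discovery_stat)) 0 else m$discovery_stat$p_value), con)
    writeLines(apply(m$freq, 1, function(r) {
      paste(sprintf("%.6f", r), collapse = " ")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal text format
#'
#' @param path Path to a MEME minimal file.
#' @return List of `nre_motif` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ab_line <- grep("^ALPHABET=", lines, value = TRUE)[1]
  alphabet <- strsplit(trimws(sub("^ALPHABET=", "", ab_line)), "")[[1]]
  bg <- stats::setNames(rep(1 / length(alphabet), length(alphabet)), alphabet)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    bg <- stats::setNames(as.numeric(toks[seq(2, length(toks), 2)]),
                          toks[seq(1, length(toks), 2)])[alphabet]
  }
  starts <- grep("^MOTIF ", lines)
  motifs <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    id <- strsplit(trimws(sub("^MOTIF", "", lines[starts[i]])), "\\s+")[[1]][1]
    hdr_at <- starts[i] + grep("letter-probability matrix",
                               lines[(starts[i] + 1):length(lines)])[1]
    hdr <- lines[hdr_at]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr))
    rows <- lines[(hdr_at + 1):(hdr_at + w)]
    freq <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    colnames(freq) <- alphabet
    # the file frequencies are already smoothed; a vanishing pseudocount
    # reconstructs them (and keeps log-odds finite)
    motifs[[i]] <- new_nre_motif(freq * nsites, bg, pseudocount = 1e-6,
                                 id = id, n_sites = nsites)
  }
  motifs
}

#' Write scan matches as a FIMO-style TSV
#'
#' @param matches Tibble from [scan_motif()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fimo_tsv <- function(matches, path) {
  write_table(matches, path,
              key = c("motif_id", "sequence_id", "start", "stop"))
}
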