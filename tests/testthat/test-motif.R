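uniform_bg <- function(alphabet = aa_alphabet()) {
  stats::setNames(rep(1 / length(alphabet), length(alphabet)), alphabet)
}

# Brute-force tail oracle over every width-w word of an alphabet, on the
# same discretised integer score grid the DP uses.
brute_force_tails <- function(tab, bg) {
  w <- nrow(tab$int_scores)
  n <- length(bg)
  idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), w)))
  sc <- rowSums(vapply(seq_len(w), function(k) {
    tab$int_scores[k, idx[, k]]
  }, numeric(nrow(idx))))
  pr <- apply(idx, 1, function(r) prod(bg[r]))
  list(scores = sc, probs = pr,
       tail = function(s) sum(pr[sc >= s]))
}

test_that("background frequencies use +1 pseudocounts and degeneracy splits", {
  bgA <- build_background(strrep("A", 100))
  expect_equal(unname(bgA["A"]), 101 / 120)
  expect_equal(unname(bgA["C"]), 1 / 120)
  expect_equal(sum(bgA), 1)
  # B contributes half to D and half to N
  bgB <- build_background("BB")
  expect_equal(unname(bgB["D"]), 2 / 22)
  expect_equal(unname(bgB["N"]), 2 / 22)
  # near-uniform corpus gives near-uniform background
  set.seed(2)
  bgU <- build_background(random_sequences(50, 200))
  expect_true(max(abs(bgU - 0.05)) < 0.01)
})

test_that("PWM construction follows the pseudocounted closed form", {
  bg <- uniform_bg()
  m <- build_pwm(rep("ACDE", 4), bg, pseudocount = 0.1)
  expect_equal(unname(m$log_odds[1, "A"]),
               log2((4 + 0.1 * 0.05) / (4 + 0.1) / 0.05))
  # column sums = sites + total pseudocount
  raw <- m$counts + matrix(rep(0.1 * bg, each = 4), nrow = 4)
  expect_equal(unname(rowSums(raw)), rep(4 + 0.1, 4))
  expect_equal(m$consensus, "ACDE")
  expect_true(all(is.finite(m$log_odds)))
  # degenerate site letters spread background-proportionally
  mx <- build_pwm(c("XA", "CA"), bg)
  expect_equal(unname(mx$counts[1, ]), rep(0.05, 20) + c(0, 1, rep(0, 18)),
               tolerance = 1e-12)
  expect_error(build_pwm(c("AC", "ACD"), bg), "width")
})

test_that("DP tail probabilities equal brute-force enumeration", {
  # 4-letter alphabet, widths 2 and 6, non-uniform background
  ab <- c("A", "C", "G", "T")
  bg4 <- stats::setNames(c(0.4, 0.1, 0.3, 0.2), ab)
  set.seed(31)
  for (w in c(2L, 6L)) {
    sites <- vapply(1:5, function(i) {
      paste(sample(ab, w, TRUE), collapse = "")
    }, "")
    m <- build_pwm(sites, bg4)
    tab <- pwm_pvalue_table(m, resolution = 1 / 1000)
    oracle <- brute_force_tails(tab, bg4)
    ss <- sort(unique(oracle$scores))
    expect_equal(nrekit:::pvalue_lookup(tab, ss),
                 vapply(ss, oracle$tail, 0), tolerance = 1e-12)
    # below the minimum score the tail is 1
    expect_equal(nrekit:::pvalue_lookup(tab, min(ss) - 5L), 1)
    # tails are monotone non-increasing
    expect_true(all(diff(tab$tail) <= 1e-15))
  }
  # full 20-letter alphabet at width 2
  m20 <- build_pwm(c("AC", "AD", "AC"), uniform_bg())
  tab20 <- pwm_pvalue_table(m20)
  oracle20 <- brute_force_tails(tab20, uniform_bg())
  ss <- sort(unique(oracle20$scores))
  expect_equal(nrekit:::pvalue_lookup(tab20, ss),
               vapply(ss, oracle20$tail, 0), tolerance = 1e-12)
})

test_that("the maximum-score word has p equal to its background mass", {
  # a strict-maximum motif: argmax letter unique in every column
  bg <- uniform_bg()
  m <- build_pwm(rep("FSY", 3), bg)
  tab <- pwm_pvalue_table(m)
  smax <- sum(apply(tab$int_scores, 1, max))
  expect_equal(nrekit:::pvalue_lookup(tab, smax), 0.05^3, tolerance = 1e-12)
})

test_that("scanning reports thresholded, overlap-resolved matches", {
  bg <- uniform_bg()
  motif_str <- "VGPWKTGLSGQLQKAFVTGVP"
  m <- build_pwm(rep(motif_str, 5), bg, id = "m1")
  seg <- paste0(strrep("Q", 8), motif_str, strrep("Q", 7))
  hits <- scan_motif(m, seg, p_threshold = 0.001)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 9L)
  expect_equal(hits$matched_sequence, motif_str)
  # oracle: exhaustive offset scoring finds the same unique sub-threshold hit
  tab <- pwm_pvalue_table(m)
  enc <- nrekit:::aa_encode(seg)
  sc <- nrekit:::offset_scores(enc, tab, m$background)
  expect_equal(which(nrekit:::pvalue_lookup(tab, sc) <= 0.001), 9L)

  # width longer than the segment -> empty
  expect_equal(nrow(scan_motif(m, "ACDEF")), 0)
  # invariance to segment order and to unrelated padding
  segs <- c(a = seg, b = strrep("A", 40))
  h1 <- scan_motif(m, tibble::tibble(protein_id = names(segs),
                                     sequence = segs))
  h2 <- scan_motif(m, tibble::tibble(protein_id = rev(names(segs)),
                                     sequence = rev(segs)))
  expect_equal(dplyr::arrange(h1, .data$sequence_id),
               dplyr::arrange(h2, .data$sequence_id))
  padded <- paste0(seg, strrep("D", 30))
  expect_equal(scan_motif(m, padded)$start, 9L)
})

test_that("random background segments rarely reach the scan threshold", {
  bg <- uniform_bg()
  m <- build_pwm(rep("VGPWKTGLSG", 5), bg, id = "m1")
  set.seed(17)
  segs <- random_sequences(1000, 40)
  hits <- scan_motif(m, segs, p_threshold = 0.001)
  # expected matches per segment = 31 offsets * 0.001; >= 99% of segments
  # should have none
  expect_gte(mean(!(sprintf("seq_%d", 1:1000) %in% hits$sequence_id)), 0.99)
})

test_that("ZOOPS discovery is deterministic and rejects pure background", {
  set.seed(4)
  segs <- random_sequences(60, 45)
  m1 <- discover_zoops(segs, widths = 10, n_motifs = 1, seed = 3,
                       n_starts = 2, max_iter = 50)
  m2 <- discover_zoops(segs, widths = 10, n_motifs = 1, seed = 3,
                       n_starts = 2, max_iter = 50)
  expect_identical(lapply(m1, function(m) m$freq),
                   lapply(m2, function(m) m$freq))
  # on shuffled-letter segments any model must clear the significance bar
  # to be reported; weak ones are discarded (empty list is valid)
  if (length(m1) > 0) {
    expect_lte(m1[[1]]$discovery_stat$p_value, 0.005)
  }
  succeed()
})

test_that("ZOOPS EM recovers a planted motif and its sites", {
  fix <- planted_trimmed_segments(n = 120, seed = 19)
  mot <- discover_zoops(fix$trimmed, widths = 21, n_motifs = 1, seed = 2)
  expect_equal(length(mot), 1)
  m <- mot[[1]]
  planted <- "VGPWKTGLSGQLQKAFVTGVP"
  agree <- sum(strsplit(m$consensus, "")[[1]] == strsplit(planted, "")[[1]])
  expect_gte(agree, 19)
  # posterior site table points at the planted intervals
  truth <- fix$sim$truth
  st <- m$sites |>
    dplyr::inner_join(fix$trimmed[, c("protein_id", "start")],
                      by = c(sequence_id = "protein_id"),
                      suffix = c("", "_seg")) |>
    dplyr::mutate(protein_pos = .data$start + .data$start_seg - 1L) |>
    dplyr::inner_join(truth[, c("protein_id", "motif_start")],
                      by = c(sequence_id = "protein_id"))
  planted_only <- st[!is.na(st$motif_start), ]
  expect_gte(mean(abs(planted_only$protein_pos -
                        planted_only$motif_start) <= 3), 0.9)
})

test_that("MEME minimal format round-trips motif models", {
  bg <- build_background(c("ACDEFGHIKL", "MNPQRSTVWY"))
  m <- build_pwm(c("ACDE", "ACDF", "ACDE"), bg, id = "rt")
  path <- tempfile(fileext = ".meme")
  write_meme(list(m), path)
  back <- read_meme(path)[[1]]
  expect_equal(back$id, "rt")
  expect_equal(back$width, 4)
  expect_equal(unname(back$freq), unname(m$freq), tolerance = 1e-3)
  expect_equal(back$consensus, m$consensus)
})

test_that("motif tidiers expose the model as tables", {
  m <- build_pwm(c("ACDE", "ACDF", "ACDE"), uniform_bg(), id = "t1")
  td <- tidy(m)
  expect_equal(nrow(td), 4 * 20)
  expect_equal(sum(td$count), 3 * 4)
  gl <- glance(m)
  expect_equal(gl$width, 4)
  expect_equal(gl$consensus, m$consensus)
})
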