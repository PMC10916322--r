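seg_tbl <- function(seqs, kind = "JM", class_label = "LRR-VI-2") {
  tibble::tibble(protein_id = paste0("p", seq_along(seqs)), kind = kind,
                 start = 1L, end = nchar(seqs),
                 length = nchar(seqs), sequence = seqs,
                 has_internal_domain = FALSE,
                 species = "sp1", class_label = class_label)
}

test_that("length histogram puts the mode where the lengths are", {
  segs <- seg_tbl(c(strrep("A", 40), strrep("A", 40), strrep("A", 50)))
  h <- length_distribution(segs, bin_width = 2)
  top <- h[which.max(h$count), ]
  expect_true(top$bin_start <= 40 && 40 <= top$bin_end)
  expect_equal(sum(h$count), 3)
  # degenerate single-segment histogram
  h1 <- length_distribution(seg_tbl(strrep("A", 33)))
  expect_equal(sum(h1$count), 1)
})

test_that("recovered length mode matches the planted mixture mode", {
  sim <- simulate_rlk_dataset(n_proteins = 400, seed = 21,
                              nre_modes = c(40, 50),
                              nre_weights = c(0.8, 0.2),
                              planting_rate = 0)
  segs <- extract_nre(sim$proteins, assign_topology(sim$proteins))
  h <- length_distribution(segs, bin_width = 2)
  pooled <- h |>
    dplyr::count(.data$bin_start, wt = .data$count, name = "count")
  mode_bin <- pooled$bin_start[which.max(pooled$count)]
  expect_lte(abs(mode_bin - 40), 2)
})

test_that("scaled composition maps residues onto their fractional spans", {
  # identity mapping at L = bins
  p200 <- scaled_composition(seg_tbl(paste(
    rep(c("A", "D"), 100), collapse = "")), bins = 200)
  expect_equal(unname(p200$freq[1, "A"]), 1)
  expect_equal(unname(p200$freq[2, "D"]), 1)
  expect_equal(unname(p200$freq[200, "D"]), 1)
  # constant sequence fills every bin
  p100 <- scaled_composition(seg_tbl(strrep("S", 100)), bins = 200)
  expect_true(all(abs(p100$freq[, "S"] - 1) < 1e-12))
  # length-3 "ADA": bins 1-66 pure A, 68-133 pure D, 135-200 pure A,
  # boundary bins split 2/3-1/3 (0-based bins 66 and 133)
  p3 <- scaled_composition(seg_tbl("ADA"), bins = 200)
  expect_equal(unname(p3$freq[1, "A"]), 1)
  expect_equal(unname(p3$freq[66, "A"]), 1)
  expect_equal(unname(p3$freq[67, "A"]), 2 / 3, tolerance = 1e-9)
  expect_equal(unname(p3$freq[67, "D"]), 1 / 3, tolerance = 1e-9)
  expect_equal(unname(p3$freq[100, "D"]), 1)
  expect_equal(unname(p3$freq[200, "A"]), 1)
})

test_that("scaled profile weight is conserved and bins are stochastic", {
  sim <- simulate_rlk_dataset(n_proteins = 80, seed = 5)
  segs <- extract_nre(sim$proteins, assign_topology(sim$proteins))
  prof <- scaled_composition(segs, bins = 200)
  expect_equal(sum(prof$weight), sum(segs$length), tolerance = 1e-6)
  rs <- rowSums(prof$freq[prof$support > 0, ])
  expect_true(all(abs(rs - 1) < 1e-9))
  # sequence weighting: each segment contributes total weight 1
  prof_seq <- scaled_composition(segs, bins = 200, weighting = "sequence")
  expect_equal(sum(prof_seq$weight), nrow(segs), tolerance = 1e-6)
})

test_that("logo information content behaves like Shannon information", {
  # identical tails: every column at the log2(20) ceiling
  segs <- seg_tbl(rep(paste0(strrep("Q", 15), "FSYEELEKATDNFSQWERTY"), 3))
  lg <- terminal_logo(segs, 20, "C")
  expect_equal(lg$ic, rep(log2(20), 20), tolerance = 1e-12)
  expect_equal(lg$n, 3)
  # a 0.5/0.5 two-letter column has ic = log2(20) - 1
  two <- seg_tbl(c(strrep("A", 20), strrep("C", 20)))
  lg2 <- terminal_logo(two, 20, "N")
  expect_equal(lg2$ic, rep(log2(20) - 1, 20), tolerance = 1e-12)
  # ic bounds hold on arbitrary data
  set.seed(1)
  lg3 <- terminal_logo(seg_tbl(random_sequences(50, 30)), 20, "C")
  expect_true(all(lg3$ic >= 0 & lg3$ic <= log2(20) + 1e-12))
  # entropy symmetry: relabelling letters leaves ic unchanged
  perm <- stats::setNames(sample(aa_alphabet()), aa_alphabet())
  orig <- random_sequences(50, 30)
  relabelled <- vapply(strsplit(orig, ""),
                       function(ch) paste(perm[ch], collapse = ""), "")
  expect_equal(terminal_logo(seg_tbl(relabelled), 20, "C")$ic,
               terminal_logo(seg_tbl(orig), 20, "C")$ic, tolerance = 1e-12)
  # segments shorter than the window are excluded and counted
  mixed <- seg_tbl(c(strrep("A", 30), strrep("A", 10)))
  expect_equal(terminal_logo(mixed, 20, "C")$excluded, 1)
  expect_error(terminal_logo(seg_tbl(strrep("A", 5)), 20, "C"), "shorter")
})

test_that("uniform columns drive information content to zero", {
  set.seed(99)
  lg <- terminal_logo(seg_tbl(random_sequences(10000, 20)), 20, "C")
  expect_true(all(lg$ic < 0.05))
})

test_that("the C-terminal consensus and its variants are detected", {
  hit1 <- find_signature(paste0(strrep("G", 30), "FSYEELEKATDNFS"))
  expect_equal(hit1$agreements, 14L)
  expect_true(hit1$st_motif_present)
  expect_true(hit1$thr_minus5)
  expect_equal(c(hit1$start, hit1$end), c(31, 44))

  hit2 <- find_signature(paste0(strrep("G", 30), "FSYEELEKATNNFD"))
  expect_equal(hit2$agreements, 14L)
  expect_true(hit2$st_motif_present)

  expect_equal(nrow(find_signature(strrep("G", 40))), 0)
})

test_that("signature recovery degrades monotonically with substitutions", {
  consensus <- "FSYEELEKATDNFS"
  set.seed(7)
  recovery_at <- function(rate, n = 200) {
    hits <- vapply(seq_len(n), function(i) {
      ch <- strsplit(consensus, "")[[1]]
      flip <- which(stats::runif(14) < rate)
      ch[flip] <- vapply(ch[flip],
                         function(l) sample(setdiff(aa_alphabet(), l), 1), "")
      nrow(find_signature(paste0(strrep("Q", 26), paste(ch, collapse = ""))))
    }, 0L)
    mean(hits)
  }
  r <- vapply(c(0, 0.3, 0.6), recovery_at, 0)
  expect_equal(r[1], 1)
  expect_true(r[1] >= r[2] && r[2] >= r[3])
})

test_that("LRR-VI-2 typing needs both S at -28 and a motif match", {
  motif_str <- "VGPWKTGLSGQLQKAFVTGVP"
  bg <- stats::setNames(rep(0.05, 20), aa_alphabet())
  motif <- build_pwm(rep(motif_str, 4), bg, id = "lrrvi2")
  # segment: motif + padding with S at -28 (length 60)
  pad <- strrep("Q", 60 - 21)
  base <- paste0(motif_str, pad)
  put <- function(s, at_from_end, letter) {
    L <- nchar(s)
    paste0(substr(s, 1, L - at_from_end), letter,
           substr(s, L - at_from_end + 2, L))
  }
  seg1 <- put(base, 28, "S")
  seg2 <- put(strrep("Q", 60), 28, "S") # no motif
  seg3 <- put(base, 28, "A")
  segs <- seg_tbl(c(seg1, seg2, seg3))
  ty <- classify_lrr_vi_2_type(segs, motif)
  expect_equal(ty$type, c("type1", "type2", "type2"))
  # segments shorter than 31 residues fall to type 2 with the short flag
  short <- classify_lrr_vi_2_type(seg_tbl(strrep("S", 25)), motif)
  expect_equal(short$type, "type2")
  expect_true(short$short)
})

test_that("occurrence summary counts categories and the TM-bearing share", {
  pr <- toy_proteins(as.list(stats::setNames(rep(strrep("A", 10), 4),
                                             paste0("p", 1:4))))
  pr$species <- c("sp1", "sp1", "sp2", "sp3")
  top <- tibble::tibble(protein_id = pr$id,
                        category = c("RK", "RK", "RK", "RLCK_noTM"),
                        has_ecd = TRUE, has_tm = TRUE,
                        extracellular_len = 0L,
                        tm_start = NA_integer_, tm_end = NA_integer_)
  groups <- tibble::tibble(species = c("sp1", "sp2", "sp3", "sp4"),
                           group = c("angiosperms", "angiosperms",
                                     "angiosperms", "algae"))
  occ <- summarize_occurrence(pr, top, groups)
  ang <- occ[occ$group == "angiosperms", ]
  expect_equal(sum(ang$n), 4)
  expect_equal(unique(ang$pct_tm_bearing), 75)
  # empty group retains its zero rows
  expect_true("algae" %in% occ$group)
  expect_equal(sum(occ$n[occ$group == "algae"]), 0)
})

test_that("occurrence proportions on synthetic data match the generator", {
  sim <- simulate_rlk_dataset(n_proteins = 200, seed = 13)
  top <- assign_topology(sim$proteins)
  occ <- summarize_occurrence(sim$proteins, top)
  by_cat <- occ |> dplyr::count(.data$category, wt = .data$n, name = "n")
  expect_equal(stats::setNames(by_cat$n, by_cat$category)[
    names(sort(table(sim$truth$category)))],
    sort(table(sim$truth$category)), ignore_attr = TRUE)
})
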