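test_that("class counts and abundance scores partition the corpus", {
  segs <- tibble::tibble(
    protein_id = paste0("p", 1:10),
    class_label = rep(c("A", "B", "C"), c(2, 3, 5)),
    has_internal_domain = FALSE)
  cc <- count_classes(segs)
  expect_equal(cc$Ntotal, rep(10, 3))
  expect_equal(stats::setNames(cc$Ac, cc$class_label),
               c(A = 0.2, B = 0.3, C = 0.5))
  expect_equal(sum(cc$Nc), unique(cc$Ntotal))
  # domain-bearing segments are excluded from the corpus
  segs$has_internal_domain[1] <- TRUE
  cc2 <- count_classes(segs)
  expect_equal(unique(cc2$Ntotal), 9)
  expect_equal(attr(cc2, "excluded_with_domain"), 1)
  # single class
  one <- count_classes(segs[segs$class_label == "C", ])
  expect_equal(one$Ac, 1)
})

test_that("normalized frequency reproduces its closed form and edge cases", {
  expect_equal(normalized_frequency(1, 1, 1, 1), 1)
  expect_equal(round(normalized_frequency(3532, 3532, 5265, 457685), 1), 58.3)
  expect_equal(round(normalized_frequency(1220, 1221, 2096, 457685), 1), 127.0)
  expect_error(normalized_frequency(0, 0, 1, 1), "P = 0")
  # strictly increasing in Nm at fixed P, Nc, Ntotal
  f <- normalized_frequency(1:50, 60, 100, 1000)
  expect_true(all(diff(f) > 0))
})

test_that("uniform once-per-segment occurrence calibrates F to 1", {
  nc <- c(10, 20, 30)
  ntot <- sum(nc)
  f <- normalized_frequency(Nm = nc, P = ntot, Nc = nc, Ntotal = ntot)
  expect_equal(f, rep(1, 3), tolerance = 1e-12)
})

test_that("overrepresentation filtering is strictly greater-than", {
  res <- tibble::tibble(motif_id = "m", class_label = c("a", "b", "c"),
                        F = c(1.0, 58.3, 0.4))
  kept <- filter_overrepresented(res, 1.0)
  expect_equal(kept$class_label, "b")
  expect_equal(nrow(filter_overrepresented(res[0, ])), 0)
})

test_that("species presence counts distinct species with a match", {
  matches <- tibble::tibble(motif_id = "m1",
                            sequence_id = c("p1", "p2", "p3"))
  recs <- tibble::tibble(protein_id = paste0("p", 1:3),
                         species = c("X", "X", "Y"))
  expect_equal(species_presence(matches, recs)$species_count, 2)
  expect_equal(nrow(species_presence(matches[0, ], recs)), 0)
})

test_that("phosphosite containment is inclusive on both match boundaries", {
  matches <- tibble::tibble(motif_id = "m1", sequence_id = "p1",
                            start = 323L, stop = 343L, score = 5,
                            p_value = 1e-4, matched_sequence = "x")
  sites <- tibble::tibble(protein_id = "p1",
                          position = c(330L, 323L, 343L, 344L, 322L),
                          residue = "S", source = "t")
  cm <- map_phosphosites(matches, sites)
  expect_equal(sort(cm$position), c(323, 330, 343))
  expect_equal(cm$motif_offset[cm$position == 330], 8L)
  expect_equal(cm$motif_offset[cm$position == 323], 1L)
})

test_that("sequence identity counts consensus agreements with degeneracy", {
  expect_equal(sequence_identity("FSYEEL", "FSYEEL"), 1)
  expect_equal(sequence_identity("FSYEEL", "FSYDEL"), 5 / 6)
  expect_equal(sequence_identity("NGB", "NGD"), 1)
  expect_equal(sequence_identity("NGB", "NGN"), 1)
  expect_equal(sequence_identity("XXX", "QWE"), 1)
  expect_error(sequence_identity("AB", "ABC"), "length")
})

test_that("conservation tiers cut at 50 and 80 percent mean identity", {
  bg <- stats::setNames(rep(0.05, 20), aa_alphabet())
  m <- build_pwm(rep("FSYEELEKAT", 3), bg, id = "m1")
  mk_matches <- function(seqs) {
    tibble::tibble(motif_id = "m1", sequence_id = paste0("p", seq_along(seqs)),
                   start = 1L, stop = 10L, score = 1, p_value = 1e-4,
                   matched_sequence = seqs)
  }
  # identities 1.0, 0.8, 0.9 -> mean 90, high
  cs <- conservation_summary(m, mk_matches(c(
    "FSYEELEKAT", "FSYEELEKWW", "FSYEELEKAW")))
  expect_equal(cs$mean_si, 90)
  expect_equal(cs$tier, "high")
  # mean exactly 80 is moderate ("more than 80" is high)
  cs80 <- conservation_summary(m, mk_matches(c("FSYEELEKWW", "FSYEELEKWW")))
  expect_equal(cs80$mean_si, 80)
  expect_equal(cs80$tier, "moderate")
  cs_mod <- conservation_summary(m, mk_matches(c("FSYEELWWWW", "FSYEELEKAT")))
  expect_equal(cs_mod$tier, "moderate")
  cs_low <- conservation_summary(m, mk_matches("WWWWWWWWWW"))
  expect_equal(cs_low$tier, "low")
  # zero matches -> no summary row
  expect_equal(nrow(conservation_summary(m, mk_matches(character(0)))), 0)
})

test_that("motifs lacking S/T/Y at a phosphosite offset are excluded", {
  bg <- stats::setNames(rep(0.05, 20), aa_alphabet())
  m <- build_pwm(rep("AGSTY", 3), bg, id = "m1") # G at offset 2
  matches <- tibble::tibble(motif_id = "m1", sequence_id = "p1",
                            start = 11L, stop = 15L, score = 1,
                            p_value = 1e-4, matched_sequence = "AGSTY")
  site_ok <- tibble::tibble(motif_id = "m1", protein_id = "p1",
                            position = 13L, residue = "S",
                            motif_offset = 3L, match_start = 11L,
                            match_stop = 15L)
  expect_true(conservation_summary(m, matches, site_ok)$sty_ok)
  site_bad <- dplyr::mutate(site_ok, position = 12L, motif_offset = 2L)
  cs <- conservation_summary(m, matches, site_bad)
  expect_false(cs$sty_ok)
  # ... and build_report moves the motif to the exclusions
  enr <- tibble::tibble(motif_id = "m1", class_label = "A", Nm = 1L,
                        P = 1L, Nc = 1L, Ntotal = 1L, F = 1.5,
                        species_count = 1L)
  rep_ok <- build_report(enr, conservation_summary(m, matches, site_ok),
                         list(m))
  expect_equal(rep_ok$PhosphoSites, "3")
  rep_bad <- build_report(enr, cs, list(m))
  expect_equal(nrow(rep_bad), 0)
  expect_equal(nrow(attr(rep_bad, "exclusions")), 1)
})

test_that("per-class occurrences always sum to the corpus total", {
  fix <- planted_trimmed_segments(n = 120, seed = 23, single_class = FALSE)
  bg <- build_background(fix$trimmed)
  m <- build_pwm(rep("VGPWKTGLSGQLQKAFVTGVP", 5), bg, id = "m1")
  matches <- scan_motif(m, fix$trimmed, p_threshold = 0.001)
  enr <- motif_enrichment(matches, fix$trimmed)
  expect_equal(sum(enr$Nm), unique(enr$P))
  # the motif is planted in the single simulated class, so F > 1 there
  expect_true(all(enr$F[enr$class_label == "LRR-VI-2"] > 1))
})

test_that("report rows render offsets 6;9 style and sort by identity", {
  fix <- planted_trimmed_segments(n = 80, seed = 29)
  sim <- fix$sim
  bg <- build_background(fix$trimmed)
  m <- build_pwm(rep("VGPWKTGLSGQLQKAFVTGVP", 5), bg, id = "m1")
  matches <- scan_motif(m, fix$trimmed, p_threshold = 0.001)
  pm <- matches_to_protein_coords(matches, fix$trimmed)
  contained <- map_phosphosites(pm, sim$phosphosites)
  enr <- motif_enrichment(matches, fix$trimmed)
  cons <- conservation_summary(m, matches, contained)
  rep1 <- build_report(enr, cons, list(m))
  expect_equal(rep1$PhosphoSites[1], "6;9")
  expect_equal(rep1$Motif[1], "VGPWKTGLSGQLQKAFVTGVP")
  # deterministic bytes
  p1 <- tempfile(); p2 <- tempfile()
  write_table(rep1, p1, key = c("Motif", "Class"))
  write_table(build_report(enr, cons, list(m)), p2, key = c("Motif", "Class"))
  expect_identical(readLines(p1), readLines(p2))
})
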