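# End-to-end pipeline: classify -> extract -> profile -> discover ->
# scan -> enrich -> phospho-map, with a run manifest.

#' Run the full NRE analysis pipeline
#'
#' Chains every stage on a protein dataset: topology assignment, NRE
#' extraction (with anchor refinement), C-terminal stripping, profiling
#' (length distribution, scaled composition, terminal logos, consensus
#' signature), ZOOPS motif discovery on the trimmed segments, scanning,
#' class enrichment with the normalized-frequency filter, and
#' phosphosite-motif mapping. All report tables are written under
#' `out_dir` together with a JSON run manifest (config snapshot, input
#' digests, stage timings, output list, seed); re-running with identical
#' inputs and seed reproduces identical outputs.
#'
#' @param fasta_path,annotation_path,phosphosite_path Input files
#'   (`phosphosite_path` may be NULL).
#' @param out_dir Output directory.
#' @param config An [nre_config()] list.
#' @param widths Motif widths passed to [discover_zoops()].
#' @param n_motifs Maximum motifs to discover.
#' @return Invisibly, a list with every intermediate result and the
#'   manifest.
#' @export
run_nre_pipeline <- function(fasta_path, annotation_path,
                             phosphosite_path = NULL,
                             out_dir = ".", config = nre_config(),
                             widths = c(10, 15, 21, 28, 36, 44),
                             n_motifs = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_all <- as.numeric(Sys.time())
  timings <- list()
  stage <- function(name, expr) {
    t0 <- as.numeric(Sys.time())
    res <- force(expr)
    timings[[name]] <<- round(as.numeric(Sys.time()) - t0, 3)
    nre_log(name, t0 = t0)
    res
  }

  proteins <- stage("read", read_proteins(fasta_path, annotation_path))
  topology <- stage("classify", assign_topology(proteins, config))
  segments <- stage("extract", extract_nre(proteins, topology, config))
  trimmed <- stage("strip", strip_cterminal(segments, config$cterm_strip))

  hist_tbl <- stage("profile_length", length_distribution(segments))
  profile <- stage("profile_scaled",
                   scaled_composition(segments, config$scale_bins))
  logo_c <- stage("profile_logo",
                  terminal_logo(segments, config$terminal_window, "C"))
  signature <- stage("signature", {
    purrr::map2(segments$protein_id, segments$sequence, function(id, s) {
      hit <- find_signature(s, config$signature_min_agree)
      if (nrow(hit)) dplyr::mutate(hit, protein_id = id, .before = 1) else NULL
    }) |> dplyr::bind_rows()
  })

  motifs <- stage("discover",
                  discover_zoops(trimmed, widths = widths,
                                 n_motifs = n_motifs,
                                 p_threshold = config$discovery_p,
                                 seed = config$random_seed))
  matches <- stage("scan", {
    dplyr::bind_rows(lapply(motifs, function(m) {
      scan_motif(m, trimmed, p_threshold = config$scan_p,
                 resolution = config$pvalue_resolution)
    }))
  })

  enrichment <- NULL
  contained <- NULL
  report <- NULL
  if (length(motifs) > 0 && nrow(matches) > 0) {
    enrichment <- stage("enrich", motif_enrichment(matches, trimmed))
    over <- filter_overrepresented(enrichment, config$nf_threshold)
    sites <- if (!is.null(phosphosite_path) && file.exists(phosphosite_path)) {
      read_phosphosites(phosphosite_path, proteins)
    } else {
      tibble::tibble(protein_id = character(), position = integer(),
                     residue = character(), source = character())
    }
    pm <- matches_to_protein_coords(matches, trimmed)
    contained <- stage("phospho_map", map_phosphosites(pm, sites))
    conservation <- dplyr::bind_rows(lapply(motifs, function(m) {
      conservation_summary(m, matches, contained)
    }))
    report <- stage("report", build_report(
      over, conservation, motifs))
  }

  # --- outputs ---
  outputs <- c(
    topology = write_table(topology, file.path(out_dir, "topology.tsv"),
                           key = "protein_id"),
    segments = write_table(
      segments[, setdiff(names(segments), "sequence")],
      file.path(out_dir, "nre_segments.tsv"), key = "protein_id"),
    nre_fasta = write_nre_fasta(segments,
                                file.path(out_dir, "nre_segments.fasta")),
    lengths = write_table(hist_tbl, file.path(out_dir, "length_hist.tsv")),
    signature = write_table(signature,
                            file.path(out_dir, "signature_hits.tsv"),
                            key = "protein_id")
  )
  prof_tbl <- tibble::as_tibble(profile$freq) |>
    dplyr::mutate(bin = dplyr::row_number() - 1L, .before = 1)
  outputs["profile"] <- write_table(prof_tbl,
                                    file.path(out_dir, "scaled_profile.tsv"),
                                    key = "bin")
  logo_tbl <- tibble::as_tibble(logo_c$freq) |>
    dplyr::mutate(position = dplyr::row_number(), .before = 1) |>
    dplyr::mutate(ic_bits = logo_c$ic, n = logo_c$n)
  outputs["logo"] <- write_table(logo_tbl, file.path(out_dir, "logo_C.tsv"),
                                 key = "position")
  if (length(motifs) > 0) {
    outputs["motifs"] <- write_meme(motifs, file.path(out_dir, "motifs.meme"))
    outputs["matches"] <- write_fimo_tsv(matches,
                                         file.path(out_dir, "matches.tsv"))
  }
  if (!is.null(enrichment)) {
    outputs["enrichment"] <- write_table(
      enrichment, file.path(out_dir, "enrichment.tsv"),
      key = c("motif_id", "class_label"))
  }
  if (!is.null(contained)) {
    outputs["phospho"] <- write_table(
      contained, file.path(out_dir, "phospho_containment.tsv"),
      key = c("motif_id", "protein_id", "position"))
  }
  if (!is.null(report)) {
    outputs["report"] <- write_table(report, file.path(out_dir, "report.tsv"),
                                     key = names(report)[1:2])
  }
  cfg_path <- write_config(config, file.path(out_dir, "config_used.txt"))

  manifest <- list(
    config = unclass(config),
    seed = config$random_seed,
    inputs = as.list(tools::md5sum(stats::na.omit(
      c(fasta_path, annotation_path, phosphosite_path)))),
    timings = timings,
    outputs = unname(outputs),
    total_elapsed = round(as.numeric(Sys.time()) - t_all, 3)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(proteins = proteins, topology = topology,
                 segments = segments, trimmed = trimmed,
                 length_hist = hist_tbl, profile = profile, logo = logo_c,
                 signature = signature, motifs = motifs, matches = matches,
                 enrichment = enrichment, contained = contained,
                 report = report, manifest = manifest, outputs = outputs,
                 config = config))
}
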