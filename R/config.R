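#' Pipeline configuration
#'
#' All tunables of the NRE pipeline with their defaults. The defaults follow
#' the analysis conventions of the large-scale plant RLK NRE survey this
#' package implements: an extracellular stretch shorter than 60 residues
#' (180 nt) does not count as an ectodomain, profiles are scaled to 200
#' positions, terminal logos use 20 residues, motif discovery and scanning
#' use p-value thresholds 0.005 and 0.001, the final 14 residues (the
#' C-terminal consensus) are stripped before motif work, and conservation
#' tiers cut at 50% and 80% identity.
#'
#' @param extracellular_max_len Residues; a TM-bearing protein with fewer
#'   extracellular residues than this and no annotated ectodomain is an
#'   RLCK with TM region.
#' @param scale_bins Number of bins for position-scaled composition.
#' @param terminal_window Residues in terminal logos.
#' @param discovery_p Motif discovery p-value threshold.
#' @param scan_p Motif scan p-value threshold.
#' @param cterm_strip Residues stripped from the NRE C-terminus before
#'   motif discovery (the 14-aa consensus).
#' @param identity_high,identity_moderate Conservation tier cuts (fractions).
#' @param nf_threshold Normalized-frequency cut; motifs with F strictly
#'   above it are called overrepresented.
#' @param tm_window,tm_gravy_threshold Fallback transmembrane detector:
#'   Kyte-Doolittle window length (odd) and mean-hydropathy threshold.
#' @param anchor_search_radius Residues searched either side of an annotated
#'   kinase start for the (L/I/V)GXG anchor.
#' @param signature_min_agree Minimum positional agreements (of 14) for a
#'   C-terminal consensus hit.
#' @param pwm_pseudocount Per-cell pseudocount multiplier on the background.
#' @param pvalue_resolution Score discretisation step, in bits, for exact
#'   p-value dynamic programming.
#' @param random_seed Integer seed used by stochastic stages.
#'
#' @return A list of class `nre_config`.
#' @export
#' @examples
#' cfg <- nre_config(scan_p = 1e-4)
#' cfg$scan_p
nre_config <- function(extracellular_max_len = 60,
                       scale_bins = 200,
                       terminal_window = 20,
                       discovery_p = 0.005,
                       scan_p = 0.001,
                       cterm_strip = 14,
                       identity_high = 0.80,
                       identity_moderate = 0.50,
                       nf_threshold = 1.0,
                       tm_window = 19,
                       tm_gravy_threshold = 1.6,
                       anchor_search_radius = 30,
                       signature_min_agree = 10,
                       pwm_pseudocount = 0.1,
                       pvalue_resolution = 1 / 1000,
                       random_seed = 1L) {
  cfg <- list(
    extracellular_max_len = extracellular_max_len,
    scale_bins = as.integer(scale_bins),
    terminal_window = as.integer(terminal_window),
    discovery_p = discovery_p,
    scan_p = scan_p,
    cterm_strip = as.integer(cterm_strip),
    identity_high = identity_high,
    identity_moderate = identity_moderate,
    nf_threshold = nf_threshold,
    tm_window = as.integer(tm_window),
    tm_gravy_threshold = tm_gravy_threshold,
    anchor_search_radius = as.integer(anchor_search_radius),
    signature_min_agree = as.integer(signature_min_agree),
    pwm_pseudocount = pwm_pseudocount,
    pvalue_resolution = pvalue_resolution,
    random_seed = as.integer(random_seed)
  )
  stopifnot(
    cfg$extracellular_max_len > 0, cfg$scale_bins > 0,
    cfg$terminal_window > 0, cfg$discovery_p > 0, cfg$scan_p > 0,
    cfg$cterm_strip >= 0, cfg$nf_threshold > 0,
    cfg$identity_moderate < cfg$identity_high, cfg$identity_high <= 1,
    cfg$tm_window >= 11, cfg$tm_window %% 2 == 1,
    cfg$pvalue_resolution > 0
  )
  structure(cfg, class = "nre_config")
}

#' Read a pipeline configuration from a key-value text file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and lines
#' starting with `#` are ignored. Keys must be [nre_config()] argument
#' names; unknown keys are an error naming the key.
#'
#' @param path Path to the config file.
#' @return An `nre_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- stringr::str_match(lines, "^([A-Za-z_]+)\\s*[:=]\\s*(.+)$")
  if (any(is.na(kv[, 1]))) {
    stop("unparseable config line: ", lines[which(is.na(kv[, 1]))[1]],
         call. = FALSE)
  }
  keys <- kv[, 2]
  vals <- as.numeric(kv[, 3])
  known <- names(formals(nre_config))
  if (any(!keys %in% known)) {
    stop("unknown config key: ", paste(setdiff(keys, known), collapse = ", "),
         call. = FALSE)
  }
  do.call(nre_config, as.list(stats::setNames(vals, keys)))
}

#' Write a pipeline configuration to a key-value text file
#'
#' @param config An `nre_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, format, "", scientific = FALSE)),
             path)
  invisible(path)
}

# Structured one-line log message: stage, counts, elapsed.
nre_log <- function(stage, ..., t0 = NULL) {
  fields <- c(...)
  msg <- sprintf("[%s] stage=%s", format(Sys.time(), "%H:%M:%S"), stage)
  if (length(fields)) {
    msg <- paste(msg, paste(names(fields), fields, sep = "=", collapse = " "))
  }
  if (!is.null(t0)) {
    msg <- sprintf("%s elapsed=%.2fs", msg, as.numeric(Sys.time()) - t0)
  }
  message(msg)
  invisible(msg)
}
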