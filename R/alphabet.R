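# Amino-acid alphabet, degenerate-letter expansions and hydropathy scale.

#' The 20 standard amino-acid letters
#'
#' Alphabetical one-letter codes used for all frequency matrices in the
#' package. Degenerate letters (see [aa_degenerate()]) are admitted in
#' sequences and motif consensi but never appear as matrix columns.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Degenerate amino-acid letters and their expansion sets
#'
#' B stands for D/N, Z for E/Q, J for I/L and X for any of the 20
#' standard residues. These codes occur in published NRE motif consensi
#' and are scored as (background-weighted) averages over their expansion
#' set throughout the package.
#'
#' @return Named list of character vectors.
#' @export
aa_degenerate <- function() {
  list(B = c("D", "N"), Z = c("E", "Q"), J = c("I", "L"), X = aa_alphabet())
}

# All admissible sequence letters.
aa_extended <- function() c(aa_alphabet(), names(aa_degenerate()))

# Kyte-Doolittle hydropathy values, indexed by one-letter code.
kyte_doolittle <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Encode a sequence string as integer indices into aa_alphabet();
# degenerate letters get codes 21..24 (B, Z, J, X); anything else errors.
aa_encode <- function(sequence) {
  letters_ext <- aa_extended()
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- match(chars, letters_ext)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("sequence contains letters outside the amino-acid alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  idx
}

# Row-stochastic 24 x 20 matrix mapping every admissible letter code to a
# probability row over the 20 standard letters. Degenerate letters split
# `how = "uniform"`ly over their expansion set, or proportionally to a
# background vector (`how = "background"`).
aa_expansion_matrix <- function(background = NULL) {
  ab <- aa_alphabet()
  deg <- aa_degenerate()
  m <- matrix(0, nrow = 20L + length(deg), ncol = 20L,
              dimnames = list(aa_extended(), ab))
  m[cbind(seq_len(20L), seq_len(20L))] <- 1
  for (d in names(deg)) {
    members <- deg[[d]]
    if (is.null(background)) {
      m[d, members] <- 1 / length(members)
    } else {
      w <- background[match(members, ab)]
      m[d, members] <- w / sum(w)
    }
  }
  m
}

# TRUE where consensus letter (possibly degenerate) matches an observed
# standard letter; vectorised over equal-length character vectors.
aa_letters_agree <- function(consensus_letters, observed_letters) {
  deg <- aa_degenerate()
  mapply(function(cl, ob) {
    if (cl == ob) return(TRUE)
    if (cl %in% names(deg)) return(ob %in% deg[[cl]])
    if (ob %in% names(deg)) return(cl %in% deg[[ob]])
    FALSE
  }, consensus_letters, observed_letters, USE.NAMES = FALSE)
}

# Validate a sequence against the extended alphabet (logical).
aa_valid <- function(sequence) {
  all(strsplit(sequence, "", fixed = TRUE)[[1]] %in% aa_extended())
}
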