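#' Amino-acid alphabet and residue tables
#'
#' `amino_acids()` returns the 20 standard one-letter residue codes.
#' `uniform_background()` returns the default background distribution
#' (uniform over the 20 residues). `kyte_doolittle()` returns the
#' hydropathy index used by [extract_tm_region()]. `residue_properties()`
#' returns the fixed 10-property physico-chemical table (logical matrix,
#' properties x residues) used by [conservation_scores()].
#'
#' @return See description; all tables are named by residue code.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname amino_acids
#' @export
uniform_background <- function() {
  stats::setNames(rep(1 / 20, 20), amino_acids())
}

#' @rdname amino_acids
#' @export
kyte_doolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)[amino_acids()]
}

#' @rdname amino_acids
#' @export
residue_properties <- function() {
  aa <- amino_acids()
  set <- function(members) stats::setNames(aa %in% members, aa)
  rbind(
    hydrophobic = set(c("A", "C", "F", "G", "H", "I", "K", "L", "M",
                        "T", "V", "W", "Y")),
    polar       = set(c("C", "D", "E", "H", "K", "N", "Q", "R", "S",
                        "T", "W", "Y")),
    small       = set(c("A", "C", "D", "G", "N", "P", "S", "T", "V")),
    tiny        = set(c("A", "G", "S")),
    aliphatic   = set(c("I", "L", "V")),
    aromatic    = set(c("F", "H", "W", "Y")),
    positive    = set(c("H", "K", "R")),
    negative    = set(c("D", "E")),
    charged     = set(c("D", "E", "H", "K", "R")),
    proline     = set("P")
  )
}

# residues coded 1..20 for the DP kernel; errors list offending characters
encode_residues <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, amino_acids())
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop(sprintf("%s contains non-amino-acid symbols: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  idx
}

# split a string (or pass through a character vector of single residues)
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]
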