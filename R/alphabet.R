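#' Canonical amino-acid alphabet
#'
#' The 20 canonical residues in the alphabetic order used for every encoder
#' dimension in this package ('ACDEFGHIKLMNPQRSTVWY').
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' kcr_alphabet()
kcr_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# letters treated as "uncertain composition": windows containing any of
# these are dropped at extraction time
.kcr_ambiguous <- c("B", "J", "O", "U", "X", "Z")

#' Default five-group physicochemical residue grouping
#'
#' Grouping used by the EGAAC encoder: g1 aliphatic (G,A,V,L,M,I), g2
#' aromatic (F,Y,W), g3 positively charged (K,R,H), g4 negatively charged
#' (D,E), g5 uncharged/polar (S,T,C,P,N,Q). A user-supplied grouping must be
#' a named character vector mapping each of the 20 residues to exactly one
#' of five group labels.
#'
#' @return Named character vector: names are residues, values group labels
#'   \code{"g1"}..\code{"g5"}.
#' @export
#' @examples
#' table(kcr_residue_groups())
kcr_residue_groups <- function() {
  g <- c(
    G = "g1", A = "g1", V = "g1", L = "g1", M = "g1", I = "g1",
    F = "g2", Y = "g2", W = "g2",
    K = "g3", R = "g3", H = "g3",
    D = "g4", E = "g4",
    S = "g5", T = "g5", C = "g5", P = "g5", N = "g5", Q = "g5"
  )
  g[kcr_alphabet()]
}

# validate a grouping: 5 disjoint groups covering all 20 residues
.check_grouping <- function(grouping) {
  aa <- kcr_alphabet()
  if (is.null(names(grouping)) || !setequal(names(grouping), aa) ||
      anyDuplicated(names(grouping)) > 0) {
    stop("grouping must map each of the 20 canonical residues exactly once",
         call. = FALSE)
  }
  if (length(unique(grouping)) != 5L) {
    stop("grouping must define exactly 5 groups", call. = FALSE)
  }
  grouping[aa]
}
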