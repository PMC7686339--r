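# column order of PSI-BLAST ASCII PSSM score blocks
.psiblast_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                     "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a PSI-BLAST ASCII PSSM profile
#'
#' Parses the standard \code{-out_ascii_pssm} layout and returns the first
#' (log-odds) 20-column score block with residue columns re-ordered to the
#' package's alphabetic order. With \code{center_pos} given, the 31 rows
#' covering positions \code{center_pos - n .. center_pos + n} are returned
#' as a window profile.
#'
#' @param path PSSM file path.
#' @param center_pos Optional 1-based window center; if NULL the full
#'   protein profile is returned.
#' @param n Flank length (default 15).
#' @return A \code{kcr_pssm_profile}: numeric matrix (rows = positions,
#'   columns = 20 residues alphabetic) with attributes \code{residues}
#'   (the protein's own sequence) and \code{source = "psiblast_file"}.
#' @export
read_psiblast_pssm <- function(path, center_pos = NULL, n = 15L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  fields <- strsplit(trimws(lines), "\\s+")
  is_row <- vapply(fields, function(f) {
    length(f) >= 22L && !is.na(suppressWarnings(as.integer(f[1]))) &&
      f[2] %in% LETTERS &&
      !anyNA(suppressWarnings(as.numeric(f[3:22])))
  }, logical(1))
  if (!any(is_row)) {
    stop("malformed PSI-BLAST PSSM: no score rows found in ", path,
         call. = FALSE)
  }
  rows <- fields[is_row]
  mat <- t(vapply(rows, function(f) as.numeric(f[3:22]), numeric(20)))
  res <- vapply(rows, `[[`, character(1), 2L)
  pos <- vapply(rows, function(f) as.integer(f[1]), integer(1))
  if (!identical(pos, seq_along(pos))) {
    stop("malformed PSI-BLAST PSSM: non-contiguous positions in ", path,
         call. = FALSE)
  }
  colnames(mat) <- .psiblast_order
  mat <- mat[, kcr_alphabet(), drop = FALSE]
  out <- structure(mat, residues = res, source = "psiblast_file",
                   class = "kcr_pssm_profile")
  if (is.null(center_pos)) out else slice_pssm(out, center_pos, n)
}

#' Slice a window profile out of a full-protein profile
#'
#' @param profile A \code{kcr_pssm_profile} covering the whole protein.
#' @param center_pos 1-based window center.
#' @param n Flank length; the slice covers \code{center_pos +/- n}.
#' @return A \code{(2n+1) x 20} \code{kcr_pssm_profile}.
#' @export
slice_pssm <- function(profile, center_pos, n = 15L) {
  L <- nrow(profile)
  if (center_pos - n < 1L || center_pos + n > L) {
    stop("window [", center_pos - n, ", ", center_pos + n,
         "] outside profile of length ", L, call. = FALSE)
  }
  out <- profile[(center_pos - n):(center_pos + n), , drop = FALSE]
  structure(out, source = attr(profile, "source"),
            class = "kcr_pssm_profile")
}

#' Build a corpus-level positional log-odds profile
#'
#' Fallback profile when PSI-BLAST output is unavailable: from the positive
#' training windows, for window position \eqn{i} and residue \eqn{j},
#' \deqn{S(i,j) = \log_2 \frac{(c_{ij} + 1)/(N + 20)}{b_j}}
#' with pseudo-count 1 and background \eqn{b_j} the overall residue
#' frequency in the full training corpus. The table has one row per window
#' position and is applied uniformly to every window of the corpus (it
#' carries positional corpus signal, not per-window signal).
#'
#' @param windows A \code{kcr_windows} data.frame containing at least one
#'   positive window; counts use the positive windows, background uses all.
#' @param pseudo Pseudo-count, default 1.
#' @return A \code{(2n+1) x 20} \code{kcr_pssm_profile} with
#'   \code{source = "internal_fallback"}.
#' @export
build_internal_profile <- function(windows, pseudo = 1) {
  seqs <- window_sequences(windows)
  lab <- if (is.data.frame(windows)) as.character(windows$label) else
    rep("positive", length(seqs))
  pos_seqs <- seqs[lab == "positive"]
  if (length(pos_seqs) == 0L) {
    stop("at least one positive training window is required", call. = FALSE)
  }
  aa <- kcr_alphabet()
  all_m <- seq_matrix(seqs)
  background <- vapply(aa, function(r) mean(all_m == r), numeric(1))
  background[background == 0] <- 1 / (length(all_m) + 20)  # keep finite
  background <- background / sum(background)
  m <- seq_matrix(pos_seqs)
  N <- nrow(m)
  S <- t(vapply(seq_len(ncol(m)), function(i) {
    counts <- vapply(aa, function(r) sum(m[, i] == r), numeric(1))
    log2(((counts + pseudo) / (N + 20 * pseudo)) / background)
  }, numeric(20)))
  colnames(S) <- aa
  structure(S, source = "internal_fallback", class = "kcr_pssm_profile")
}

#' Sigmoid normalisation of PSSM scores
#'
#' Elementwise logistic squashing \eqn{\Phi(S) = 1 / (1 + e^{-S/w})} with
#' scale \eqn{w} equal to the window length (31), mapping raw scores into
#' (0, 1) monotonically.
#'
#' @param S Numeric scalar, vector or matrix of finite scores.
#' @param w Scale, default 31.
#' @return Same shape as \code{S}, values strictly in (0, 1).
#' @export
#' @examples
#' sigmoid_normalize(0)        # 0.5
#' sigmoid_normalize(31)       # 1 / (1 + exp(-1))
sigmoid_normalize <- function(S, w = 31) {
  stopifnot(all(is.finite(S)))
  1 / (1 + exp(-S / w))
}

#' PSSM feature encoding of peptide windows
#'
#' Produces the 620-dimensional PSSM feature: the window's 31 x 20 profile
#' is sigmoid-normalised ([sigmoid_normalize()]) and flattened
#' position-major. The profile source is either a single corpus-level
#' fallback table ([build_internal_profile()]; every window then shares the
#' same feature values) or a named list of per-protein PSI-BLAST profiles
#' ([read_psiblast_pssm()]), sliced at each window's center. The
#' \code{"rowsum"} variant instead sums profile rows by the window's own
#' residue type into a 20 x 20 matrix before normalisation (400
#' dimensions).
#'
#' @param windows A \code{kcr_windows} data.frame (required for per-protein
#'   profiles) or character vector of sequences (fallback table only).
#' @param pssm A \code{kcr_pssm_profile} table with \code{2n+1} rows, or a
#'   named list of full-protein \code{kcr_pssm_profile}s keyed by protein
#'   id.
#' @param w Sigmoid scale, default the window length.
#' @param variant \code{"flat"} (620-dim, default) or \code{"rowsum"}
#'   (400-dim).
#' @return Numeric matrix, one row per window; columns
#'   \code{"PSSM:pos-15:A"} ... for \code{"flat"}, \code{"PSSM:A:A"} ... for
#'   \code{"rowsum"}.
#' @export
encode_pssm <- function(windows, pssm, w = NULL,
                        variant = c("flat", "rowsum")) {
  variant <- match.arg(variant)
  seqs <- window_sequences(windows)
  L <- nchar(seqs[1])
  n <- (L - 1L) %/% 2L
  if (is.null(w)) w <- L
  aa <- kcr_alphabet()

  get_profile <- function(i) {
    if (inherits(pssm, "kcr_pssm_profile")) {
      if (nrow(pssm) != L) {
        stop("fallback profile has ", nrow(pssm), " rows, windows have ",
             L, call. = FALSE)
      }
      pssm
    } else if (is.list(pssm)) {
      if (!is.data.frame(windows)) {
        stop("per-protein profiles require a kcr_windows data.frame",
             call. = FALSE)
      }
      id <- windows$protein_id[i]
      prof <- pssm[[id]]
      if (is.null(prof)) stop("no PSSM profile for protein ", id,
                              call. = FALSE)
      slice_pssm(prof, windows$center_pos[i], n)
    } else {
      stop("`pssm` must be a kcr_pssm_profile or a named list of them",
           call. = FALSE)
    }
  }

  if (variant == "flat") {
    cn <- as.vector(vapply(position_labels(L),
                           function(p) paste0("PSSM:", p, ":", aa),
                           character(20)))
    out <- t(vapply(seq_along(seqs), function(i) {
      as.vector(t(sigmoid_normalize(get_profile(i), w = w)))
    }, numeric(20L * L)))
  } else {
    cn <- as.vector(t(outer(aa, aa, function(a, b) paste0("PSSM:", a, ":", b))))
    out <- t(vapply(seq_along(seqs), function(i) {
      prof <- get_profile(i)
      res <- strsplit(seqs[i], "")[[1]]
      S <- matrix(0, 20, 20, dimnames = list(aa, aa))
      for (r in aa) {
        rows <- which(res == r)
        if (length(rows)) S[r, ] <- colSums(prof[rows, , drop = FALSE])
      }
      as.vector(t(sigmoid_normalize(S, w = w)))
    }, numeric(400)))
  }
  colnames(out) <- cn
  out
}
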