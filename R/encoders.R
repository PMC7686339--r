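# ---- shared helpers ---------------------------------------------------------

# windows -> character vector of sequences
window_sequences <- function(windows) {
  s <- if (is.data.frame(windows)) windows$sequence else windows
  if (!is.character(s) || length(s) == 0L) {
    stop("no window sequences supplied", call. = FALSE)
  }
  if (length(unique(nchar(s))) != 1L) {
    stop("all windows must have equal length", call. = FALSE)
  }
  s
}

# sequences -> n x L character matrix, canonical residues enforced
seq_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  bad <- setdiff(unique(as.vector(m)), kcr_alphabet())
  if (length(bad)) {
    stop("nonstandard residue(s) in window: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m
}

# ordered dipeptide names "AA","AC",... (400, first-residue-major)
dipeptide_names <- function() {
  aa <- kcr_alphabet()
  as.vector(t(outer(aa, aa, paste0)))
}

# position labels -n..+n as "pos-15", "pos0", "pos+15"
position_labels <- function(L) {
  n <- (L - 1L) %/% 2L
  offs <- seq(-n, n)
  ifelse(offs > 0, sprintf("pos+%d", offs),
         ifelse(offs < 0, sprintf("pos%d", offs), "pos0"))
}

# ---- encoders ---------------------------------------------------------------

#' Amino-acid composition (AAC) of peptide windows
#'
#' Frequency of each of the 20 residues over the window, i.e.
#' \eqn{P_x(k) = n_x(k) / n} with \eqn{n} the window length (31 by default
#' upstream). Entries sum to 1 per window.
#'
#' @param windows A \code{kcr_windows} data.frame or character vector of
#'   equal-length peptide sequences over the canonical alphabet.
#' @return Numeric matrix, one row per window, 20 named columns
#'   (\code{"AAC:A"} .. \code{"AAC:Y"}).
#' @export
#' @examples
#' encode_aac(c("AKAKA", "KKKKK"))
encode_aac <- function(windows) {
  m <- seq_matrix(window_sequences(windows))
  aa <- kcr_alphabet()
  out <- vapply(aa, function(r) rowMeans(m == r), numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(NULL, paste0("AAC:", aa)))
  out
}

#' Amino-acid pair composition (AAPC)
#'
#' Frequencies of the 400 ordered residue pairs. The default mode counts
#' adjacent dipeptides (\eqn{n - 1} pairs in an \eqn{n}-mer) normalised by
#' \eqn{n - 1}. The \code{"allpairs"} mode instead counts every ordered
#' position pair \eqn{(i, j), i \ne j} normalised by \eqn{n (n - 1)}; both
#' modes produce rows summing to 1. The mode used is recorded in the
#' \code{"mode"} attribute.
#'
#' @inheritParams encode_aac
#' @param mode \code{"adjacent"} (default) or \code{"allpairs"}.
#' @return Numeric matrix with 400 columns \code{"AAPC:AA"} ..
#'   \code{"AAPC:YY"}.
#' @export
encode_aapc <- function(windows, mode = c("adjacent", "allpairs")) {
  mode <- match.arg(mode)
  m <- seq_matrix(window_sequences(windows))
  aa <- kcr_alphabet()
  L <- ncol(m)
  nw <- nrow(m)
  out <- matrix(0, nw, 400, dimnames = list(NULL,
                paste0("AAPC:", dipeptide_names())))
  if (mode == "adjacent") {
    for (j in seq_len(L - 1L)) {
      idx <- (match(m[, j], aa) - 1L) * 20L + match(m[, j + 1L], aa)
      hit <- cbind(seq_len(nw), idx)
      out[hit] <- out[hit] + 1
    }
    out <- out / (L - 1L)
  } else {
    # ordered pairs (i, j), i != j: count(a,b) = c_a * c_b - [a == b] * c_a
    counts <- vapply(aa, function(r) rowSums(m == r), numeric(nw))
    for (a in seq_len(20L)) {
      for (b in seq_len(20L)) {
        v <- counts[, a] * counts[, b]
        if (a == b) v <- v - counts[, a]
        out[, (a - 1L) * 20L + b] <- v
      }
    }
    out <- out / (L * (L - 1L))
  }
  attr(out, "mode") <- mode
  out
}

#' Binary (one-hot) encoding (BE)
#'
#' Each position contributes a 20-dimensional indicator in alphabetic
#' residue order ('A' = 1 followed by 19 zeros, 'C' = 0,1,0,...), positions
#' concatenated N- to C-terminal: 31 x 20 = 620 dimensions for a 31-mer.
#'
#' @inheritParams encode_aac
#' @return Numeric 0/1 matrix with \code{20 * L} columns
#'   (\code{"BE:pos-15:A"}, ...).
#' @export
encode_be <- function(windows) {
  m <- seq_matrix(window_sequences(windows))
  aa <- kcr_alphabet()
  L <- ncol(m)
  nw <- nrow(m)
  pl <- position_labels(L)
  out <- matrix(0, nw, 20L * L, dimnames = list(NULL,
                as.vector(vapply(pl, function(p) paste0("BE:", p, ":", aa),
                                 character(20)))))
  for (j in seq_len(L)) {
    out[cbind(seq_len(nw), (j - 1L) * 20L + match(m[, j], aa))] <- 1
  }
  out
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For each gap \eqn{k}, counts residue pairs at positions \eqn{(i, i+k+1)}
#' (i.e. separated by exactly \eqn{k} residues) over the 400 ordered pairs,
#' normalised by the number of such pairs (\eqn{n - k - 1}) so that each
#' k-block sums to 1; \code{normalize = FALSE} returns raw counts. Gaps
#' k = 1..4 give 4 x 400 = 1600 dimensions (k = 0 would duplicate adjacent
#' AAPC).
#'
#' @inheritParams encode_aac
#' @param k_min,k_max Gap range, defaults 1 and 4.
#' @param normalize Divide each k-block by its pair count (default TRUE).
#' @return Numeric matrix with \code{400 * (k_max - k_min + 1)} columns
#'   (\code{"CKSAAP:k=1:AA"}, ...), blocks ordered by k.
#' @export
encode_cksaap <- function(windows, k_min = 1L, k_max = 4L, normalize = TRUE) {
  stopifnot(k_min >= 1L, k_min <= k_max)
  m <- seq_matrix(window_sequences(windows))
  aa <- kcr_alphabet()
  L <- ncol(m)
  if (L - k_max - 1L < 1L) {
    stop("window too short for gap k = ", k_max, call. = FALSE)
  }
  nw <- nrow(m)
  dp <- dipeptide_names()
  blocks <- lapply(seq(k_min, k_max), function(k) {
    blk <- matrix(0, nw, 400, dimnames = list(NULL,
                  paste0("CKSAAP:k=", k, ":", dp)))
    n_pairs <- L - k - 1L
    for (i in seq_len(n_pairs)) {
      idx <- (match(m[, i], aa) - 1L) * 20L + match(m[, i + k + 1L], aa)
      hit <- cbind(seq_len(nw), idx)
      blk[hit] <- blk[hit] + 1
    }
    if (normalize) blk / n_pairs else blk
  })
  do.call(cbind, blocks)
}

#' Enhanced amino-acid composition (EAAC)
#'
#' AAC computed inside a fixed-length sub-window (default 5) sliding from
#' the N- to the C-terminus: a 31-mer yields 27 sub-windows x 20 residues =
#' 540 dimensions, each 20-entry block summing to 1. Only full-length
#' sub-windows are used.
#'
#' @inheritParams encode_aac
#' @param subwindow Sliding sub-window length, default 5.
#' @return Numeric matrix with \code{20 * (L - subwindow + 1)} columns
#'   (\code{"EAAC:win1:A"}, ...), blocks ordered by sub-window start.
#' @export
encode_eaac <- function(windows, subwindow = 5L) {
  m <- seq_matrix(window_sequences(windows))
  L <- ncol(m)
  if (subwindow > L) stop("subwindow exceeds window length", call. = FALSE)
  aa <- kcr_alphabet()
  nw <- nrow(m)
  n_sub <- L - subwindow + 1L
  blocks <- lapply(seq_len(n_sub), function(w) {
    sub <- m[, w:(w + subwindow - 1L), drop = FALSE]
    blk <- vapply(aa, function(r) rowSums(sub == r) / subwindow, numeric(nw))
    matrix(blk, nrow = nw,
           dimnames = list(NULL, paste0("EAAC:win", w, ":", aa)))
  })
  do.call(cbind, blocks)
}

#' Enhanced grouped amino-acid composition (EGAAC)
#'
#' Like EAAC but over five physicochemical residue groups (see
#' [kcr_residue_groups()]): 27 sub-windows x 5 groups = 135 dimensions for a
#' 31-mer, each 5-entry block summing to 1.
#'
#' @inheritParams encode_eaac
#' @param grouping Named character vector mapping each residue to one of 5
#'   group labels; default [kcr_residue_groups()].
#' @return Numeric matrix with \code{5 * (L - subwindow + 1)} columns
#'   (\code{"EGAAC:win1:g1"}, ...).
#' @export
encode_egaac <- function(windows, subwindow = 5L,
                         grouping = kcr_residue_groups()) {
  grouping <- .check_grouping(grouping)
  m <- seq_matrix(window_sequences(windows))
  L <- ncol(m)
  if (subwindow > L) stop("subwindow exceeds window length", call. = FALSE)
  groups <- sort(unique(grouping))
  gm <- matrix(grouping[m], nrow = nrow(m))
  nw <- nrow(m)
  n_sub <- L - subwindow + 1L
  blocks <- lapply(seq_len(n_sub), function(w) {
    sub <- gm[, w:(w + subwindow - 1L), drop = FALSE]
    blk <- vapply(groups, function(g) rowSums(sub == g) / subwindow,
                  numeric(nw))
    matrix(blk, nrow = nw,
           dimnames = list(NULL, paste0("EGAAC:win", w, ":", groups)))
  })
  do.call(cbind, blocks)
}

#' Incorporated (concatenated) feature encoding
#'
#' Concatenates all seven encoders in the fixed order AAC, AAPC, BE, CKSAAP,
#' EAAC, EGAAC, PSSM: 20 + 400 + 620 + 1600 + 540 + 135 + 620 = 3935
#' dimensions for a 31-mer. Without a PSSM source (\code{pssm = NULL} and
#' \code{allow_no_pssm = TRUE}) the PSSM block is omitted (3315 dimensions).
#'
#' @inheritParams encode_aac
#' @param pssm PSSM source passed to [encode_pssm()]: a
#'   \code{kcr_pssm_profile} table or a named list of per-protein profiles
#'   (then \code{windows} must be a \code{kcr_windows} data.frame).
#' @param allow_no_pssm If TRUE, a missing \code{pssm} drops the PSSM block
#'   instead of erroring.
#' @param aapc_mode Passed to [encode_aapc()].
#' @return Numeric matrix with prefixed column names; attribute
#'   \code{"encoders"} lists the blocks included.
#' @export
encode_incorporated <- function(windows, pssm = NULL, allow_no_pssm = FALSE,
                                aapc_mode = "adjacent") {
  if (is.null(pssm) && !allow_no_pssm) {
    stop("no PSSM source supplied; pass `pssm` or set allow_no_pssm = TRUE",
         call. = FALSE)
  }
  parts <- list(encode_aac(windows),
                encode_aapc(windows, mode = aapc_mode),
                encode_be(windows),
                encode_cksaap(windows),
                encode_eaac(windows),
                encode_egaac(windows))
  enc <- c("aac", "aapc", "be", "cksaap", "eaac", "egaac")
  if (!is.null(pssm)) {
    parts <- c(parts, list(encode_pssm(windows, pssm)))
    enc <- c(enc, "pssm")
  }
  out <- do.call(cbind, parts)
  attr(out, "encoders") <- enc
  out
}

# ---- user-facing feature-matrix builder -------------------------------------

#' Encode a window set into a labeled feature matrix
#'
#' Applies the requested encoders in the canonical order and returns the
#' rectangular feature matrix together with the window keys and labels.
#'
#' @param windows A \code{kcr_windows} data.frame.
#' @param encoders Character subset of \code{c("aac", "aapc", "be",
#'   "cksaap", "eaac", "egaac", "pssm")}, or \code{"incorporated"} for all
#'   seven.
#' @param pssm PSSM source (see [encode_pssm()]); required iff "pssm" is
#'   requested.
#' @param aapc_mode,grouping Options forwarded to the respective encoders.
#' @return A \code{kcr_features} object: list with \code{x} (numeric
#'   matrix), \code{keys} (data.frame \code{protein_id}, \code{center_pos}),
#'   \code{labels} (factor negative/positive) and \code{encoders}.
#' @export
kcr_encode <- function(windows,
                       encoders = c("aac", "aapc", "be", "cksaap",
                                    "eaac", "egaac"),
                       pssm = NULL, aapc_mode = "adjacent",
                       grouping = kcr_residue_groups()) {
  stopifnot(is.data.frame(windows))
  all_enc <- c("aac", "aapc", "be", "cksaap", "eaac", "egaac", "pssm")
  if (identical(encoders, "incorporated")) encoders <- all_enc
  bad <- setdiff(encoders, all_enc)
  if (length(bad)) stop("unknown encoder(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  encoders <- all_enc[all_enc %in% encoders]  # canonical order
  if ("pssm" %in% encoders && is.null(pssm)) {
    stop("encoder 'pssm' requested but no PSSM source supplied",
         call. = FALSE)
  }
  parts <- lapply(encoders, function(e) {
    switch(e,
           aac = encode_aac(windows),
           aapc = encode_aapc(windows, mode = aapc_mode),
           be = encode_be(windows),
           cksaap = encode_cksaap(windows),
           eaac = encode_eaac(windows),
           egaac = encode_egaac(windows, grouping = grouping),
           pssm = encode_pssm(windows, pssm))
  })
  structure(
    list(x = do.call(cbind, parts),
         keys = data.frame(protein_id = windows$protein_id,
                           center_pos = windows$center_pos),
         labels = as_kcr_label(windows$label),
         encoders = encoders,
         params = list(aapc_mode = aapc_mode)),
    class = "kcr_features"
  )
}

#' @export
print.kcr_features <- function(x, ...) {
  cat(sprintf("<kcr_features> %d windows x %d dimensions [%s]\n",
              nrow(x$x), ncol(x$x), paste(x$encoders, collapse = "+")))
  cat(sprintf("  labels: %d positive / %d negative\n",
              sum(x$labels == "positive"), sum(x$labels == "negative")))
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' Key columns \code{protein_id}, \code{center_pos}, \code{label} followed
#' by one column per feature dimension, header included.
#'
#' @param features A \code{kcr_features} object.
#' @param path File path.
#' @return \code{kcr_write_features}: invisibly \code{path};
#'   \code{kcr_read_features}: a \code{kcr_features} object.
#' @export
kcr_write_features <- function(features, path) {
  stopifnot(inherits(features, "kcr_features"))
  df <- cbind(features$keys,
              data.frame(label = as.character(features$labels)),
              as.data.frame(features$x, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname kcr_write_features
#' @export
kcr_read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  keys <- df[, c("protein_id", "center_pos")]
  labels <- as_kcr_label(df$label)
  x <- as.matrix(df[, setdiff(names(df),
                              c("protein_id", "center_pos", "label")),
                    drop = FALSE])
  structure(list(x = x, keys = keys, labels = labels,
                 encoders = unique(sub(":.*$", "", tolower(colnames(x)))),
                 params = list()),
            class = "kcr_features")
}
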