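#' Position-specific residue frequency matrix
#'
#' Per-position residue frequencies across a window set — the numeric
#' content of a sequence-logo display. Rows are window positions
#' (-n .. +n, center 0), columns the 20 residues; every row sums to 1.
#'
#' @param windows A \code{kcr_windows} data.frame or character vector of
#'   equal-length sequences.
#' @return Numeric matrix \code{(2n+1) x 20} with attribute
#'   \code{"sample_size"}.
#' @export
position_frequency_matrix <- function(windows) {
  seqs <- window_sequences(windows)
  m <- seq_matrix(seqs)
  aa <- kcr_alphabet()
  out <- t(vapply(seq_len(ncol(m)), function(i) {
    vapply(aa, function(r) mean(m[, i] == r), numeric(1))
  }, numeric(20)))
  dimnames(out) <- list(position_labels(ncol(m)), aa)
  attr(out, "sample_size") <- nrow(m)
  out
}

#' Two-sample position-specific composition comparison
#'
#' Per (position, residue) cell, the frequency difference between two
#' window sets (\eqn{\Delta = f_A - f_B}) with a two-proportion z-test
#' p-value, the numeric content of a two-sample logo. Cells significant at
#' \code{alpha} (after Bonferroni correction across all
#' \code{(2n+1) x 20} cells by default) are flagged \code{"enriched"}
#' (\eqn{\Delta > 0}) or \code{"depleted"}.
#'
#' @param windows_a,windows_b Window sets (data.frames or sequence
#'   vectors), equal window length.
#' @param alpha Significance level, default 0.05.
#' @param bonferroni Apply Bonferroni correction across cells (default
#'   TRUE).
#' @param correct Apply the Yates continuity correction to the z statistic
#'   (default TRUE); without it the asymptotic test is anti-conservative at
#'   the low per-cell counts typical of residue frequencies.
#' @return data.frame with columns \code{position}, \code{residue},
#'   \code{delta}, \code{p_value}, \code{p_adj}, \code{flag}.
#' @export
two_sample_position_test <- function(windows_a, windows_b, alpha = 0.05,
                                     bonferroni = TRUE, correct = TRUE) {
  fa <- position_frequency_matrix(windows_a)
  fb <- position_frequency_matrix(windows_b)
  if (!identical(dim(fa), dim(fb))) {
    stop("window sets must have equal window length", call. = FALSE)
  }
  n1 <- attr(fa, "sample_size")
  n2 <- attr(fb, "sample_size")
  delta <- fa - fb
  pooled <- (fa * n1 + fb * n2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  cc <- if (correct) 0.5 * (1 / n1 + 1 / n2) else 0
  z <- ifelse(se > 0, pmax(0, abs(delta) - cc) / se, 0)
  p <- 2 * stats::pnorm(-z)
  m <- length(p)
  p_adj <- if (bonferroni) pmin(1, p * m) else p
  flag <- ifelse(p_adj < alpha,
                 ifelse(delta > 0, "enriched", "depleted"), "ns")
  out <- data.frame(position = rep(rownames(fa), 20),
                    residue = rep(colnames(fa), each = nrow(fa)),
                    delta = as.vector(delta),
                    p_value = as.vector(p),
                    p_adj = as.vector(p_adj),
                    flag = as.vector(flag))
  attr(out, "n_a") <- n1
  attr(out, "n_b") <- n2
  out
}

#' Write a position-frequency matrix as CSV
#'
#' Rows labeled by window position (-15 .. +15 for 31-mers), one column per
#' residue.
#'
#' @param pfm Matrix from [position_frequency_matrix()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
kcr_write_pfm <- function(pfm, path) {
  utils::write.csv(as.data.frame(pfm), path, row.names = TRUE)
  invisible(path)
}
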