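# shared fixture builders (everything generated in code, no stored data)

# n random valid 31-mer windows (center K, canonical alphabet), labeled
random_windows <- function(n, L = 31L, seed = 1, p_pos = 0.5) {
  aa <- kcr_alphabet()
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    ch <- sample(aa, L, replace = TRUE)
    ch[(L + 1L) %/% 2L] <- "K"
    paste(ch, collapse = "")
  }, character(1))
  structure(
    data.frame(protein_id = sprintf("W%03d", seq_len(n)),
               center_pos = (L + 1L) %/% 2L,
               label = ifelse(stats::runif(n) < p_pos, "positive",
                              "negative"),
               sequence = seqs),
    class = c("kcr_windows", "data.frame"), n = (L - 1L) %/% 2L)
}

# a kcr_proteins object from named sequences
make_proteins <- function(...) {
  seqs <- list(...)
  structure(
    lapply(names(seqs), function(id) {
      list(id = id, sequence = seqs[[id]], positive_sites = integer(0))
    }),
    class = "kcr_proteins")
}

# alternating A/K 31-mer starting and ending with A (16 A, 15 K)
alt_window <- function() {
  paste(rep(c("A", "K"), length.out = 31), collapse = "")
}

# balanced feature matrix with one planted informative column among noise
planted_matrix <- function(n = 200L, p_noise = 50L, shift = 1.5, seed = 1) {
  set.seed(seed)
  y <- rep(c("positive", "negative"), each = n %/% 2L)
  x <- matrix(stats::rnorm(n * (p_noise + 1L)), n,
              dimnames = list(NULL, c("signal",
                                      paste0("noise", seq_len(p_noise)))))
  x[, "signal"] <- x[, "signal"] + ifelse(y == "positive", shift, 0)
  list(x = x, y = y)
}
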