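test_that("FASTA reading takes ids from headers, uppercases, keeps order", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "MKAL", "ayqr",
               ">P2|x", "GGGG"), path)
  prots <- read_fasta(path)
  expect_length(prots, 2L)
  expect_equal(vapply(prots, `[[`, character(1), "id"), c("P1", "P2|x"))
  expect_equal(prots[[1]]$sequence, "MKALAYQR")  # multi-line, uppercased
})

test_that("empty and malformed FASTA are handled explicitly", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_warning(prots <- read_fasta(empty), "empty")
  expect_length(prots, 0L)
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("not a header", "MKAL"), bad)
  expect_error(read_fasta(bad), "malformed")
  expect_error(read_fasta("/nonexistent.fasta"), "not found")
})

test_that("annotations attach to lysines and reject everything else", {
  seq1 <- paste0(strrep("A", 15), "K", strrep("A", 15))  # K at 16
  prots <- make_proteins(P1 = seq1)
  tab <- data.frame(protein_id = c("P1", "P1", "PX", "P1"),
                    position = c(16L, 3L, 5L, 99L))
  out <- attach_annotations(prots, tab)
  expect_equal(out[[1]]$positive_sites, 16L)
  rej <- attr(out, "rejected")
  expect_equal(nrow(rej), 3L)
  expect_setequal(rej$reason, c("not lysine", "unknown id", "out of range"))
})

test_that("window extraction honors flank and alphabet filters", {
  seq31 <- paste0(strrep("A", 15), "K", strrep("A", 15))
  prots <- attach_annotations(make_proteins(P1 = seq31),
                              data.frame(protein_id = "P1", position = 16L))
  w <- extract_windows(prots)
  expect_equal(nrow(w), 1L)
  expect_equal(w$sequence, seq31)          # boundary: window == protein
  expect_equal(w$label, "positive")

  # K at position 10 of a 31-mer: left flank < 15, no window
  seq_short <- paste0(strrep("A", 9), "K", strrep("A", 21))
  w2 <- extract_windows(make_proteins(P1 = seq_short))
  expect_equal(nrow(w2), 0L)
  expect_equal(attr(w2, "report")$dropped_short_flank, 1L)

  # 3 clean-flanked lysines, 1 annotated -> 1 positive + 2 negative
  seq3 <- paste0(strrep("A", 15), "K", strrep("G", 10), "K",
                 strrep("G", 10), "K", strrep("A", 15))
  prots3 <- attach_annotations(
    make_proteins(P1 = seq3),
    data.frame(protein_id = "P1", position = 16L))
  w3 <- extract_windows(prots3)
  expect_equal(nrow(w3), 3L)
  expect_equal(sum(w3$label == "positive"), 1L)
  expect_equal(sum(w3$label == "negative"), 2L)

  # ambiguous residue inside the window drops it
  seqx <- paste0(strrep("A", 14), "X", "K", strrep("A", 15))
  wx <- extract_windows(make_proteins(P1 = seqx))
  expect_equal(nrow(wx), 0L)
  expect_equal(attr(wx, "report")$dropped_ambiguous, 1L)
})

test_that("every emitted window is a canonical 31-mer centered on K", {
  prots <- kcr_generate(kcr_generator_config(n_proteins = 25), seed = 3)
  w <- extract_windows(prots)
  expect_true(all(nchar(w$sequence) == 31L))
  expect_true(all(substr(w$sequence, 16, 16) == "K"))
  chars <- unique(unlist(strsplit(w$sequence, "")))
  expect_true(all(chars %in% kcr_alphabet()))
  # windows partition the valid lysines into positives and negatives
  n_k_valid <- sum(vapply(prots, function(p) {
    ch <- strsplit(p$sequence, "")[[1]]
    k <- which(ch == "K")
    sum(k > 15 & k <= length(ch) - 15)
  }, numeric(1)))
  expect_equal(nrow(w), n_k_valid)
})

test_that("greedy redundancy reduction follows the first-fit rule", {
  # identical sequences collapse to one representative
  s <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 3), collapse = "")
  two <- make_proteins(A = s, B = s)
  expect_length(reduce_redundancy(two), 1L)

  # chain A~B 35%, B~C 35%, A~C 10% at threshold 30%:
  # A representative, B joins A, C below threshold to A -> retained
  id_tab <- matrix(c(1, .35, .10, .35, 1, .35, .10, .35, 1), 3,
                   dimnames = list(c("sa", "sb", "sc"), c("sa", "sb", "sc")))
  key <- c(sa = "AAAA", sb = "CCCC", sc = "DDDD")
  stub <- function(a, b) {
    id_tab[names(key)[match(a, key)], names(key)[match(b, key)]]
  }
  chain <- make_proteins(A = "AAAA", B = "CCCC", C = "DDDD")
  reps <- reduce_redundancy(chain, 0.30, identity_fun = stub)
  expect_setequal(vapply(reps, `[[`, character(1), "id"), c("A", "C"))
  cl <- attr(reps, "clusters")
  expect_equal(cl$representative[cl$protein_id == "B"], "A")

  # below-threshold pair is kept whole
  pair <- make_proteins(A = "AAAA", B = "CCCC")
  stub25 <- function(a, b) 0.25
  expect_length(reduce_redundancy(pair, 0.30, identity_fun = stub25), 2L)

  expect_error(reduce_redundancy(two, identity_threshold = 1.5), "0, 1")
})

test_that("alignment identity is 1 for identical, low for unrelated", {
  expect_equal(kcrpred:::pairwise_identity("MKALAYQR", "MKALAYQR"), 1)
  expect_lt(kcrpred:::pairwise_identity(strrep("AC", 10), strrep("WY", 10)),
            0.3)
})

test_that("train/test split is stratified with floor rounding and seeded", {
  w <- random_windows(1000, seed = 2, p_pos = 0.2)
  w$label <- rep(c("positive", "negative"), c(200, 800))
  sp <- split_train_test(w, fraction = 0.8, seed = 5)
  expect_equal(sum(sp$train$label == "positive"), 160L)
  expect_equal(sum(sp$train$label == "negative"), 640L)
  expect_equal(nrow(sp$test), 200L)
  # disjointness on (protein_id, center_pos)
  key <- function(d) paste(d$protein_id, d$center_pos)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  # determinism
  sp2 <- split_train_test(w, fraction = 0.8, seed = 5)
  expect_identical(sp$train$sequence, sp2$train$sequence)

  w4 <- random_windows(4, seed = 3)
  w4$label <- c("positive", "positive", "negative", "negative")
  sp4 <- split_train_test(w4, fraction = 0.5, seed = 1)
  expect_equal(as.vector(table(sp4$train$label)), c(1L, 1L))

  w1 <- random_windows(3, seed = 4)
  w1$label <- c("positive", "negative", "negative")
  expect_error(split_train_test(w1), "fewer than 2")
})

test_that("protein-level split keeps each protein on one side", {
  w <- random_windows(60, seed = 8)
  w$protein_id <- rep(sprintf("P%02d", 1:12), each = 5)
  sp <- split_train_test(w, seed = 1, level = "protein")
  expect_length(intersect(unique(sp$train$protein_id),
                          unique(sp$test$protein_id)), 0L)
})

test_that("undersampling balances classes as a seeded subset of the input", {
  w <- random_windows(1000, seed = 6)
  w$label <- rep(c("positive", "negative"), c(100, 900))
  u <- undersample(w, seed = 9)
  expect_equal(as.vector(table(u$label)), c(100L, 100L))
  expect_true(all(u$sequence %in% w$sequence))
  expect_identical(undersample(w, seed = 9)$sequence, u$sequence)
  expect_false(identical(undersample(w, seed = 10)$sequence, u$sequence))

  wb <- random_windows(100, seed = 7)
  wb$label <- rep(c("positive", "negative"), each = 50)
  expect_warning(ub <- undersample(wb), "unchanged")
  expect_equal(nrow(ub), 100L)

  w0 <- random_windows(5, seed = 1)
  w0$label <- "positive"
  expect_error(undersample(w0), "per class")
})

test_that("window TSV round-trips", {
  w <- random_windows(20, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  kcr_write_windows(w, path)
  w2 <- kcr_read_windows(path)
  expect_equal(as.data.frame(w), as.data.frame(w2))
  expect_equal(attr(w2, "n"), 15L)
})
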