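uniformK <- strrep("K", 31)

test_that("encoder dimensionalities match the printed table for 31-mers", {
  w <- random_windows(50, seed = 1)
  dims <- c(aac = 20L, aapc = 400L, be = 620L, cksaap = 1600L,
            eaac = 540L, egaac = 135L)
  got <- vapply(names(dims), function(e) {
    ncol(kcr_encode(w, encoders = e)$x)
  }, integer(1))
  expect_equal(got, dims)
  for (e in names(dims)) {
    x <- kcr_encode(w, encoders = e)$x
    expect_false(anyDuplicated(colnames(x)) > 0)
  }
})

test_that("AAC counts residues and normalises to 1", {
  a <- encode_aac(uniformK)
  expect_equal(unname(a[1, "AAC:K"]), 1)
  expect_equal(sum(a), 1)
  alt <- encode_aac(alt_window())
  expect_equal(unname(alt[1, "AAC:A"]), 16 / 31)
  expect_equal(unname(alt[1, "AAC:K"]), 15 / 31)
  x <- encode_aac(random_windows(30, seed = 2))
  expect_equal(unname(rowSums(x)), rep(1, 30))
})

test_that("AAC equals the positionwise mean of the one-hot encoding", {
  w <- random_windows(40, seed = 3)
  aac <- encode_aac(w)
  be <- encode_be(w)
  for (r in kcr_alphabet()) {
    cols <- grep(paste0(":", r, "$"), colnames(be))
    expect_equal(unname(aac[, paste0("AAC:", r)]),
                 unname(rowMeans(be[, cols])))
  }
})

test_that("AAPC adjacent mode counts dipeptides; allpairs mode matches its
           brute-force enumeration", {
  a <- encode_aapc(uniformK)
  expect_equal(unname(a[1, "AAPC:KK"]), 1)
  alt <- encode_aapc(alt_window())
  expect_equal(unname(alt[1, "AAPC:AK"]), 15 / 30)
  expect_equal(unname(alt[1, "AAPC:KA"]), 15 / 30)
  w <- random_windows(20, seed = 4)
  for (mode in c("adjacent", "allpairs")) {
    x <- encode_aapc(w, mode = mode)
    expect_equal(unname(rowSums(x)), rep(1, 20), tolerance = 1e-12)
  }
  # brute-force all ordered position pairs oracle
  x_all <- encode_aapc(w, mode = "allpairs")
  for (i in c(1, 20)) {
    ch <- strsplit(w$sequence[i], "")[[1]]
    brute <- numeric(0)
    for (nm in colnames(x_all)) {
      pr <- substr(nm, 6, 7)
      a1 <- substr(pr, 1, 1); a2 <- substr(pr, 2, 2)
      n_ab <- sum(outer(ch == a1, ch == a2) & !diag(31))
      brute[nm] <- n_ab / (31 * 30)
    }
    expect_equal(unname(x_all[i, ]), unname(brute[colnames(x_all)]))
  }
})

test_that("binary encoding is per-position one-hot in alphabetic order", {
  w <- paste0("A", "C", strrep("K", 29))
  be <- encode_be(w)
  expect_equal(unname(be[1, 1:20]), c(1, rep(0, 19)))          # 'A'
  expect_equal(unname(be[1, 21:40]), c(0, 1, rep(0, 18)))      # 'C'
  x <- encode_be(random_windows(25, seed = 5))
  expect_equal(unname(rowSums(x)), rep(31, 25))  # exactly 31 ones
  expect_true(all(x %in% c(0, 1)))
})

test_that("CKSAAP matches brute-force k-spaced pair enumeration", {
  u <- encode_cksaap(uniformK)
  for (k in 1:4) {
    expect_equal(unname(u[1, paste0("CKSAAP:k=", k, ":KK")]), 1)
  }
  alt <- encode_cksaap(alt_window())
  expect_equal(unname(alt[1, "CKSAAP:k=1:AA"]), 15 / 29)
  expect_equal(unname(alt[1, "CKSAAP:k=1:KK"]), 14 / 29)

  w <- random_windows(20, seed = 6)
  x <- encode_cksaap(w)
  for (i in seq_len(nrow(w))) {
    ch <- strsplit(w$sequence[i], "")[[1]]
    for (k in 1:4) {
      # independent double loop over (i, i+k+1) pairs
      brute <- table(factor(
        vapply(seq_len(31 - k - 1), function(p) {
          paste0(ch[p], ch[p + k + 1])
        }, character(1)),
        levels = kcrpred:::dipeptide_names())) / (31 - k - 1)
      cols <- paste0("CKSAAP:k=", k, ":", names(brute))
      expect_equal(unname(x[i, cols]), unname(as.vector(brute)))
    }
  }
  # each k-block sums to 1
  for (k in 1:4) {
    cols <- grep(paste0("k=", k, ":"), colnames(x), fixed = TRUE)
    expect_equal(unname(rowSums(x[, cols])), rep(1, 20))
  }
  expect_error(encode_cksaap("AKAKA", k_max = 4), "too short")
})

test_that("EAAC blocks equal AAC computed on the corresponding 5-mer", {
  u <- encode_eaac(uniformK)
  expect_true(all(u[1, grep(":K$", colnames(u))] == 1))
  alt <- encode_eaac(alt_window())
  expect_equal(unname(alt[1, "EAAC:win1:A"]), 3 / 5)
  expect_equal(unname(alt[1, "EAAC:win1:K"]), 2 / 5)

  w <- random_windows(15, seed = 7)
  x <- encode_eaac(w)
  expect_equal(ncol(x), 540L)
  for (i in c(1, 8, 15)) {
    for (sub in c(1, 13, 27)) {
      five <- substr(w$sequence[i], sub, sub + 4)
      aac5 <- encode_aac(five)
      cols <- paste0("EAAC:win", sub, ":", kcr_alphabet())
      expect_equal(unname(x[i, cols]), unname(aac5[1, ]))
    }
  }
  blocks <- matrix(colSums(x[, ]), nrow = 20)  # 27 blocks x 20 entries
  expect_equal(unname(colSums(blocks)), rep(15, 27))  # each block row-sums 1
  expect_error(encode_eaac("AKA", subwindow = 5), "exceeds")
})

test_that("EGAAC groups residues into the five physicochemical classes", {
  u <- encode_egaac(uniformK)
  expect_true(all(u[1, grep(":g3$", colnames(u))] == 1))  # K is basic
  alt <- encode_egaac(alt_window())
  expect_equal(unname(alt[1, "EGAAC:win1:g1"]), 3 / 5)  # A aliphatic
  expect_equal(unname(alt[1, "EGAAC:win1:g3"]), 2 / 5)
  x <- encode_egaac(random_windows(10, seed = 8))
  expect_equal(ncol(x), 135L)
  for (sub in c(1, 27)) {
    cols <- grep(paste0("win", sub, ":"), colnames(x), fixed = TRUE)
    expect_equal(unname(rowSums(x[, cols])), rep(1, 10))
  }
  badgroups <- setNames(rep("g1", 20), kcr_alphabet())
  expect_error(encode_egaac(uniformK, grouping = badgroups), "5 groups")
})

test_that("incorporated encoding concatenates the seven blocks in order", {
  w <- random_windows(5, seed = 9)
  prof <- build_internal_profile(w)
  inc <- encode_incorporated(w, pssm = prof)
  expect_equal(ncol(inc), 3935L)
  expect_equal(20L + 400L + 620L + 1600L + 540L + 135L + 620L, 3935L)
  prefixes <- unique(sub(":.*$", "", colnames(inc)))
  expect_equal(prefixes, c("AAC", "AAPC", "BE", "CKSAAP", "EAAC", "EGAAC",
                           "PSSM"))
  no_pssm <- encode_incorporated(w, allow_no_pssm = TRUE)
  expect_equal(ncol(no_pssm), 3315L)
  expect_false(any(grepl("^PSSM", colnames(no_pssm))))
  expect_error(encode_incorporated(w), "PSSM")
})

test_that("encoders reject nonstandard residues and ragged windows", {
  expect_error(encode_aac("AXKAA"), "nonstandard")
  expect_error(encode_aac(c("AKA", "AKAAA")), "equal length")
})

test_that("feature names round-trip through index lookup", {
  w <- random_windows(3, seed = 10)
  f <- kcr_encode(w, encoders = c("aac", "egaac"))
  nm <- colnames(f$x)
  expect_identical(nm[match(nm, colnames(f$x))], nm)
  expect_equal(f$encoders, c("aac", "egaac"))
})

test_that("feature CSV round-trips with labels and keys", {
  w <- random_windows(12, seed = 11)
  f <- kcr_encode(w, encoders = "aac")
  path <- withr::local_tempfile(fileext = ".csv")
  kcr_write_features(f, path)
  f2 <- kcr_read_features(path)
  expect_equal(f2$x, f$x)
  expect_equal(as.character(f2$labels), as.character(f$labels))
  expect_equal(f2$keys$protein_id, f$keys$protein_id)
})
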