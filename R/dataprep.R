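#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased; record ids are the first whitespace-delimited
#' token of each header. Site annotations are attached separately with
#' [attach_annotations()].
#'
#' @param path FASTA file path (multi-line sequences allowed).
#' @return A \code{kcr_proteins} object: a list of records with fields
#'   \code{id}, \code{sequence} and \code{positive_sites} (empty on read).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(structure(list(), class = "kcr_proteins"))
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  proteins <- mapply(function(id, s) {
    list(id = id, sequence = s, positive_sites = integer(0))
  }, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  structure(proteins, class = "kcr_proteins")
}

#' @export
print.kcr_proteins <- function(x, ...) {
  npos <- sum(vapply(x, function(p) length(p$positive_sites), integer(1)))
  cat(sprintf("<kcr_proteins> %d sequences, %d annotated Kcr sites\n",
              length(x), npos))
  invisible(x)
}

#' Read a site-annotation table
#'
#' Tab-separated, two columns \code{protein_id<TAB>position} (1-based); a
#' header line is detected and skipped if the second field of the first row
#' is not numeric.
#'
#' @param path File path.
#' @return data.frame with columns \code{protein_id}, \code{position}.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  header <- length(first) == 1L &&
    is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][2])))
  tab <- utils::read.table(path, sep = "\t", header = header,
                           col.names = c("protein_id", "position"),
                           colClasses = c("character", "integer"))
  tab
}

#' Attach Kcr site annotations to proteins
#'
#' Rows whose protein id is unknown, whose position falls outside the
#' sequence, or whose position does not index a lysine are collected in a
#' rejection report (attribute \code{"rejected"}), never silently dropped.
#'
#' @param proteins A \code{kcr_proteins} object.
#' @param table data.frame with columns \code{protein_id}, \code{position}
#'   (1-based).
#' @return The proteins with \code{positive_sites} filled in; the attribute
#'   \code{"rejected"} holds a data.frame \code{protein_id}, \code{position},
#'   \code{reason}.
#' @export
attach_annotations <- function(proteins, table) {
  stopifnot(inherits(proteins, "kcr_proteins"),
            all(c("protein_id", "position") %in% names(table)))
  ids <- vapply(proteins, `[[`, character(1), "id")
  rej <- list()
  sites <- stats::setNames(vector("list", length(proteins)), ids)
  for (r in seq_len(nrow(table))) {
    id <- as.character(table$protein_id[r])
    pos <- as.integer(table$position[r])
    i <- match(id, ids)
    if (is.na(i)) {
      rej[[length(rej) + 1L]] <- data.frame(protein_id = id, position = pos,
                                            reason = "unknown id")
    } else if (is.na(pos) || pos < 1L || pos > nchar(proteins[[i]]$sequence)) {
      rej[[length(rej) + 1L]] <- data.frame(protein_id = id, position = pos,
                                            reason = "out of range")
    } else if (substr(proteins[[i]]$sequence, pos, pos) != "K") {
      rej[[length(rej) + 1L]] <- data.frame(protein_id = id, position = pos,
                                            reason = "not lysine")
    } else {
      sites[[i]] <- c(sites[[i]], pos)
    }
  }
  for (i in seq_along(proteins)) {
    proteins[[i]]$positive_sites <- sort(unique(as.integer(sites[[i]])))
  }
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(protein_id = character(0), position = integer(0),
               reason = character(0))
  attr(proteins, "rejected") <- rejected
  proteins
}

#' Extract labeled peptide windows around lysines
#'
#' One window per lysine that has at least \code{n} residues on both sides
#' and no nonstandard residue (B, J, O, U, X, Z or any other non-canonical
#' letter) inside the window. The window is labeled positive iff its center
#' position is an annotated Kcr site. Lysines with short flanks or uncertain
#' composition are dropped and counted in the report attribute.
#'
#' @param proteins A \code{kcr_proteins} object (annotations attached).
#' @param n Flank length; windows have \code{2 * n + 1} residues (default
#'   n = 15, i.e. 31-mers).
#' @return A \code{kcr_windows} data.frame with columns \code{protein_id},
#'   \code{center_pos}, \code{label} ("positive"/"negative") and
#'   \code{sequence}; attributes \code{n} and \code{report} (counts of
#'   emitted and dropped windows).
#' @export
#' @examples
#' p <- structure(list(list(id = "P1",
#'   sequence = paste(rep("A", 31), collapse = ""),
#'   positive_sites = integer(0))), class = "kcr_proteins")
#' extract_windows(p)  # no lysine: zero windows
extract_windows <- function(proteins, n = 15L) {
  stopifnot(inherits(proteins, "kcr_proteins"), n >= 1L)
  aa <- kcr_alphabet()
  out <- list()
  dropped_flank <- 0L
  dropped_ambiguous <- 0L
  for (p in proteins) {
    chars <- strsplit(p$sequence, "")[[1]]
    L <- length(chars)
    for (pos in which(chars == "K")) {
      if (pos - n < 1L || pos + n > L) {
        dropped_flank <- dropped_flank + 1L
        next
      }
      win <- chars[(pos - n):(pos + n)]
      if (!all(win %in% aa)) {
        dropped_ambiguous <- dropped_ambiguous + 1L
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        protein_id = p$id,
        center_pos = pos,
        label = if (pos %in% p$positive_sites) "positive" else "negative",
        sequence = paste(win, collapse = "")
      )
    }
  }
  windows <- if (length(out)) do.call(rbind, out) else
    data.frame(protein_id = character(0), center_pos = integer(0),
               label = character(0), sequence = character(0))
  structure(windows,
            class = c("kcr_windows", "data.frame"),
            n = as.integer(n),
            report = list(emitted = nrow(windows),
                          dropped_short_flank = dropped_flank,
                          dropped_ambiguous = dropped_ambiguous))
}

# matches / alignment length of a Needleman-Wunsch global alignment
pairwise_identity <- function(a, b) {
  letters26 <- LETTERS
  m <- matrix(-1, 26, 26, dimnames = list(letters26, letters26))
  diag(m) <- 2
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = m,
                                       gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) /
    nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' Greedy redundancy reduction of protein sequences
#'
#' CD-HIT-style greedy incremental clustering: proteins are visited
#' longest-first; each joins the first retained representative with pairwise
#' identity at or above the threshold (matches over alignment length of a
#' global alignment), otherwise it becomes a new representative. Only
#' representatives are returned. The full word-filter heuristics of CD-HIT
#' are out of scope; this is the greedy rule at its core.
#'
#' @param proteins A \code{kcr_proteins} object.
#' @param identity_threshold Clustering threshold in (0, 1], default 0.30.
#' @param identity_fun Function \code{(seq_a, seq_b) -> identity in [0,1]};
#'   defaults to global-alignment identity. Injectable for testing or for
#'   plugging in an external aligner.
#' @return Representatives as a \code{kcr_proteins} object; attribute
#'   \code{"clusters"} maps every input id to its representative id.
#' @export
reduce_redundancy <- function(proteins, identity_threshold = 0.30,
                              identity_fun = pairwise_identity) {
  stopifnot(inherits(proteins, "kcr_proteins"))
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1) {
    stop("identity_threshold must lie in (0, 1]", call. = FALSE)
  }
  lens <- vapply(proteins, function(p) nchar(p$sequence), integer(1))
  ord <- order(-lens)  # longest first, stable for ties
  reps <- list()
  membership <- character(0)
  for (i in ord) {
    p <- proteins[[i]]
    joined <- NA_character_
    for (r in reps) {
      if (identity_fun(p$sequence, r$sequence) >= identity_threshold) {
        joined <- r$id
        break
      }
    }
    if (is.na(joined)) {
      reps[[length(reps) + 1L]] <- p
      joined <- p$id
    }
    membership[p$id] <- joined
  }
  out <- structure(reps, class = "kcr_proteins")
  attr(out, "clusters") <- data.frame(protein_id = names(membership),
                                      representative = unname(membership))
  out
}

#' Stratified train/test split of peptide windows
#'
#' Positive and negative windows are split independently at the stated
#' fraction (train size = floor(fraction x class size)), seeded. With
#' \code{level = "protein"} whole proteins are assigned to one side to avoid
#' homolog leakage between train and test.
#'
#' @param windows A \code{kcr_windows} data.frame.
#' @param fraction Training fraction in (0, 1), default 0.8.
#' @param seed Integer seed.
#' @param level \code{"window"} (default, matches per-site train/test
#'   accounting) or \code{"protein"}.
#' @return List with elements \code{train}, \code{test} (both
#'   \code{kcr_windows}) and \code{seed}.
#' @export
split_train_test <- function(windows, fraction = 0.8, seed = 1,
                             level = c("window", "protein")) {
  level <- match.arg(level)
  stopifnot(fraction > 0, fraction < 1)
  lab <- as.character(windows$label)
  for (cl in c("positive", "negative")) {
    if (sum(lab == cl) < 2L) {
      stop("class '", cl, "' has fewer than 2 windows", call. = FALSE)
    }
  }
  idx_train <- with_seed(seed, {
    if (level == "window") {
      unlist(lapply(c("positive", "negative"), function(cl) {
        idx <- which(lab == cl)
        sample(idx, floor(fraction * length(idx)))
      }))
    } else {
      ids <- unique(windows$protein_id)
      train_ids <- sample(ids, floor(fraction * length(ids)))
      which(windows$protein_id %in% train_ids)
    }
  })
  n_attr <- attr(windows, "n")
  mk <- function(df) {
    structure(df, class = c("kcr_windows", "data.frame"), n = n_attr)
  }
  list(train = mk(windows[sort(idx_train), , drop = FALSE]),
       test = mk(windows[sort(setdiff(seq_len(nrow(windows)), idx_train)), ,
                         drop = FALSE]),
       seed = seed)
}

#' Random undersampling of the negative class
#'
#' Keeps all positive windows and a seeded uniform sample of negatives of
#' equal size, the balancing step used before training on heavily imbalanced
#' site data. If negatives do not outnumber positives the input is returned
#' unchanged with a warning.
#'
#' @param windows A \code{kcr_windows} data.frame.
#' @param seed Integer seed.
#' @return A balanced \code{kcr_windows} data.frame (row order: input order).
#' @export
undersample <- function(windows, seed = 1) {
  lab <- as.character(windows$label)
  n_pos <- sum(lab == "positive")
  n_neg <- sum(lab == "negative")
  if (n_pos == 0L || n_neg == 0L) {
    stop("undersample requires at least one window per class", call. = FALSE)
  }
  if (n_neg <= n_pos) {
    warning("negatives do not outnumber positives; returning input unchanged",
            call. = FALSE)
    return(windows)
  }
  keep_neg <- with_seed(seed, sample(which(lab == "negative"), n_pos))
  keep <- sort(c(which(lab == "positive"), keep_neg))
  structure(windows[keep, , drop = FALSE],
            class = c("kcr_windows", "data.frame"),
            n = attr(windows, "n"))
}

#' Write / read a window set as TSV
#'
#' Four tab-separated columns \code{protein_id, center_pos, label, sequence}
#' with a header.
#'
#' @param windows A \code{kcr_windows} data.frame.
#' @param path File path.
#' @return \code{kcr_write_windows}: invisibly, \code{path};
#'   \code{kcr_read_windows}: a \code{kcr_windows} data.frame.
#' @export
kcr_write_windows <- function(windows, path) {
  utils::write.table(as.data.frame(windows)[, c("protein_id", "center_pos",
                                                "label", "sequence")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname kcr_write_windows
#' @export
kcr_read_windows <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer",
                                         "character", "character"))
  n <- (nchar(df$sequence[1]) - 1L) %/% 2L
  structure(df, class = c("kcr_windows", "data.frame"),
            n = if (nrow(df)) n else NA_integer_)
}
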