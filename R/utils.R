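# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All package randomness flows through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic fan-out of one user-facing seed into per-stage seeds, so
#' that e.g. the train/test split and the undersampling draw are decoupled
#' but both reproducible from a single integer.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label.
#' @return An integer in [0, 2^31).
#' @export
#' @examples
#' kcr_stage_seed(1, "split")
kcr_stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

# stratified fold assignment: returns integer fold id per sample
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# normalize label input to a factor with levels negative < positive
as_kcr_label <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- ifelse(labels, "positive", "negative")
  if (is.numeric(labels)) labels <- ifelse(labels > 0, "positive", "negative")
  bad <- setdiff(unique(labels), c("positive", "negative"))
  if (length(bad)) {
    stop("labels must be 'positive'/'negative' (got: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  factor(labels, levels = c("negative", "positive"))
}
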