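#' Label windows as reliable, unreliable, or discarded
#'
#' Turns per-window absolute heart-rate errors into binary reliability
#' labels: errors strictly below 2 bpm are reliable (class 1), errors
#' strictly above 6 bpm are unreliable (class 0), and errors in the
#' ambiguous band [2, 6] bpm — including the boundaries, since the defining
#' inequalities are strict — are discarded (label `NA`), excluded from both
#' training and testing. Windows without an estimate or without a reference
#' are likewise discarded, with a distinct reason code.
#'
#' @param records Data frame with an `abs_err_bpm` column (see
#'   [extract_windows()]).
#' @return `records` with added `label` (1, 0 or `NA`) and `label_reason`
#'   (`"reliable"`, `"unreliable"`, `"ambiguous"`, `"no_estimate"`,
#'   `"no_reference"`).
#' @examples
#' label_windows(data.frame(abs_err_bpm = c(1.5, 4, 7)))$label
#' @export
label_windows <- function(records) {
  err <- records$abs_err_bpm
  label <- rep(NA_integer_, nrow(records))
  reason <- rep("ambiguous", nrow(records))
  reason[is.na(err)] <- "no_estimate"
  if (!is.null(records$hr_ref_bpm)) {
    reason[is.na(records$hr_ref_bpm)] <- "no_reference"
  }
  ok <- !is.na(err)
  label[ok & err < 2] <- 1L
  label[ok & err > 6] <- 0L
  reason[ok & err < 2] <- "reliable"
  reason[ok & err > 6] <- "unreliable"
  records$label <- label
  records$label_reason <- reason
  records
}

#' Subject-stratified fold assignment
#'
#' Assigns every subject — and hence every one of their windows — to exactly
#' one of `k` folds, so no individual contributes to both training and test
#' data. Subjects are shuffled deterministically by seed, then assigned in
#' decreasing order of record count to the currently smallest fold (greedy
#' balancing by record count).
#'
#' @param subject_ids Character/factor vector, one entry per record.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the subject shuffle.
#' @return Integer vector of fold ids (1..k) aligned to `subject_ids`, with
#'   attribute `subject_folds` (named vector mapping subject to fold).
#' @export
make_subject_folds <- function(subject_ids, k = 5, seed = 1L) {
  subject_ids <- as.character(subject_ids)
  counts <- table(subject_ids)
  if (length(counts) < k) {
    stop("need at least k = ", k, " distinct subjects, got ", length(counts))
  }
  subs <- with_seed(seed, sample(names(counts)))
  subs <- subs[order(-counts[subs])]  # stable: preserves shuffled tie order
  load <- numeric(k)
  fold_of <- stats::setNames(integer(length(subs)), subs)
  for (s in subs) {
    f <- which.min(load)
    fold_of[s] <- f
    load[f] <- load[f] + counts[[s]]
  }
  out <- fold_of[subject_ids]
  names(out) <- NULL
  attr(out, "subject_folds") <- fold_of
  out
}
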