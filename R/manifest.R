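# Dataset bookkeeping: subjects, severities, train/test partition, step counts.

#' Default dataset manifest
#'
#' Five subjects walking a standardized 10-m protocol: each session (one per
#' condition, Pre and Post levodopa) comprises 8 runs of 150 steps, i.e.
#' 1200 steps per session. Three subjects (two mild, one severe) form the
#' training partition and two (one mild, one severe) the test partition, so
#' the training tables hold 3600 steps per condition and the test tables
#' 2400.
#'
#' @param n_train,n_test Subjects per partition.
#' @param runs_per_session,steps_per_run Session structure.
#' @param severities Severity labels, recycled over subjects (defaults give
#'   mild/mild/severe training and mild/severe test subjects).
#' @return A data.frame of class `wo_manifest` with one row per subject:
#'   `subject_id`, `severity`, `partition`, `runs_per_session`,
#'   `steps_per_run`, `steps_per_session`.
#' @export
dataset_manifest <- function(n_train = 3L, n_test = 2L,
                             runs_per_session = 8L, steps_per_run = 150L,
                             severities = NULL) {
  n <- n_train + n_test
  if (is.null(severities)) {
    severities <- c(rep_len(c("mild", "mild", "severe"), n_train),
                    rep_len(c("mild", "severe"), n_test))
  }
  out <- data.frame(
    subject_id = sprintf("S%d", seq_len(n)),
    severity = rep_len(severities, n),
    partition = c(rep("train", n_train), rep("test", n_test)),
    runs_per_session = runs_per_session,
    steps_per_run = steps_per_run,
    steps_per_session = runs_per_session * steps_per_run,
    stringsAsFactors = FALSE)
  class(out) <- c("wo_manifest", "data.frame")
  out
}

#' Validate a dataset manifest
#'
#' Checks that the train and test subject sets are disjoint, that both
#' partitions are non-empty, and that the step-count arithmetic holds
#' (runs x steps/run = steps/session).
#'
#' @param manifest A [dataset_manifest()]-style data.frame.
#' @return Invisibly, a list with `steps_per_condition` (named by partition)
#'   and `n_subjects`; errors on a hard violation.
#' @export
validate_manifest <- function(manifest) {
  req <- c("subject_id", "partition", "runs_per_session", "steps_per_run",
           "steps_per_session")
  miss <- setdiff(req, names(manifest))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  tr <- manifest$subject_id[manifest$partition == "train"]
  te <- manifest$subject_id[manifest$partition == "test"]
  if (length(intersect(tr, te))) {
    stop("train and test partitions overlap: ",
         paste(intersect(tr, te), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(manifest$subject_id)) {
    stop("duplicated subject ids in manifest", call. = FALSE)
  }
  bad <- manifest$runs_per_session * manifest$steps_per_run !=
    manifest$steps_per_session
  if (any(bad)) {
    stop("step-count arithmetic fails for: ",
         paste(manifest$subject_id[bad], collapse = ", "), call. = FALSE)
  }
  steps <- tapply(manifest$steps_per_session, manifest$partition, sum)
  invisible(list(steps_per_condition = steps,
                 n_subjects = nrow(manifest)))
}
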