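#' Read a cohort bundle from a directory of delimited files
#'
#' Expects the documented comma-separated UTF-8 files with header rows:
#' \code{admissions.csv}, \code{blood_cultures.csv} (one row per draw x
#' isolate, draw-level fields repeated; empty \code{organism_code} marks a
#' negative draw), \code{cvc_tip_cultures.csv}, \code{vitals.csv},
#' \code{commensals.txt} (one code per line) and optionally
#' \code{reference_labels.csv}. Timestamps are ISO-8601 at minute
#' resolution (\code{YYYY-MM-DDTHH:MM}). The returned bundle has passed all
#' structural invariants (see \code{\link{validate_bundle}}).
#'
#' @param directory_path directory containing the cohort files.
#' @return a validated \code{\link{cohort_bundle}}.
#' @export
read_cohort <- function(directory_path) {
  if (!dir.exists(directory_path)) {
    stop("cohort directory not found: ", directory_path, call. = FALSE)
  }
  p <- function(f) file.path(directory_path, f)
  for (f in c("admissions.csv", "blood_cultures.csv",
              "cvc_tip_cultures.csv", "vitals.csv", "commensals.txt")) {
    if (!file.exists(p(f))) {
      stop("missing cohort file: ", f, " in ", directory_path, call. = FALSE)
    }
  }
  rd <- function(f) utils::read.csv(p(f), colClasses = "character",
                                    na.strings = "", fileEncoding = "UTF-8")
  ref <- if (file.exists(p("reference_labels.csv"))) {
    rl <- rd("reference_labels.csv")
    rl$cvc_bsi <- rl$cvc_bsi %in% c("TRUE", "true", "1")
    rl$ha <- rl$ha %in% c("TRUE", "true", "1")
    rl
  } else NULL
  cohort_bundle(
    admissions = rd("admissions.csv"),
    blood_cultures = rd("blood_cultures.csv"),
    tip_cultures = rd("cvc_tip_cultures.csv"),
    vitals = rd("vitals.csv"),
    commensal_list = read_commensal_list(p("commensals.txt")),
    reference_labels = ref
  )
}

#' Write a cohort bundle to a directory of delimited files
#'
#' The inverse of \code{\link{read_cohort}}. Output is deterministic:
#' fixed column order, rows sorted by id then timestamp, LF line endings —
#' two writes of the same bundle are byte-identical, and
#' \code{read_cohort(write_cohort(b))} reproduces \code{b}. When the bundle
#' carries no reference labels, \code{reference_labels.csv} is omitted.
#'
#' @param bundle a validated \code{\link{cohort_bundle}}.
#' @param directory_path output directory (created if absent; parent must
#'   exist).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(bundle, directory_path) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!dir.exists(directory_path)) {
    ok <- dir.create(directory_path, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory_path, call. = FALSE)
  }
  p <- function(f) file.path(directory_path, f)
  wr <- function(d, f) {
    ts_cols <- names(d)[vapply(d, inherits, logical(1), "POSIXct")]
    for (cc in ts_cols) d[[cc]] <- format_ts(d[[cc]])
    con <- file(p(f), open = "wb")
    on.exit(close(con), add = TRUE)
    utils::write.csv(d, con, row.names = FALSE, na = "", eol = "\n",
                     quote = FALSE)
    f
  }
  adm <- bundle$admissions
  adm <- adm[order(adm$admission_id), , drop = FALSE]
  bc <- bundle$blood_cultures
  bc <- bc[order(bc$admission_id, bc$draw_ts, bc$draw_id,
                 bc$organism_code, na.last = FALSE, method = "radix"), ,
           drop = FALSE]
  tc <- bundle$tip_cultures
  tc <- tc[order(tc$admission_id, tc$collect_ts, tc$organism_code,
                 method = "radix"), , drop = FALSE]
  vt <- bundle$vitals
  vt <- vt[order(vt$admission_id, vt$obs_ts, vt$kind, method = "radix"), ,
           drop = FALSE]

  files <- c(wr(adm, "admissions.csv"),
             wr(bc, "blood_cultures.csv"),
             wr(tc, "cvc_tip_cultures.csv"),
             wr(vt, "vitals.csv"))
  writeLines(sort(bundle$commensal_list), p("commensals.txt"), sep = "\n")
  files <- c(files, "commensals.txt")
  if (!is.null(bundle$reference_labels)) {
    rl <- bundle$reference_labels
    rl <- rl[order(rl$episode_id, method = "radix"), , drop = FALSE]
    files <- c(files, wr(rl, "reference_labels.csv"))
  }
  invisible(p(files))
}

#' Write final episode labels to CSV
#'
#' One row per potential episode: \code{episode_id}, \code{admission_id},
#' \code{anchor_ts}, \code{variant}, \code{cvc_bsi}, \code{ha},
#' \code{suppressed_by_rit}, \code{index_episode_id} and the semicolon-
#' joined evidence tags — the audit trail that supports discrepancy review.
#'
#' @param labels label data.frame from \code{\link{run_surveillance}}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
write_episode_labels <- function(labels, path) {
  out <- labels
  out$anchor_ts <- format_ts(out$anchor_ts)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, na = "", eol = "\n",
                   quote = FALSE)
  invisible(path)
}

#' Read episode labels written by \code{write_episode_labels}
#' @param path CSV path.
#' @return data.frame of labels with parsed timestamps and logical flags.
#' @export
read_episode_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, colClasses = "character", na.strings = "")
  d$anchor_ts <- parse_ts(d$anchor_ts)
  for (cc in intersect(c("cvc_bsi", "ha", "suppressed_by_rit"), names(d))) {
    d[[cc]] <- d[[cc]] %in% c("TRUE", "true", "1")
  }
  d
}
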