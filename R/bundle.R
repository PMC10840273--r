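#' Assemble a validated cohort bundle
#'
#' A cohort bundle is the in-memory form of one surveillance extract: the
#' admission table plus its microbiology and vital-sign satellites and the
#' common-commensal organism list. Blood cultures are stored long, one row
#' per draw x isolate with the draw-level fields repeated; a negative draw
#' is a row whose \code{organism_code} is missing. Negative cultures are
#' explicit rows, not absent rows, because admissions with only negative
#' cultures form their own stratum in evaluation.
#'
#' @param admissions data.frame with columns \code{admission_id},
#'   \code{patient_id}, \code{admit_ts}, \code{discharge_ts} (POSIXct or
#'   ISO-8601 strings \code{YYYY-MM-DDTHH:MM}).
#' @param blood_cultures data.frame with columns \code{draw_id},
#'   \code{admission_id}, \code{draw_ts}, \code{site} (one of
#'   \code{"peripheral"}, \code{"central"}, \code{"unspecified"}),
#'   \code{organism_code} (NA or "" marks a negative draw),
#'   \code{ttp_hours} (time to positivity, hours; NA when not recorded).
#' @param tip_cultures data.frame with columns \code{admission_id},
#'   \code{collect_ts}, \code{organism_code}, \code{cfu_per_ml}.
#' @param vitals data.frame with columns \code{admission_id},
#'   \code{obs_ts}, \code{kind} (\code{"temperature"}, \code{"sbp"} or
#'   \code{"dbp"}), \code{value}.
#' @param commensal_list character vector of organism codes on the
#'   common-commensal list (see \code{\link{read_commensal_list}}).
#' @param reference_labels optional data.frame with columns
#'   \code{episode_id}, \code{cvc_bsi}, \code{ha} carrying per-episode
#'   reference labels for evaluation.
#' @return an object of class \code{cohort_bundle}.
#' @seealso \code{\link{read_cohort}}, \code{\link{write_cohort}},
#'   \code{\link{generate_cohort}}
#' @export
cohort_bundle <- function(admissions,
                          blood_cultures = empty_blood_cultures(),
                          tip_cultures = empty_tip_cultures(),
                          vitals = empty_vitals(),
                          commensal_list = default_commensal_list(),
                          reference_labels = NULL) {
  b <- list(
    admissions = coerce_admissions(admissions),
    blood_cultures = coerce_blood_cultures(blood_cultures),
    tip_cultures = coerce_tip_cultures(tip_cultures),
    vitals = coerce_vitals(vitals),
    commensal_list = norm_code(as.character(commensal_list)),
    reference_labels = if (is.null(reference_labels)) NULL else
      coerce_reference_labels(reference_labels)
  )
  class(b) <- "cohort_bundle"
  validate_bundle(b)
}

empty_blood_cultures <- function() {
  data.frame(draw_id = character(), admission_id = character(),
             draw_ts = as.POSIXct(character(), tz = "UTC"),
             site = character(), organism_code = character(),
             ttp_hours = numeric(), stringsAsFactors = FALSE)
}

empty_tip_cultures <- function() {
  data.frame(admission_id = character(),
             collect_ts = as.POSIXct(character(), tz = "UTC"),
             organism_code = character(), cfu_per_ml = numeric(),
             stringsAsFactors = FALSE)
}

empty_vitals <- function() {
  data.frame(admission_id = character(),
             obs_ts = as.POSIXct(character(), tz = "UTC"),
             kind = character(), value = numeric(),
             stringsAsFactors = FALSE)
}

as_ts_col <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    # truncate to minute resolution
    as.POSIXct(floor(as.numeric(x) / 60) * 60, origin = "1970-01-01",
               tz = "UTC")
  } else {
    parse_ts(as.character(x))
  }
}

coerce_admissions <- function(d) {
  need_cols(d, c("admission_id", "patient_id", "admit_ts", "discharge_ts"),
            "admissions")
  data.frame(admission_id = as.character(d$admission_id),
             patient_id = as.character(d$patient_id),
             admit_ts = as_ts_col(d$admit_ts),
             discharge_ts = as_ts_col(d$discharge_ts),
             stringsAsFactors = FALSE)
}

coerce_blood_cultures <- function(d) {
  need_cols(d, c("draw_id", "admission_id", "draw_ts", "site",
                 "organism_code", "ttp_hours"), "blood_cultures")
  org <- as.character(d$organism_code)
  org[!is.na(org) & trimws(org) == ""] <- NA_character_
  out <- data.frame(draw_id = as.character(d$draw_id),
                    admission_id = as.character(d$admission_id),
                    draw_ts = as_ts_col(d$draw_ts),
                    site = as.character(d$site),
                    organism_code = ifelse(is.na(org), NA_character_,
                                           norm_code(org)),
                    ttp_hours = as.numeric(d$ttp_hours),
                    stringsAsFactors = FALSE)
  # draw-level fields must agree across the rows of one draw
  key <- unique(out[c("draw_id", "admission_id", "draw_ts", "site")])
  if (anyDuplicated(key$draw_id)) {
    stop("draw_id with conflicting draw-level fields: ",
         paste(unique(key$draw_id[duplicated(key$draw_id)]),
               collapse = ", "), call. = FALSE)
  }
  # multiple bottles of one draw growing the same species collapse to one row
  out <- out[!duplicated(out[c("draw_id", "organism_code")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

coerce_tip_cultures <- function(d) {
  need_cols(d, c("admission_id", "collect_ts", "organism_code",
                 "cfu_per_ml"), "cvc_tip_cultures")
  data.frame(admission_id = as.character(d$admission_id),
             collect_ts = as_ts_col(d$collect_ts),
             organism_code = norm_code(as.character(d$organism_code)),
             cfu_per_ml = as.numeric(d$cfu_per_ml),
             stringsAsFactors = FALSE)
}

coerce_vitals <- function(d) {
  need_cols(d, c("admission_id", "obs_ts", "kind", "value"), "vitals")
  data.frame(admission_id = as.character(d$admission_id),
             obs_ts = as_ts_col(d$obs_ts),
             kind = as.character(d$kind),
             value = as.numeric(d$value),
             stringsAsFactors = FALSE)
}

coerce_reference_labels <- function(d) {
  need_cols(d, c("episode_id", "cvc_bsi", "ha"), "reference_labels")
  data.frame(episode_id = as.character(d$episode_id),
             cvc_bsi = as.logical(d$cvc_bsi),
             ha = as.logical(d$ha),
             stringsAsFactors = FALSE)
}

need_cols <- function(d, cols, what) {
  if (!is.data.frame(d)) stop(what, " must be a data.frame", call. = FALSE)
  miss <- setdiff(cols, names(d))
  if (length(miss)) {
    stop(what, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(d)
}

#' Validate a cohort bundle
#'
#' Checks the structural invariants of the bundle: every foreign key
#' resolves to an admission, draw ids are consistent (one timestamp, site
#' and admission per draw), a time to positivity implies a grown organism,
#' draws fall inside their admission interval, discharge does not precede
#' admission, vitals are finite and positive, and the commensal list is
#' non-empty.
#'
#' @param b a \code{cohort_bundle}.
#' @return the bundle, invisibly usable, after passing all checks.
#' @export
validate_bundle <- function(b) {
  stopifnot(inherits(b, "cohort_bundle"))
  adm <- b$admissions
  if (anyDuplicated(adm$admission_id)) {
    stop("duplicate admission_id: ",
         paste(unique(adm$admission_id[duplicated(adm$admission_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(is.na(adm$admit_ts)) || any(is.na(adm$discharge_ts))) {
    stop("admissions: missing admit/discharge timestamp", call. = FALSE)
  }
  bad <- adm$discharge_ts < adm$admit_ts
  if (any(bad)) {
    stop("admissions with discharge before admission: ",
         paste(adm$admission_id[bad], collapse = ", "), call. = FALSE)
  }

  bc <- b$blood_cultures
  check_fk(bc$admission_id, adm$admission_id, "blood_cultures")
  # one draw = one (admission, timestamp, site)
  if (nrow(bc)) {
    key <- unique(bc[c("draw_id", "admission_id", "draw_ts", "site")])
    if (anyDuplicated(key$draw_id)) {
      stop("draw_id with conflicting draw-level fields: ",
           paste(unique(key$draw_id[duplicated(key$draw_id)]),
                 collapse = ", "), call. = FALSE)
    }
    if (!all(bc$site %in% c("peripheral", "central", "unspecified"))) {
      stop("blood_cultures: site must be peripheral/central/unspecified",
           call. = FALSE)
    }
    orphan_ttp <- !is.na(bc$ttp_hours) & is.na(bc$organism_code)
    if (any(orphan_ttp)) {
      stop("blood_cultures: ttp_hours recorded on negative draw(s): ",
           paste(unique(bc$draw_id[orphan_ttp]), collapse = ", "),
           call. = FALSE)
    }
    if (any(!is.na(bc$ttp_hours) & bc$ttp_hours < 0)) {
      stop("blood_cultures: negative ttp_hours", call. = FALSE)
    }
    idx <- match(bc$admission_id, adm$admission_id)
    outside <- bc$draw_ts < adm$admit_ts[idx] |
      bc$draw_ts > adm$discharge_ts[idx]
    if (any(outside)) {
      stop("blood culture draw outside its admission interval: ",
           paste(unique(bc$draw_id[outside]), collapse = ", "),
           call. = FALSE)
    }
  }

  tc <- b$tip_cultures
  check_fk(tc$admission_id, adm$admission_id, "cvc_tip_cultures")
  if (any(tc$cfu_per_ml < 0)) {
    stop("cvc_tip_cultures: negative cfu_per_ml", call. = FALSE)
  }

  vt <- b$vitals
  check_fk(vt$admission_id, adm$admission_id, "vitals")
  if (nrow(vt)) {
    if (!all(vt$kind %in% c("temperature", "sbp", "dbp"))) {
      stop("vitals: kind must be temperature/sbp/dbp", call. = FALSE)
    }
    if (any(!is.finite(vt$value) | vt$value <= 0)) {
      stop("vitals: values must be finite and positive", call. = FALSE)
    }
  }

  if (!length(b$commensal_list)) {
    stop("commensal list must be non-empty", call. = FALSE)
  }
  b
}

check_fk <- function(keys, universe, what) {
  dangling <- setdiff(unique(keys), universe)
  if (length(dangling)) {
    stop(what, ": admission_id not found in admissions: ",
         paste(utils::head(dangling, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  n_draws <- length(unique(x$blood_cultures$draw_id))
  pos <- unique(x$blood_cultures$draw_id[!is.na(x$blood_cultures$organism_code)])
  cat("cohort_bundle:",
      nrow(x$admissions), "admissions,",
      n_draws, "blood-culture draws (", length(pos), "positive ),",
      nrow(x$tip_cultures), "tip cultures,",
      nrow(x$vitals), "vital observations\n")
  if (!is.null(x$reference_labels)) {
    cat("  reference labels:", nrow(x$reference_labels), "episodes,",
        sum(x$reference_labels$cvc_bsi), "CVC-BSI\n")
  }
  invisible(x)
}

# Per-draw view of the long blood-culture table (one row per draw).
draw_table <- function(bc) {
  if (!nrow(bc)) {
    return(data.frame(draw_id = character(), admission_id = character(),
                      draw_ts = as.POSIXct(character(), tz = "UTC"),
                      site = character(), positive = logical(),
                      stringsAsFactors = FALSE))
  }
  d <- bc[!duplicated(bc$draw_id),
          c("draw_id", "admission_id", "draw_ts", "site")]
  pos_ids <- unique(bc$draw_id[!is.na(bc$organism_code)])
  d$positive <- d$draw_id %in% pos_ids
  d <- d[order(d$admission_id, d$draw_ts, d$draw_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}
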