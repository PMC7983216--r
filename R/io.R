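#' Write a plan bundle to JSON
#'
#' The interchange format for one plan: prescriptions, provenance, and one
#' object per structure with its dose grid (Gy) and cumulative volumes in
#' percent.
#'
#' @param plan A [plan_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plan_bundle <- function(plan, path) {
  if (!inherits(plan, "plan_record")) stop("expected a 'plan_record'",
                                           call. = FALSE)
  obj <- list(
    format = "kbplanr-plan-v1",
    patient_id = plan$patient_id,
    provenance = plan$provenance,
    prescriptions_gy = as.list(plan$prescriptions),
    structures = lapply(plan$curves, function(cv) list(
      structure = cv$structure_name,
      volume_cc = cv$volume_cc,
      dose_gy = cv$dose_gy,
      volume_pct = 100 * cv$rel_volume)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a plan bundle written by [write_plan_bundle()]
#'
#' Curves are validated on read: volumes are normalized from percent to
#' fractions, sub-1e-9 monotonicity glitches are repaired silently, larger
#' violations are rejected with the offending structure named.
#'
#' @param path JSON plan bundle.
#' @return A [plan_record()].
#' @export
read_plan_bundle <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "kbplanr-plan-v1")) {
    stop(sprintf("'%s' is not a kbplanr plan bundle (missing format tag)",
                 path), call. = FALSE)
  }
  curves <- lapply(obj$structures, function(s) {
    dvh_curve(s$structure, s$volume_cc, as.numeric(s$dose_gy),
              as.numeric(s$volume_pct) / 100)
  })
  names(curves) <- vapply(obj$structures, function(s) s$structure, character(1))
  plan_record(obj$patient_id, curves,
              unlist(obj$prescriptions_gy),
              provenance = obj$provenance)
}

#' Export one DVH curve as CSV
#'
#' Format: comment header lines `# structure=<name>` and `# volume_cc=<v>`,
#' then columns `dose_gy,volume_pct` (cumulative, percent).
#'
#' @param curve A [dvh_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(curve, path) {
  assert_dvh_curve(curve)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# structure=%s", curve$structure_name),
               sprintf("# volume_cc=%.6g", curve$volume_cc),
               "dose_gy,volume_pct"), con)
  utils::write.table(
    data.frame(dose_gy = curve$dose_gy, volume_pct = 100 * curve$rel_volume),
    con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a DVH CSV written by [write_dvh_csv()]
#'
#' @param path CSV file with `# structure=` / `# volume_cc=` headers.
#' @return A [dvh_curve()].
#' @export
read_dvh_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    hit <- grep(sprintf("^#\\s*%s=", key), hdr, value = TRUE)
    if (!length(hit)) stop(sprintf("missing '# %s=' header in %s", key, path),
                           call. = FALSE)
    sub(sprintf("^#\\s*%s=", key), "", hit[1L])
  }
  structure_name <- get_field("structure")
  volume_cc <- as.numeric(get_field("volume_cc"))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!all(c("dose_gy", "volume_pct") %in% names(df))) {
    stop(sprintf("expected columns dose_gy,volume_pct in %s", path),
         call. = FALSE)
  }
  dvh_curve(structure_name, volume_cc, df$dose_gy, df$volume_pct / 100)
}

criterion_to_list <- function(cr) {
  out <- list(id = cr$id, structure = cr$structure,
              direction = cr$direction, max_points = cr$max_points,
              mode = cr$mode)
  if (cr$mode == "threshold") {
    out$metric <- list(kind = cr$metric$kind)
    if (length(cr$metric$parameter) && is.finite(cr$metric$parameter)) {
      out$metric$parameter <- cr$metric$parameter
    }
    out$acceptable <- cr$acceptable
    out$excellent <- cr$excellent
  } else {
    out$metric <- cr$metric
  }
  out
}

criterion_from_list <- function(x) {
  metric <- if (is.list(x$metric)) {
    dose_metric(x$metric$kind,
                if (is.null(x$metric$parameter)) NA_real_
                else x$metric$parameter)
  } else {
    x$metric
  }
  criterion(x$structure, metric, x$direction,
            acceptable = if (is.null(x$acceptable)) NA_real_ else x$acceptable,
            excellent = if (is.null(x$excellent)) NA_real_ else x$excellent,
            max_points = x$max_points, mode = x$mode, id = x$id)
}

#' Write a criteria set to YAML (or JSON)
#'
#' @param set A [criteria_set()].
#' @param path Output path; `.json` extension selects JSON, anything else
#'   YAML.
#' @return `path`, invisibly.
#' @export
write_criteria <- function(set, path) {
  if (!inherits(set, "criteria_set")) stop("expected a 'criteria_set'",
                                           call. = FALSE)
  obj <- list(name = set$name,
              criteria = lapply(set$criteria, criterion_to_list))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' Read a criteria set written by [write_criteria()]
#'
#' @param path YAML or JSON criteria file.
#' @return A [criteria_set()].
#' @export
read_criteria <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  criteria_set(obj$name, lapply(obj$criteria, criterion_from_list))
}

#' Serialize a PQM report to JSON
#'
#' @param report A `pqm_report` from [score_plan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(report, path) {
  if (!inherits(report, "pqm_report")) stop("expected a 'pqm_report'",
                                            call. = FALSE)
  obj <- list(patient_id = report$patient_id, total = report$total,
              per_criterion = report$per_criterion)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}
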