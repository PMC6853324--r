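#' Assemble a longitudinal ART cohort table
#'
#' A cohort table is the single input currency of the analysis pipeline: a
#' long-format table of patient visits (one row per visit) together with a
#' per-patient table of baseline covariates.
#'
#' @param visits data.frame with columns `patient_id`, `time_on_art` (years
#'   since ART start, baseline visit at 0), `cd4` (cells/uL, `NA` allowed),
#'   `viral_load` (copies/mL, `NA` allowed) and optionally `first_line`
#'   (logical, default `TRUE`).
#' @param baselines data.frame with columns `patient_id`, `sex` (0 = male,
#'   1 = female, `NA` allowed), `age` (years), `baseline_cd4` (cells/uL),
#'   `baseline_log_vl` (log10 copies/mL) and `in_care` (0 = lost to
#'   follow-up, 1 = in care; never missing).
#' @param require_baseline enforce that every patient's first visit is at
#'   `time_on_art == 0`.
#'
#' @return An object of class `cd4_cohort`: a list with elements `visits`,
#'   `baselines` and `standardization` (`NULL` until
#'   [standardize_covariates()] is applied).
#' @seealso [read_cohort()], [apply_exclusions()], [standardize_covariates()]
#' @export
cohort_table <- function(visits, baselines, require_baseline = TRUE) {
  visits <- as.data.frame(visits)
  baselines <- as.data.frame(baselines)
  need_v <- c("patient_id", "time_on_art", "cd4", "viral_load")
  need_b <- c("patient_id", "sex", "age", "baseline_cd4", "baseline_log_vl",
              "in_care")
  miss <- setdiff(need_v, names(visits))
  if (length(miss))
    stop("visits table is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(need_b, names(baselines))
  if (length(miss))
    stop("baselines table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"first_line" %in% names(visits)) visits$first_line <- TRUE
  visits$patient_id <- as.character(visits$patient_id)
  baselines$patient_id <- as.character(baselines$patient_id)
  visits$first_line <- as.logical(visits$first_line)

  if (anyDuplicated(baselines$patient_id))
    stop("duplicated patient_id in baselines table")
  orphan <- setdiff(visits$patient_id, baselines$patient_id)
  if (length(orphan))
    stop("visits reference patient_id(s) with no baseline row: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  if (anyDuplicated(visits[c("patient_id", "time_on_art")]))
    stop("duplicate (patient_id, time_on_art) pair in visits table")
  if (any(is.na(baselines$in_care)))
    stop("in_care must never be missing")
  if (any(visits$time_on_art < 0, na.rm = TRUE))
    stop("time_on_art must be >= 0")
  vl <- visits$viral_load
  if (any(vl <= 0, na.rm = TRUE))
    stop("viral_load must be positive (copies/mL) or missing")

  visits <- visits[order(visits$patient_id, visits$time_on_art), , drop = FALSE]
  rownames(visits) <- NULL
  if (require_baseline) {
    first_t <- tapply(visits$time_on_art, visits$patient_id, min)
    bad <- names(first_t)[first_t != 0]
    if (length(bad))
      stop("patient(s) without a baseline (time_on_art = 0) visit: ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(visits = visits, baselines = baselines,
                 standardization = NULL),
            class = "cd4_cohort")
}

#' @export
print.cd4_cohort <- function(x, ...) {
  cat("ART cohort:", nrow(x$baselines), "patients,",
      nrow(x$visits), "visits\n")
  nmis <- c(cd4 = sum(is.na(x$visits$cd4)),
            viral_load = sum(is.na(x$visits$viral_load)),
            sex = sum(is.na(x$baselines$sex)),
            baseline_cd4 = sum(is.na(x$baselines$baseline_cd4)),
            baseline_log_vl = sum(is.na(x$baselines$baseline_log_vl)))
  cat("missing cells:",
      paste(names(nmis), nmis, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$standardization)) {
    cat("standardized covariates:",
        paste(x$standardization$covariate, collapse = ", "),
        sprintf("(%s sd)\n", attr(x$standardization, "method")))
  }
  invisible(x)
}

#' Read a longitudinal cohort from delimited text
#'
#' Reads a long-format visit file (and optionally a separate baseline file)
#' into a [cohort_table()]. Missing CD4/viral-load/covariate cells are kept
#' as `NA`, never dropped; rows whose required keys (`patient_id`,
#' `time_on_art`) cannot be parsed are rejected and reported.
#'
#' @param path delimited text file with a header; one row per visit. When
#'   `baseline_path` is `NULL` the baseline columns must be repeated on the
#'   visit rows.
#' @param baseline_path optional separate per-patient baseline file.
#' @param mapping named character vector/list mapping canonical column names
#'   (`patient_id`, `time_on_art`, `cd4`, `viral_load`, `first_line`, `sex`,
#'   `age`, `baseline_cd4`, `baseline_log_vl`, `in_care`) to the column
#'   names used in the file(s). Unmapped names are taken verbatim.
#' @param sep field separator; `","` (default) or `"\t"` etc.
#' @param na_strings tokens to treat as a missing cell (default the empty
#'   string and `"NA"`).
#' @return A `cd4_cohort`; the per-row rejection report (if any) is attached
#'   as attribute `"rejected"`.
#' @export
read_cohort <- function(path, baseline_path = NULL, mapping = NULL,
                        sep = ",", na_strings = c("", "NA")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = na_strings, stringsAsFactors = FALSE,
                           check.names = FALSE)
  map <- function(canon) {
    if (!is.null(mapping) && canon %in% names(mapping))
      as.character(mapping[[canon]]) else canon
  }
  pick <- function(df, canon, required = TRUE) {
    col <- map(canon)
    if (!col %in% names(df)) {
      if (required) stop("required column '", canon, "' (file column '",
                         col, "') not found")
      return(NULL)
    }
    df[[col]]
  }

  visits <- data.frame(patient_id = as.character(pick(raw, "patient_id")),
                       time_on_art = suppressWarnings(
                         as.numeric(pick(raw, "time_on_art"))),
                       cd4 = suppressWarnings(as.numeric(pick(raw, "cd4"))),
                       viral_load = suppressWarnings(
                         as.numeric(pick(raw, "viral_load"))),
                       stringsAsFactors = FALSE)
  fl <- pick(raw, "first_line", required = FALSE)
  visits$first_line <- if (is.null(fl)) TRUE else as.logical(fl)

  # rows with an unparseable key cannot be analysed; report, don't silently drop
  bad <- is.na(visits$patient_id) | visits$patient_id == "" |
    is.na(visits$time_on_art)
  rejected <- NULL
  if (any(bad)) {
    rejected <- data.frame(row = which(bad),
                           reason = "unparseable patient_id/time_on_art")
    warning(sum(bad), " visit row(s) rejected (unparseable key)")
    visits <- visits[!bad, , drop = FALSE]
  }

  braw <- if (is.null(baseline_path)) raw else {
    if (!file.exists(baseline_path)) stop("file not found: ", baseline_path)
    utils::read.table(baseline_path, header = TRUE, sep = sep,
                      na.strings = na_strings, stringsAsFactors = FALSE,
                      check.names = FALSE)
  }
  baselines <- data.frame(patient_id = as.character(pick(braw, "patient_id")),
                          sex = suppressWarnings(as.numeric(pick(braw, "sex"))),
                          age = suppressWarnings(as.numeric(pick(braw, "age"))),
                          baseline_cd4 = suppressWarnings(
                            as.numeric(pick(braw, "baseline_cd4"))),
                          baseline_log_vl = suppressWarnings(
                            as.numeric(pick(braw, "baseline_log_vl"))),
                          in_care = suppressWarnings(
                            as.numeric(pick(braw, "in_care"))),
                          stringsAsFactors = FALSE)
  baselines <- baselines[!duplicated(baselines$patient_id), , drop = FALSE]

  out <- cohort_table(visits, baselines)
  attr(out, "rejected") <- rejected
  out
}

#' Write a cohort to delimited text
#'
#' The inverse of [read_cohort()]: writes the visit rows with the baseline
#' columns repeated, so that `read_cohort(write_cohort(x))` round-trips.
#' Missing cells are written as empty strings.
#'
#' @param cohort a `cd4_cohort`.
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  stopifnot(inherits(cohort, "cd4_cohort"))
  merged <- merge(cohort$visits, cohort$baselines, by = "patient_id",
                  sort = FALSE)
  merged <- merged[order(merged$patient_id, merged$time_on_art), , drop = FALSE]
  utils::write.table(merged, path, sep = sep, row.names = FALSE, na = "",
                     quote = FALSE)
  invisible(path)
}

#' Apply the analysis exclusion filters
#'
#' Removes, in order: (a) visits not on first-line ART; (b) patients left
#' with only a baseline visit (cVL2 cannot be computed for them); and, for
#' the asymptote (CD4 >= 500) outcome only, (c) patients with baseline CD4
#' >= 500 cells/uL. Returns the filtered cohort with an exclusion report
#' attached.
#'
#' @param cohort a `cd4_cohort`.
#' @param outcome `"slope"` or `"asymptote"`.
#' @return The filtered `cd4_cohort`; the report (class
#'   `cd4_exclusion_report`) is attached as attribute `"exclusions"`.
#' @export
apply_exclusions <- function(cohort, outcome = c("slope", "asymptote")) {
  stopifnot(inherits(cohort, "cd4_cohort"))
  outcome <- match.arg(outcome)
  visits <- cohort$visits
  baselines <- cohort$baselines
  n_input <- nrow(baselines)

  n_second_line <- sum(!visits$first_line)
  visits <- visits[visits$first_line, , drop = FALSE]

  nvis <- table(visits$patient_id)
  baseline_only <- names(nvis)[nvis < 2]
  baseline_only <- union(baseline_only,
                         setdiff(baselines$patient_id, names(nvis)))
  visits <- visits[!visits$patient_id %in% baseline_only, , drop = FALSE]

  high_cd4 <- character(0)
  if (outcome == "asymptote") {
    keep_ids <- setdiff(baselines$patient_id, baseline_only)
    b <- baselines[baselines$patient_id %in% keep_ids, , drop = FALSE]
    high_cd4 <- b$patient_id[!is.na(b$baseline_cd4) & b$baseline_cd4 >= 500]
    visits <- visits[!visits$patient_id %in% high_cd4, , drop = FALSE]
  }

  retained <- unique(visits$patient_id)
  if (length(retained) == 0L)
    stop("no patients remain after exclusions")
  baselines <- baselines[baselines$patient_id %in% retained, , drop = FALSE]

  out <- cohort_table(visits, baselines)
  out$standardization <- cohort$standardization
  report <- structure(
    list(n_input = n_input, n_retained = length(retained),
         n_second_line_visits = n_second_line,
         reasons = data.frame(
           reason = c("baseline-only", "baseline-cd4-ge-500"),
           n_patients = c(length(baseline_only), length(high_cd4))),
         excluded = list(`baseline-only` = baseline_only,
                         `baseline-cd4-ge-500` = high_cd4),
         outcome = outcome),
    class = "cd4_exclusion_report")
  attr(out, "exclusions") <- report
  out
}

#' @export
print.cd4_exclusion_report <- function(x, ...) {
  cat("Exclusions (", x$outcome, " outcome): ", x$n_input, " patients in, ",
      x$n_retained, " retained\n", sep = "")
  for (i in seq_len(nrow(x$reasons)))
    cat(sprintf("  %-22s %d patients\n", x$reasons$reason[i],
                x$reasons$n_patients[i]))
  cat("  second-line visits removed:", x$n_second_line_visits, "\n")
  invisible(x)
}

#' Standardize continuous baseline covariates
#'
#' z-scores `age`, `baseline_cd4` and `baseline_log_vl` on the post-exclusion
#' analysis sample, using the observed (non-missing) values. Time on
#' treatment is deliberately left on its natural scale (years). The
#' transform parameters are stored on the cohort so that estimates can be
#' back-transformed and new data standardized consistently.
#'
#' @param cohort a `cd4_cohort` (exclusions already applied).
#' @param covariates covariate names to standardize.
#' @param method `"sample"` (n-1 denominator, the default) or `"population"`
#'   (n denominator).
#' @return The cohort with transformed baseline columns and a
#'   `standardization` data.frame (covariate, mean, sd) recording the
#'   transform and the sd convention used.
#' @export
standardize_covariates <- function(cohort,
                                   covariates = c("age", "baseline_cd4",
                                                  "baseline_log_vl"),
                                   method = c("sample", "population")) {
  stopifnot(inherits(cohort, "cd4_cohort"))
  method <- match.arg(method)
  if (!is.null(cohort$standardization))
    stop("covariates are already standardized")
  b <- cohort$baselines
  info <- data.frame(covariate = covariates, mean = NA_real_, sd = NA_real_)
  for (i in seq_along(covariates)) {
    cv <- covariates[i]
    if (!cv %in% names(b)) stop("unknown covariate: ", cv)
    x <- b[[cv]]
    obs <- x[!is.na(x)]
    if (length(obs) < 2L) stop("fewer than 2 observed values for ", cv)
    m <- mean(obs)
    s <- if (method == "sample") stats::sd(obs) else
      sqrt(mean((obs - m)^2))
    if (!is.finite(s) || s <= 0)
      stop("zero variance in covariate ", cv)
    b[[cv]] <- (x - m) / s
    info$mean[i] <- m
    info$sd[i] <- s
  }
  attr(info, "method") <- method
  cohort$baselines <- b
  cohort$standardization <- info
  cohort
}

# back-transform helper: raw value of a standardized covariate
unstandardize <- function(cohort, covariate, z) {
  info <- cohort$standardization
  if (is.null(info) || !covariate %in% info$covariate) return(z)
  i <- match(covariate, info$covariate)
  z * info$sd[i] + info$mean[i]
}
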