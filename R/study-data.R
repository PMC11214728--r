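#' Construct a longitudinal study dataset
#'
#' Normalises a long-format data frame (one row per subject-occasion) into the
#' canonical representation used throughout memlong. Main-study data carry the
#' outcome `Y` and the surrogate exposure `C`; validation-study data carry the
#' surrogate `C` and the true exposure `c` (and, for an internal validation
#' study, the subjects also appear in the main study).
#'
#' Two time scales are always carried: `t_outcome`, the time scale of the
#' outcome model (e.g. time since baseline), and `t_mem`, the time scale of
#' the measurement error model (e.g. age). When only one is supplied it is
#' copied into both and a message records this.
#'
#' @param data A data frame in long format, one row per subject-occasion.
#' @param role `"main"` or `"validation"`.
#' @param id,t_outcome,t_mem,surrogate,true_exposure,outcome,present Column
#'   names (strings) in `data`. `t_mem`, `true_exposure`, `outcome` and
#'   `present` are optional; `present` defaults to `TRUE` everywhere.
#' @param covariates Character vector of covariate (`W`) column names; may be
#'   empty. Order is preserved and defines the order of covariate terms.
#'
#' @return A tibble of class `memlong_study` with canonical columns `.id`,
#'   `.t_out`, `.t_mem`, `.C`, `.c`, `.y`, `.present` plus the covariate
#'   columns, sorted by subject and outcome time, with attributes `role` and
#'   `covariates`.
#'
#' @examples
#' d <- data.frame(id = rep(1:2, each = 3), t = rep(0:2, 2),
#'                 C = rnorm(6), y = rnorm(6))
#' study_data(d, role = "main", id = "id", t_outcome = "t",
#'            surrogate = "C", outcome = "y")
#' @export
study_data <- function(data, role = c("main", "validation"),
                       id = "id", t_outcome = "t_outcome", t_mem = NULL,
                       surrogate = "surrogate", true_exposure = NULL,
                       outcome = NULL, covariates = character(),
                       present = NULL) {
  role <- match.arg(role)
  data <- tibble::as_tibble(data)

  need <- c(id, t_outcome, surrogate, t_mem, true_exposure, outcome,
            covariates, present)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("columns not found in `data`: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (role == "validation" && is.null(true_exposure)) {
    stop("validation data require a `true_exposure` column", call. = FALSE)
  }

  out <- tibble::tibble(
    .id = as.character(data[[id]]),
    .t_out = as.numeric(data[[t_outcome]]),
    .C = as.numeric(data[[surrogate]])
  )
  if (is.null(t_mem)) {
    out$.t_mem <- out$.t_out
    message("single time column supplied; using `", t_outcome,
            "` for both the outcome-model and MEM time scales")
  } else {
    out$.t_mem <- as.numeric(data[[t_mem]])
  }
  out$.c <- if (is.null(true_exposure)) NA_real_ else
    as.numeric(data[[true_exposure]])
  out$.y <- if (is.null(outcome)) NA_real_ else as.numeric(data[[outcome]])
  out$.present <- if (is.null(present)) TRUE else as.logical(data[[present]])
  for (w in covariates) out[[w]] <- as.numeric(data[[w]])

  out <- dplyr::arrange(out, .data$.id, .data$.t_out)

  dup <- duplicated(out[, c(".id", ".t_out")])
  if (any(dup)) {
    stop("duplicate (subject, outcome time) pairs, e.g. subject ",
         out$.id[which(dup)[1]], " at t = ", out$.t_out[which(dup)[1]],
         call. = FALSE)
  }
  if (role == "validation" && anyNA(out$.c[out$.present])) {
    stop("validation data have missing true exposure on present records",
         call. = FALSE)
  }
  if (anyNA(out$.C[out$.present]) && anyNA(out$.c[out$.present])) {
    bad <- out$.present & is.na(out$.C) & is.na(out$.c)
    if (any(bad)) {
      stop("present records must have at least one of surrogate or true ",
           "exposure non-missing", call. = FALSE)
    }
  }

  structure(out,
            class = c("memlong_study", class(tibble::tibble())),
            role = role, covariates = covariates)
}

#' @export
print.memlong_study <- function(x, ...) {
  cat("<memlong_study> role:", study_role(x),
      "| subjects:", dplyr::n_distinct(x$.id),
      "| records:", nrow(x), "\n")
  if (length(study_covariates(x)) > 0) {
    cat("covariates:", paste(study_covariates(x), collapse = ", "), "\n")
  }
  NextMethod()
}

study_role <- function(x) attr(x, "role")
study_covariates <- function(x) attr(x, "covariates") %||% character()

# dplyr verbs drop custom attributes; re-attach when subsetting internally
restudy <- function(x, template) {
  structure(tibble::as_tibble(x),
            class = class(template),
            role = study_role(template),
            covariates = study_covariates(template))
}

#' Check the id-set relation between a main study and its validation study
#'
#' Under an internal validation study (IVS) every validation subject must also
#' appear in the main study; under an external validation study (EVS) the two
#' id sets must be disjoint.
#'
#' @param ms,vs `memlong_study` objects with roles `"main"` and `"validation"`.
#' @param design `"ivs"` or `"evs"`.
#' @return Invisibly `TRUE`; violations raise an error.
#' @export
check_design <- function(ms, vs, design = c("evs", "ivs")) {
  design <- match.arg(design)
  ids_ms <- unique(ms$.id)
  ids_vs <- unique(vs$.id)
  if (design == "ivs" && !all(ids_vs %in% ids_ms)) {
    stop("IVS design requires every validation subject to appear in the ",
         "main study; ", sum(!(ids_vs %in% ids_ms)), " do not", call. = FALSE)
  }
  if (design == "evs" && length(intersect(ids_ms, ids_vs)) > 0) {
    stop("EVS design requires disjoint main/validation subject ids; ",
         length(intersect(ids_ms, ids_vs)), " overlap", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a long-format study table from CSV
#'
#' @param path Path to a CSV file with a header row. Missing numeric cells may
#'   be empty or `"NA"`.
#' @param role `"main"` or `"validation"`.
#' @param column_map Named list or vector mapping canonical field names
#'   (`id`, `t_outcome`, `t_mem`, `surrogate`, `true_exposure`, `outcome`,
#'   `present`, `covariates`) to column names in the file. Only `id`,
#'   `t_outcome` and `surrogate` are required.
#' @return A [study_data()] tibble.
#' @export
read_study <- function(path, role = c("main", "validation"),
                       column_map = list()) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cm <- as.list(column_map)
  defaults <- list(id = "id", t_outcome = "t_outcome", t_mem = NULL,
                   surrogate = "surrogate", true_exposure = NULL,
                   outcome = NULL, present = NULL, covariates = character())
  for (nm in names(defaults)) if (is.null(cm[[nm]])) cm[[nm]] <- defaults[[nm]]
  raw <- readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE,
                         progress = FALSE)
  study_data(raw, role = role, id = cm$id, t_outcome = cm$t_outcome,
             t_mem = cm$t_mem, surrogate = cm$surrogate,
             true_exposure = cm$true_exposure, outcome = cm$outcome,
             covariates = cm$covariates, present = cm$present)
}

#' Write a coefficient report for a fitted model
#'
#' Writes a machine-readable CSV of coefficient names, estimates, sandwich
#' standard errors and 95% Wald confidence intervals
#' (estimate +/- 1.96 * SE). Estimates are written at full double precision so
#' that [read_fit_report()] reproduces them bit-exactly.
#'
#' @param fit A `memlong_fit` (corrected), `memlong_gee` (naive) or
#'   `memlong_mem` object.
#' @param path Output file path.
#' @return Invisibly, the tibble that was written.
#' @export
write_fit_report <- function(fit, path) {
  tab <- generics::tidy(fit, conf.int = TRUE)
  out <- tab
  # %.17g round-trips IEEE doubles exactly through the text file
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  readr::write_csv(out, path)
  invisible(tab)
}

#' Read back a coefficient report written by [write_fit_report()]
#'
#' @param path Path to the report CSV.
#' @return A tibble with columns `stage`, `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
read_fit_report <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  num <- setdiff(names(raw), c("stage", "term"))
  # base-R parsing restores the exact doubles written by %.17g
  raw[num] <- lapply(raw[num], as.numeric)
  raw
}
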