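#' Construct a set of trial-level summaries
#'
#' A trial set holds, for each historical randomized trial, the per-arm sample
#' sizes together with the per-arm biomarker responder counts (`b_t`, `b_c`)
#' and clinical-endpoint responder counts (`x_t`, `x_c`). Endpoint counts may
#' be `NA` for a new (unpredicted) trial whose clinical follow-up is not yet
#' complete.
#'
#' @param trial_id character or integer identifiers, one per trial.
#' @param n_t,n_c per-arm sample sizes (treatment, control); positive integers.
#' @param b_t,b_c biomarker responder counts per arm.
#' @param x_t,x_c clinical-endpoint responder counts per arm, or `NA` for a
#'   trial whose endpoint is unobserved.
#' @return A `data.frame` of class `"trial_set"` with columns
#'   `trial_id, n_t, n_c, b_t, b_c, x_t, x_c`.
#' @examples
#' trial_set(trial_id = 1:2, n_t = c(100, 100), n_c = c(100, 100),
#'           b_t = c(4, 9), b_c = c(20, 30), x_t = c(1, 2), x_c = c(5, 8))
#' @export
trial_set <- function(trial_id, n_t, n_c, b_t, b_c, x_t = NA, x_c = NA) {
  df <- data.frame(trial_id = trial_id, n_t = n_t, n_c = n_c,
                   b_t = b_t, b_c = b_c, x_t = x_t, x_c = x_c,
                   stringsAsFactors = FALSE)
  validate_trials(df)
}

#' Validate a trial-level summary table
#'
#' Checks the count invariants of a trial table: all counts integral and
#' non-negative, `0 <= b_t <= n_t`, `0 <= b_c <= n_c`, and the same for the
#' endpoint counts where observed; `n_t > 0` and `n_c > 0`. Rows violating an
#' invariant are reported with their row index and `trial_id`.
#'
#' @param trials a `data.frame` with columns
#'   `trial_id, n_t, n_c, b_t, b_c, x_t, x_c`.
#' @return The validated table, classed `"trial_set"`, with derived totals
#'   `b = b_t + b_c` and `x = x_t + x_c` attached as columns.
#' @export
validate_trials <- function(trials) {
  required <- c("trial_id", "n_t", "n_c", "b_t", "b_c", "x_t", "x_c")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0L) {
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trials <- as.data.frame(trials)[required]

  is_count <- function(v) {
    !is.na(v) & is.finite(v) & v >= 0 & abs(v - round(v)) < 1e-8
  }
  problems <- character(0)
  note <- function(rows, what) {
    if (any(rows)) {
      ids <- trials$trial_id[rows]
      problems <<- c(problems, sprintf(
        "row %d (trial_id %s): %s", which(rows), as.character(ids), what))
    }
  }
  note(!is_count(trials$n_t) | trials$n_t <= 0, "n_t must be a positive integer")
  note(!is_count(trials$n_c) | trials$n_c <= 0, "n_c must be a positive integer")
  note(!is_count(trials$b_t), "b_t must be a non-negative integer")
  note(!is_count(trials$b_c), "b_c must be a non-negative integer")
  # endpoint counts may be jointly NA (new trial); otherwise both are counts
  x_na <- is.na(trials$x_t) & is.na(trials$x_c)
  note(xor(is.na(trials$x_t), is.na(trials$x_c)),
       "x_t and x_c must be both observed or both NA")
  note(!x_na & !is_count(trials$x_t), "x_t must be a non-negative integer")
  note(!x_na & !is_count(trials$x_c), "x_c must be a non-negative integer")
  ok_n <- is_count(trials$n_t) & trials$n_t > 0 &
    is_count(trials$n_c) & trials$n_c > 0
  note(ok_n & is_count(trials$b_t) & trials$b_t > trials$n_t, "b_t exceeds n_t")
  note(ok_n & is_count(trials$b_c) & trials$b_c > trials$n_c, "b_c exceeds n_c")
  note(ok_n & !x_na & is_count(trials$x_t) & trials$x_t > trials$n_t,
       "x_t exceeds n_t")
  note(ok_n & !x_na & is_count(trials$x_c) & trials$x_c > trials$n_c,
       "x_c exceeds n_c")
  if (length(problems) > 0L) {
    stop("invalid trial table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }

  for (col in c("n_t", "n_c", "b_t", "b_c", "x_t", "x_c")) {
    trials[[col]] <- as.integer(round(trials[[col]]))
  }
  trials$b <- trials$b_t + trials$b_c
  trials$x <- trials$x_t + trials$x_c
  class(trials) <- c("trial_set", "data.frame")
  trials
}

#' Read trial-level summaries from a delimited file
#'
#' The file has one row per trial, a header naming the columns
#' `trial_id, n_t, n_c, b_t, b_c, x_t, x_c`, and comma or tab separators.
#'
#' @param path path to a CSV or TSV file.
#' @param format `"csv"` or `"tsv"`; by default guessed from the file
#'   extension (`.tsv`/`.tab` means tab, anything else comma).
#' @return A validated `"trial_set"` (possibly with zero rows).
#' @seealso [write_trials()], [example_trials()]
#' @export
read_trials <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  validate_trials(raw)
}

#' Write trial-level summaries to a delimited file
#'
#' @param trials a `"trial_set"` or compatible `data.frame`.
#' @param path output path.
#' @param format `"csv"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  trials <- validate_trials(trials)
  cols <- c("trial_id", "n_t", "n_c", "b_t", "b_c", "x_t", "x_c")
  utils::write.table(trials[cols], path, sep = if (format == "tsv") "\t" else ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged worked-example trials
#'
#' Five hypothetical placebo-controlled vaccine trials (1:1 allocation) with
#' per-arm virus-infection counts (the biomarker) and disease counts (the
#' clinical endpoint), plus the helper [example_new_trial()] giving the new
#' regional trial whose disease outcome is not yet observed. Trial 3 has an
#' odd total sample size (529); its arms are stored as 265/264.
#'
#' @return A `"trial_set"` with five rows.
#' @examples
#' example_trials()
#' @export
example_trials <- function() {
  path <- system.file("extdata", "example_vaccine_trials.csv",
                      package = "rrbridge", mustWork = TRUE)
  read_trials(path)
}

#' @rdname example_trials
#' @return For `example_new_trial()`: a one-row `"trial_set"` for the new
#'   trial (3606 subjects in two equal arms, infections 7 vaccine / 29
#'   placebo, disease unobserved).
#' @export
example_new_trial <- function() {
  trial_set(trial_id = "new", n_t = 1803, n_c = 1803, b_t = 7, b_c = 29)
}

#' Treatment-arm share of responders
#'
#' Estimates the proportion `phi` of responders belonging to the treatment
#' arm, `b_t / (b_t + R * b_c)`, where `R = n_t / n_c` is the sample-size
#' ratio of the two arms (R = 1 for 1:1 allocation). The same estimator
#' applies to biomarker counts (giving `phi_B`) and endpoint counts
#' (`phi_X`). Under allocation ratio `R`, `phi / (1 - phi)` equals the
#' between-arm rate ratio.
#'
#' @param b_t,b_c responder counts in the treatment and control arm.
#' @param R sample-size ratio treatment:control (default 1).
#' @return The estimated proportion, in `[0, 1]`.
#' @examples
#' phi_hat(7, 29)        # 7/36
#' phi_hat(10, 86)       # 10/96
#' @export
phi_hat <- function(b_t, b_c, R = 1) {
  stopifnot(length(R) == 1L, R > 0)
  if (any(b_t < 0 | b_c < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(b_t + b_c == 0)) {
    stop("undefined proportion: no responders in either arm (b_t + b_c = 0)",
         call. = FALSE)
  }
  b_t / (b_t + R * b_c)
}

#' Vaccine efficacy from a rate ratio
#'
#' `VE = 1 - RR`, where `RR` is the treatment:control rate ratio of the
#' clinical endpoint.
#'
#' @param rr rate ratio(s), non-negative.
#' @return `1 - rr`.
#' @examples
#' vaccine_efficacy(1/6)  # 83.3%
#' @export
vaccine_efficacy <- function(rr) {
  if (any(rr < 0, na.rm = TRUE)) stop("rate ratio must be >= 0", call. = FALSE)
  1 - rr
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("Trial-level summary data: %d trial(s)\n", nrow(x)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
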