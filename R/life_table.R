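# Life tables: age-indexed annual death probabilities, read from two-column
# CSV, plus a Gompertz-Makeham generator for synthetic tables.

#' Read a life table from a two-column CSV
#'
#' Expects columns `age` (integer years, contiguous) and `qx` (annual death
#' probability); a header row is optional.
#'
#' @param path Path to the CSV file.
#' @return A `noacce_life_table` data frame with columns `age` and `qx`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path))
    stop("life table not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  lt <- utils::read.csv(path, header = has_header,
                        col.names = c("age", "qx"))
  lt <- data.frame(age = as.numeric(lt$age), qx = as.numeric(lt$qx))
  validate_life_table(lt)
  class(lt) <- c("noacce_life_table", "data.frame")
  lt
}

#' Write a life table as a two-column CSV
#' @param lt A life table data frame (`age`, `qx`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt)[c("age", "qx")], path, row.names = FALSE)
  invisible(path)
}

validate_life_table <- function(lt, entry_age = NULL) {
  if (!all(c("age", "qx") %in% names(lt)))
    stop("life table needs columns 'age' and 'qx'", call. = FALSE)
  if (nrow(lt) < 2L)
    stop("life table needs at least two rows", call. = FALSE)
  if (any(!is.finite(lt$age)) || any(diff(lt$age) != 1))
    stop("life table ages must be contiguous integers", call. = FALSE)
  if (any(!is.finite(lt$qx)) || any(lt$qx < 0) || any(lt$qx > 1))
    stop("life table qx values must lie in [0, 1]", call. = FALSE)
  if (!is.null(entry_age) && min(lt$age) > floor(entry_age))
    stop("life table must start at or below the cohort entry age",
         call. = FALSE)
  invisible(lt)
}

#' Annual death probability at a given age
#'
#' Looks up `qx` for `floor(age)`, clamping ages outside the tabulated range
#' to the first/last row.
#'
#' @param lt A life table (`age`, `qx`).
#' @param age Age in years; vectorised.
#' @return Annual death probability/probabilities.
#' @export
life_table_qx <- function(lt, age) {
  a <- pmin(pmax(floor(age), min(lt$age)), max(lt$age))
  lt$qx[match(a, lt$age)]
}

#' Convert an annual death probability to a per-cycle probability
#'
#' Complement-power form \eqn{1 - (1 - q_x)^{t}} with `cycle_length` t in
#' years, consistent with the constant-hazard convention used elsewhere.
#'
#' @param qx Annual death probability in \[0, 1\].
#' @param cycle_length Cycle length in years.
#' @return Per-cycle death probability.
#' @export
annual_to_cycle_prob <- function(qx, cycle_length = 0.25) {
  if (any(qx < 0) || any(qx > 1))
    stop("'qx' must lie in [0, 1]", call. = FALSE)
  1 - (1 - qx)^cycle_length
}

#' Generate a synthetic Gompertz-Makeham life table
#'
#' Annual death probabilities follow
#' \eqn{q_x = 1 - \exp(-(a + b\,e^{c\,x}))}: a Makeham background hazard `a`
#' plus a Gompertz senescent component with level `b` and log-slope `c`.
#' The packaged defaults (`a = 5e-4`, `b = 5e-6`, `c = 0.114`) emulate
#' all-cause mortality of an elderly Spanish cohort: qx(73) about 0.021 and
#' life expectancy at 73 of about 14 years.
#'
#' @param a Makeham (age-independent) annual hazard, `>= 0`.
#' @param b Gompertz hazard scale, `> 0` (or 0 for no senescence).
#' @param c Gompertz exponential age coefficient, `> 0`.
#' @param ages Integer ages to tabulate (default 55 to 110).
#' @return A `noacce_life_table` data frame.
#' @export
make_life_table <- function(a = 5e-4, b = 5e-6, c = 0.114, ages = 55:110) {
  if (a < 0 || b < 0 || (b > 0 && c <= 0))
    stop("need a >= 0, b >= 0 and c > 0 when b > 0", call. = FALSE)
  haz <- a + b * exp(c * ages)
  qx <- pmin(1 - exp(-haz), 1)
  if (any(qx[-length(qx)] >= 1 - 1e-12))
    warning("annual death probability reaches 1 before the terminal age; ",
            "qx capped at 1")
  lt <- data.frame(age = as.integer(ages), qx = qx)
  class(lt) <- c("noacce_life_table", "data.frame")
  lt
}
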