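#' Construct a validated life table
#'
#' A life table holds annual all-cause death probabilities `q_annual` indexed
#' by integer age and sex. It drives background mortality in every model
#' cycle. The table must cover a contiguous integer age range per sex, all
#' probabilities must lie in \[0, 1\], and the terminal age (`max_age`) is
#' absorbing: `q_annual` there equals 1, so no cohort member survives past it.
#' If the supplied entries stop short of `max_age` with q < 1, a terminal row
#' with q = 1 is appended at `max_age`.
#'
#' @param entries data.frame with columns `age` (integer years), `sex`
#'   (`"female"` or `"male"`), `q_annual` (probability in \[0,1\]).
#' @param max_age terminal age in years (default 110). Cohort members alive
#'   at this age die within the next cycle.
#' @return An object of class `life_table`: the entry data.frame with a
#'   `max_age` attribute.
#' @seealso [read_life_table()], [make_life_table()], [lookup_q()]
#' @export
life_table <- function(entries, max_age = 110L) {
  stopifnot(is.data.frame(entries))
  need <- c("age", "sex", "q_annual")
  if (!all(need %in% names(entries)))
    stop("life table needs columns: ", paste(need, collapse = ", "))
  entries <- entries[, need]
  entries$age <- as.integer(entries$age)
  entries$sex <- as.character(entries$sex)

  bad_sex <- !entries$sex %in% c("female", "male")
  if (any(bad_sex))
    stop("unknown sex label in row(s) ", paste(which(bad_sex), collapse = ", "),
         ": ", paste(unique(entries$sex[bad_sex]), collapse = ", "))
  bad_q <- !is.finite(entries$q_annual) | entries$q_annual < 0 | entries$q_annual > 1
  if (any(bad_q))
    stop("q_annual outside [0, 1] in row(s) ",
         paste(which(bad_q), collapse = ", "))

  out <- NULL
  for (sx in unique(entries$sex)) {
    e <- entries[entries$sex == sx, ]
    e <- e[order(e$age), ]
    if (anyDuplicated(e$age))
      stop("duplicate age ", e$age[duplicated(e$age)][1], " for sex ", sx)
    full <- seq(min(e$age), max(e$age))
    missing_ages <- setdiff(full, e$age)
    if (length(missing_ages))
      stop("gap in age range for sex ", sx, ": missing age ",
           paste(missing_ages, collapse = ", "))
    if (max(e$age) > max_age)
      stop("entries extend past max_age ", max_age, " for sex ", sx)
    if (max(e$age) < max_age || e$q_annual[nrow(e)] < 1) {
      # extend with the last observed q up to max_age - 1, then absorb
      ext_ages <- seq(max(e$age) + 1L, max_age)
      if (max(e$age) == max_age) {
        e$q_annual[nrow(e)] <- 1
      } else {
        ext <- data.frame(age = ext_ages, sex = sx,
                          q_annual = e$q_annual[nrow(e)])
        ext$q_annual[length(ext_ages)] <- 1
        e <- rbind(e, ext)
      }
    }
    e$q_annual[e$age == max_age] <- 1
    out <- rbind(out, e)
  }
  rownames(out) <- NULL
  structure(out, max_age = as.integer(max_age), class = c("life_table", "data.frame"))
}

#' Read a life table from a delimited text file
#'
#' Expects a CSV with header columns `age,sex,q_annual` (sex spelled
#' `female`/`male`), UTF-8. Validation errors name the offending row.
#'
#' @param source path to a CSV file, or a connection.
#' @param max_age terminal age passed to [life_table()].
#' @return a `life_table` object.
#' @export
read_life_table <- function(source, max_age = 110L) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  life_table(df, max_age = max_age)
}

#' Write a life table as CSV
#'
#' Inverse of [read_life_table()]: `read_life_table(write_life_table(lt, f))`
#' reproduces `lt` entry for entry.
#'
#' @param lt a `life_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up the annual death probability at a (possibly fractional) age
#'
#' Fractional mid-cycle ages floor to the integer age, matching the annual
#' granularity of national life tables. Ages past the terminal age return 1.
#'
#' @param lt a `life_table`.
#' @param age age in years, possibly fractional.
#' @param sex `"female"` or `"male"`.
#' @return annual death probability.
#' @export
lookup_q <- function(lt, age, sex = "female") {
  stopifnot(inherits(lt, "life_table"))
  a <- floor(age)
  out <- rep_len(1, length(a))
  below <- a < attr(lt, "max_age")
  if (any(below)) {
    i <- match(paste(a[below], sex), paste(lt$age, lt$sex))
    if (anyNA(i))
      stop("age ", paste(a[below][is.na(i)], collapse = ", "), " (", sex,
           ") not covered by the life table")
    out[below] <- lt$q_annual[i]
  }
  out
}

#' Convert an annual death probability to a per-cycle probability
#'
#' Assumes a constant hazard within the year, so the conversion is
#' `1 - (1 - q_annual)^cycle_length_years`. This is exactly invertible:
#' two independent half-year cycles recompose the annual probability.
#'
#' @param q_annual annual probability in \[0,1\].
#' @param cycle_length_years cycle length in years (default 0.5).
#' @return per-cycle probability.
#' @export
annual_to_cycle <- function(q_annual, cycle_length_years = 0.5) {
  if (any(!is.finite(q_annual)) || any(q_annual < 0) || any(q_annual > 1))
    stop("q_annual must lie in [0, 1]")
  stopifnot(cycle_length_years > 0)
  1 - (1 - q_annual)^cycle_length_years
}

#' Gompertz-Makeham annual death probability
#'
#' `q(age) = 1 - exp(-(makeham + gompertz_scale * exp(gompertz_shape * age)))`.
#' The Makeham term is an age-independent background hazard; the Gompertz term
#' grows exponentially with age, the standard shape of adult human mortality.
#' Used by the synthetic life-table generator.
#'
#' @param age age in years (vectorised).
#' @param makeham nonnegative age-independent hazard (per year).
#' @param gompertz_scale nonnegative hazard scale at age 0.
#' @param gompertz_shape nonnegative exponential growth rate per year of age.
#' @return annual death probability in \[0, 1).
#' @export
gompertz_makeham_q <- function(age, makeham, gompertz_scale, gompertz_shape) {
  if (makeham < 0 || gompertz_scale < 0 || gompertz_shape < 0)
    stop("Gompertz-Makeham parameters must be nonnegative")
  1 - exp(-(makeham + gompertz_scale * exp(gompertz_shape * age)))
}

#' @export
print.life_table <- function(x, ...) {
  cat("Life table:", length(unique(x$sex)), "sex(es), ages",
      min(x$age), "-", max(x$age),
      "(terminal age", attr(x, "max_age"), "absorbing)\n")
  invisible(x)
}
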