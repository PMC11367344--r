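#' Synthetic gender-averaged period life table
#'
#' Builds a UK-like, gender-averaged period life table from a Gompertz-Makeham
#' mortality law, \eqn{\mu(x) = A + B e^{cx}}. The table is a stand-in for a
#' national interim life table: it is calibrated so that annual death
#' probabilities and remaining life expectancy in later adulthood are close to
#' contemporary UK values (about 0.9\% annual mortality and 22 remaining years
#' at age 62), but it is synthetic and any real table can be supplied instead
#' via [read_life_table()].
#'
#' @param max_age Last age band in the table; the death probability there is 1.
#' @param makeham_a Age-independent hazard component \eqn{A} (per year).
#' @param gompertz_b Gompertz scale \eqn{B} (per year).
#' @param gompertz_c Gompertz shape \eqn{c} (per year of age).
#' @return A `data.frame` with columns `age` (integer, from 0) and `qx`
#'   (annual probability of death in the year of age starting at `age`).
#' @seealso [sample_death_age()], [life_expectancy()]
#' @export
#' @examples
#' lt <- synthetic_life_table()
#' life_expectancy(lt, 62)
synthetic_life_table <- function(max_age = 109L,
                                 makeham_a = 2e-4,
                                 gompertz_b = 2.5e-5,
                                 gompertz_c = 0.095) {
  age <- 0:max_age
  mu <- makeham_a + gompertz_b * exp(gompertz_c * (age + 0.5))
  qx <- 1 - exp(-mu)
  qx[length(qx)] <- 1
  data.frame(age = as.integer(age), qx = qx)
}

#' Read a life table from a delimited text file
#'
#' Expects a header line and two columns, `age` and `qx` (annual death
#' probability), tab- or whitespace-delimited.
#'
#' @param path Path to the file.
#' @return A validated life-table `data.frame` (columns `age`, `qx`).
#' @export
read_life_table <- function(path) {
  lt <- utils::read.table(path, header = TRUE)
  validate_life_table(lt)
  data.frame(age = as.integer(lt$age), qx = as.numeric(lt$qx))
}

validate_life_table <- function(lt) {
  if (!all(c("age", "qx") %in% names(lt))) {
    stop("life table must have columns 'age' and 'qx'", call. = FALSE)
  }
  if (any(lt$qx < 0 | lt$qx > 1)) {
    stop("life table column 'qx' must contain probabilities in [0, 1]",
         call. = FALSE)
  }
  if (is.unsorted(lt$age) || anyDuplicated(lt$age)) {
    stop("life table ages must be strictly increasing", call. = FALSE)
  }
  invisible(lt)
}

# Piecewise-constant hazard representation of an annual life table:
# m(x) = -log(1 - qx) on [x, x+1). Returns the cumulative-hazard grid used by
# both the death-age sampler (inverse transform) and life_expectancy().
.life_table_cumhaz <- function(lt) {
  m <- -log(pmax(1 - lt$qx, 1e-12))
  ages <- c(lt$age, lt$age[length(lt$age)] + 1L)
  list(age = as.numeric(ages), H = c(0, cumsum(m)))
}

#' Period life expectancy from a life table
#'
#' Deterministic remaining life expectancy at a given exact age, computed from
#' the table's annual death probabilities under a piecewise-constant hazard
#' within each year of age.
#'
#' @param life_table A life table as returned by [synthetic_life_table()].
#' @param age Exact age (years); may be non-integer.
#' @return Expected remaining years of life.
#' @export
life_expectancy <- function(life_table, age) {
  validate_life_table(life_table)
  ch <- .life_table_cumhaz(life_table)
  h0 <- stats::approx(ch$age, ch$H, xout = age, rule = 2)$y
  # integrate S(t) = exp(-(H(age + t) - H(age))) on a fine grid
  tmax <- max(ch$age) - age
  grid <- seq(0, tmax, by = 1 / 52)
  Ht <- stats::approx(ch$age, ch$H, xout = age + grid, rule = 2)$y
  s <- exp(-(Ht - h0))
  sum((s[-1] + s[-length(s)]) / 2) * (1 / 52)
}

#' Sample age at death from a life table
#'
#' Draws a continuous age at death for each current age by inverse transform
#' on the table's cumulative hazard (piecewise-constant hazard within each year
#' of age). The returned age is strictly greater than the current age. Ages
#' beyond the table's last band are clamped to that band with a warning.
#'
#' Uses the current R random number stream (`set.seed()` upstream for
#' reproducibility).
#'
#' @param age Numeric vector of current exact ages.
#' @param life_table A life table (columns `age`, `qx`).
#' @return Numeric vector of death ages, same length as `age`.
#' @export
#' @examples
#' lt <- synthetic_life_table()
#' set.seed(1)
#' mean(sample_death_age(rep(62, 1000), lt) - 62)
sample_death_age <- function(age, life_table) {
  validate_life_table(life_table)
  ch <- .life_table_cumhaz(life_table)
  top <- max(ch$age)
  if (any(age >= top)) {
    warning("age beyond life-table range; clamped to the final band")
    age <- pmin(age, top - 1e-6)
  }
  if (any(age < min(ch$age))) stop("age below life-table range", call. = FALSE)
  h_now <- stats::approx(ch$age, ch$H, xout = age)$y
  target <- h_now + stats::rexp(length(age))
  # invert the piecewise-linear cumulative hazard; beyond the final band the
  # hazard is effectively infinite (qx capped near 1), so inversion stays in
  # range; clamp defensively.
  death <- stats::approx(ch$H, ch$age, xout = pmin(target, max(ch$H)),
                         ties = max)$y
  pmax(pmin(death, top), age + 1e-9)
}
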