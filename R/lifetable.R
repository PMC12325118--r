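#' Synthetic all-cause mortality via a Gompertz-Makeham hazard
#'
#' The simulation needs an external input: age-specific all-cause mortality
#' for the modelled population (South Korea, 2021, in the original analysis).
#' Because that national life table is an external dataset, the package ships
#' a parametric stand-in: the Gompertz-Makeham hazard
#' `mu(x) = a + b * exp(eta * x)`, with defaults calibrated qualitatively to
#' modern East-Asian longevity (residual life expectancy at age 40 of roughly
#' 40 years). A real life table can be supplied via [load_life_table()].
#'
#' @param makeham_a Age-independent background hazard (per year), `>= 0`.
#' @param gompertz_b Senescent hazard scale, `> 0`... zero is allowed as a
#'   degenerate (no-senescence) limit.
#' @param gompertz_eta Senescent hazard log-slope per year of age, `>= 0`.
#' @return A list of class `thyrocea_mortality`.
#' @export
mortality_model <- function(makeham_a = 5e-4, gompertz_b = 3e-5,
                            gompertz_eta = 0.095) {
  if (makeham_a < 0 || gompertz_b < 0 || gompertz_eta < 0) {
    stop("mortality parameters must be non-negative", call. = FALSE)
  }
  structure(list(makeham_a = makeham_a, gompertz_b = gompertz_b,
                 gompertz_eta = gompertz_eta),
            class = "thyrocea_mortality")
}

#' Build a full life table from a mortality model
#'
#' Evaluates annual death probabilities `qx = 1 - exp(-mu(x))` for integer
#' ages 0--110 and closes the table with `qx(110) = 1`.
#'
#' @param model A [mortality_model()], or a list with the same fields.
#' @return A data frame of class `thyrocea_lifetable` with columns `age`
#'   (0--110) and `qx`.
#' @export
#' @examples
#' lt <- make_life_table(mortality_model())
#' lt$qx[lt$age == 40]
make_life_table <- function(model = mortality_model()) {
  ages <- 0:110
  mu <- model$makeham_a + model$gompertz_b * exp(model$gompertz_eta * ages)
  qx <- 1 - exp(-mu)
  qx[length(qx)] <- 1
  structure(data.frame(age = ages, qx = qx), class = c("thyrocea_lifetable",
                                                       "data.frame"))
}

#' Load a life table from a CSV file
#'
#' Expects a header row and two columns, `age` and `qx`, with 1-year ages.
#' Ages missing up to 110 are extrapolated: the hazard `-log(1 - qx)` is
#' extended log-linearly using its trend over the last (up to) ten observed
#' ages, and the table is closed with `qx(110) = 1`. This is the hook for
#' supplying a real national life table in place of the synthetic default.
#'
#' @param path CSV path.
#' @return A `thyrocea_lifetable` covering ages 0--110.
#' @export
load_life_table <- function(path) {
  tab <- read.csv(path)
  if (!all(c("age", "qx") %in% names(tab))) {
    stop("life table must have columns 'age' and 'qx'", call. = FALSE)
  }
  tab <- tab[order(tab$age), c("age", "qx")]
  if (anyDuplicated(tab$age) || any(diff(tab$age) != 1) || tab$age[1] != 0) {
    stop("ages must be consecutive 1-year ages starting at 0", call. = FALSE)
  }
  if (any(tab$qx < 0 | tab$qx > 1)) {
    stop("qx outside [0,1] at age(s): ",
         paste(tab$age[tab$qx < 0 | tab$qx > 1], collapse = ", "), call. = FALSE)
  }
  last <- max(tab$age)
  if (last > 110) tab <- tab[tab$age <= 110, ]
  if (last < 110) {
    k <- min(10L, nrow(tab))
    tail_tab <- tab[seq(nrow(tab) - k + 1L, nrow(tab)), ]
    h <- -log(pmax(1e-12, 1 - pmin(tail_tab$qx, 1 - 1e-12)))
    slope <- if (k >= 2 && all(h > 0)) {
      stats::coef(stats::lm(log(h) ~ tail_tab$age))[[2]]
    } else 0.1
    slope <- max(slope, 0)   # never extrapolate falling old-age mortality
    h_last <- max(h[length(h)], 1e-12)
    new_ages <- (last + 1L):110L
    new_q <- pmin(1, 1 - exp(-h_last * exp(slope * (new_ages - last))))
    tab <- rbind(tab, data.frame(age = new_ages, qx = new_q))
  }
  tab$qx[tab$age == 110] <- 1
  structure(tab, row.names = seq_len(nrow(tab)),
            class = c("thyrocea_lifetable", "data.frame"))
}

#' Write a life table to CSV
#'
#' @param table A `thyrocea_lifetable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(table, path) {
  write.csv(as.data.frame(table)[, c("age", "qx")], path, row.names = FALSE)
  invisible(path)
}

#' Residual life expectancy from a life table
#'
#' Expected number of further whole-year cycles lived from `age`, counting the
#' cycle entered at `age` (i.e. `sum over t >= 0 of S(t)` with `S(0) = 1`),
#' the convention matched by the cycle-start accrual of the simulation engine.
#'
#' @param table A `thyrocea_lifetable`.
#' @param age Starting age.
#' @return Expected residual years (numeric scalar).
#' @export
life_expectancy <- function(table, age = 40) {
  qx <- table$qx[table$age >= age]
  sum(cumprod(c(1, 1 - qx[-length(qx)])))
}

# qx lookup vector indexed by age+1, for ages 0..110, from config$mortality
config_life_table <- function(config) {
  m <- config$mortality
  if (identical(m$type, "table")) {
    tab <- data.frame(age = unlist(m$age), qx = unlist(m$qx))
    structure(tab, class = c("thyrocea_lifetable", "data.frame"))
  } else {
    make_life_table(mortality_model(m$makeham_a, m$gompertz_b, m$gompertz_eta))
  }
}
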