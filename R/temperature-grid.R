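#' Gridded daily maximum temperature series
#'
#' A `temperature_grid` holds one daily maximum temperature (tmax) series per
#' grid cell on a contiguous daily calendar, together with scenario metadata.
#' It is the exposure field consumed by [compute_threshold()],
#' [detect_heatwaves()] and the bias-correction functions. Cells are rows of
#' the `tmax` matrix; days are columns.
#'
#' @param tmax numeric matrix, cells x days, in degrees Celsius.
#' @param dates `Date` vector of length `ncol(tmax)`; must be contiguous
#'   (daily, no gaps).
#' @param scenario character scalar, one of `"observed"`, `"factual"`,
#'   `"counterfactual"` (free-form labels are allowed for derived series).
#' @param member integer ensemble member index (1 for the observed series).
#'
#' @return An object of class `temperature_grid`: a list with elements
#'   `tmax`, `dates`, `cells` (integer cell ids), `scenario`, `member`.
#' @seealso [generate_temperature_grid()] to simulate one,
#'   [write_temperature_grid()] for plain-text serialization.
#' @export
temperature_grid <- function(tmax, dates, scenario = "observed", member = 1L) {
  tmax <- as.matrix(tmax)
  dates <- as.Date(dates)
  if (ncol(tmax) != length(dates))
    stop_input("`tmax` must have one column per date (", ncol(tmax),
               " columns vs ", length(dates), " dates)")
  if (length(dates) > 1 && any(diff(dates) != 1))
    stop_input("`dates` must be contiguous daily dates with no gaps")
  if (anyNA(tmax) || any(!is.finite(tmax)))
    stop_input("`tmax` must be finite with no missing values")
  structure(
    list(tmax = tmax, dates = dates, cells = seq_len(nrow(tmax)),
         scenario = scenario, member = as.integer(member)),
    class = "temperature_grid")
}

#' @export
print.temperature_grid <- function(x, ...) {
  cat("<temperature_grid> ", nrow(x$tmax), " cells x ", length(x$dates),
      " days (", format(x$dates[1]), " to ", format(x$dates[length(x$dates)]),
      ")\n  scenario: ", x$scenario, ", member: ", x$member,
      "\n  tmax range: ", sprintf("%.2f", min(x$tmax)), " to ",
      sprintf("%.2f", max(x$tmax)), " degC\n", sep = "")
  invisible(x)
}

#' Serialize a temperature grid to CSV
#'
#' Writes the grid in long format (`cell,date,tmax`) with scenario metadata
#' in a header comment, so series can be inspected or re-read with any tool.
#'
#' @param grid a [temperature_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_temperature_grid <- function(grid, path) {
  stopifnot(inherits(grid, "temperature_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature_grid scenario=%s member=%d units=degC",
                     grid$scenario, grid$member), con)
  df <- data.frame(
    cell = rep(grid$cells, times = length(grid$dates)),
    date = rep(grid$dates, each = nrow(grid$tmax)),
    tmax = as.vector(grid$tmax))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a temperature grid written by [write_temperature_grid()]
#'
#' @param path CSV file path.
#' @return a [temperature_grid()].
#' @export
read_temperature_grid <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- list(scenario = "observed", member = 1L)
  if (startsWith(header, "#")) {
    m <- regmatches(header, regexec("scenario=(\\S+) member=(\\d+)", header))[[1]]
    if (length(m) == 3) meta <- list(scenario = m[2], member = as.integer(m[3]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  dates <- sort(unique(as.Date(df$date)))
  cells <- sort(unique(df$cell))
  tmax <- matrix(NA_real_, length(cells), length(dates))
  tmax[cbind(match(df$cell, cells), match(as.Date(df$date), dates))] <- df$tmax
  temperature_grid(tmax, dates, scenario = meta$scenario, member = meta$member)
}
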