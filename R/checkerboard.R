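#' Checkerboard growth matrix
#'
#' Growth rates measured over a two-dimensional grid of a growth-limiting
#' perturbation (rows: e.g. alpha-methyl-glucoside/glucose ratio or inducer
#' level) and drug concentration (columns).
#'
#' @param row_values Limitation-axis values (dimensionless ratio or mM).
#' @param col_concs Drug concentrations, ug/ml, sorted ascending.
#' @param growth Matrix of growth rates, 1/h, with `length(row_values)` rows
#'   and `length(col_concs)` columns; non-negative.
#' @param normalization_mode Either `"per_row_zero_dose"` (each row normalized
#'   by its own zero-dose growth; default) or `"global_max"` (whole board
#'   normalized by the highest drug-free growth rate).
#' @return An object of class `checkerboard`.
#' @export
checkerboard <- function(row_values, col_concs, growth,
                         normalization_mode = c("per_row_zero_dose", "global_max")) {
  normalization_mode <- match.arg(normalization_mode)
  growth <- as.matrix(growth)
  stopifnot(
    is.numeric(row_values), is.numeric(col_concs),
    nrow(growth) == length(row_values),
    ncol(growth) == length(col_concs)
  )
  if (is.unsorted(col_concs, strictly = TRUE)) {
    stop("`col_concs` must be strictly increasing")
  }
  if (any(growth < 0)) stop("growth rates must be non-negative")
  structure(
    list(row_values = row_values, col_concs = col_concs, growth = growth,
         normalization_mode = normalization_mode),
    class = "checkerboard"
  )
}

#' @export
print.checkerboard <- function(x, ...) {
  cat(sprintf("Checkerboard: %d limitation levels x %d concentrations (%s normalization)\n",
              length(x$row_values), length(x$col_concs), x$normalization_mode))
  invisible(x)
}

#' Normalized growth matrix of a checkerboard
#'
#' @param board A [checkerboard()].
#' @return Matrix of normalized growth (dimensionless).
#' @export
normalize_checkerboard <- function(board) {
  stopifnot(inherits(board, "checkerboard"))
  g <- board$growth
  if (board$normalization_mode == "per_row_zero_dose") {
    if (!any(board$col_concs == 0)) {
      stop("per-row normalization requires a zero-dose column")
    }
    g0 <- g[, board$col_concs == 0, drop = FALSE]
    g0 <- rowMeans(g0)
    if (any(g0 <= 0)) {
      warning("rows with non-positive zero-dose growth yield NA normalized values")
    }
    sweep(g, 1, g0, "/")
  } else {
    g / max(g[, board$col_concs == 0 | board$col_concs == min(board$col_concs)])
  }
}

#' Inhibition contour of a checkerboard
#'
#' For each limitation level (row), finds the drug concentration at which
#' normalized growth first crosses `1 - level` (e.g. `level = 0.9` gives the
#' IC90 contour), by linear interpolation of normalized growth against
#' log-concentration between the bracketing grid columns. The zero-dose
#' column anchors the search but is never used as an interpolation endpoint:
#' a row already below threshold at the smallest positive concentration is
#' left-censored; a row that never drops below threshold is right-censored.
#' Non-monotone rows (drug-rescue regime) are used at their first crossing
#' and flagged.
#'
#' @param board A [checkerboard()].
#' @param level Inhibition level in (0, 1); default 0.9.
#' @return A data frame with one row per limitation level: `row_value`,
#'   `conc` (contour concentration, NA when censored), `censored`
#'   (`"none"`, `"left"`, `"right"`) and `multiple_crossings` (logical).
#' @export
ic_contour <- function(board, level = 0.9) {
  stopifnot(inherits(board, "checkerboard"), level > 0, level < 1)
  norm <- normalize_checkerboard(board)
  thr <- 1 - level
  pos <- board$col_concs > 0
  concs <- board$col_concs[pos]
  out <- data.frame(
    row_value = board$row_values,
    conc = NA_real_,
    censored = "none",
    multiple_crossings = FALSE,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(board$row_values)) {
    y <- norm[i, pos]
    below <- y < thr
    crossings <- which(diff(below) != 0L)
    out$multiple_crossings[i] <- length(crossings) > 1L
    if (!any(below)) {
      out$censored[i] <- "right"
    } else if (below[1]) {
      out$censored[i] <- "left"
    } else {
      j <- crossings[1]
      lc <- log(concs[j:(j + 1)])
      yy <- y[j:(j + 1)]
      out$conc[i] <- exp(lc[1] + (thr - yy[1]) * diff(lc) / diff(yy))
    }
  }
  out
}

#' Fold-change in inhibitory concentration across a checkerboard
#'
#' Mean and standard deviation of contour concentrations over the
#' `2 * neighbor_halfwidth + 1` rows centered at `center_row`, divided by the
#' contour value of `reference_row`. This is the fold-change in (e.g.) IC90
#' between a stated limitation level and the unlimited condition, with the SD
#' taken over neighboring limitation levels.
#'
#' @param contours Output of [ic_contour()].
#' @param reference_row Row index (1-based) of the reference condition.
#' @param center_row Row index of the condition of interest.
#' @param neighbor_halfwidth Half-width of the neighborhood (default 1, i.e.
#'   three rows).
#' @return A list with `fold_change`, `sd`, and `censored` (TRUE when any
#'   selected or reference contour is censored, in which case the numbers are
#'   NA).
#' @export
fold_change_ic <- function(contours, reference_row, center_row,
                           neighbor_halfwidth = 1) {
  stopifnot(is.data.frame(contours), "conc" %in% names(contours))
  idx <- (center_row - neighbor_halfwidth):(center_row + neighbor_halfwidth)
  if (any(idx < 1L) || any(idx > nrow(contours))) {
    stop("neighborhood extends beyond the contour table")
  }
  sel <- contours[idx, ]
  ref <- contours[reference_row, ]
  if (any(sel$censored != "none") || ref$censored != "none") {
    return(list(fold_change = NA_real_, sd = NA_real_, censored = TRUE))
  }
  fc <- sel$conc / ref$conc
  list(fold_change = mean(fc), sd = stats::sd(fc), censored = FALSE)
}
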