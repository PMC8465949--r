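#' Computed ABC analysis
#'
#' Partitions a set of non-negative items into the "important few" (subset
#' A), an intermediate subset B and the "trivial many" (subset C) from the
#' cumulative-contribution curve. Items are sorted in decreasing order
#' (ties broken by original position, so the partition is deterministic);
#' the curve plots effort `x_i = i/n` against yield
#' `y_i = cumsum(value)/sum(value)`. The A|B boundary is the curve point
#' closest to the ideal point (0, 1); the B|C boundary is the first later
#' point whose discrete slope drops to the break-even value 1 (equivalently
#' the first later item not exceeding the mean), clipped to `n - 1` when no
#' such point exists. Zero-valued items always fall into C.
#'
#' @param values non-negative numeric vector, at least 3 items, at least
#'   one strictly positive.
#' @param names optional item labels (defaults to names of `values` or
#'   positional labels).
#' @return object of class `crs_abc`: list with `items` (sorted
#'   data frame: name, value, x, y, subset), `ab_index`, `bc_index` and the
#'   subset membership vectors `A`, `B`, `C`.
#' @export
abc_partition <- function(values, names = NULL) {
  if (is.null(names)) names <- base::names(values)
  if (is.null(names)) names <- paste0("item", seq_along(values))
  if (length(values) < 3) stop("ABC analysis needs at least 3 items")
  if (anyNA(values) || any(values < 0)) stop("ABC analysis requires non-negative items")
  if (all(values == 0)) stop("ABC analysis requires at least one positive item")

  ord <- order(-values, seq_along(values))
  v <- values[ord]
  n <- length(v)
  x <- seq_len(n) / n
  y <- cumsum(v) / sum(v)

  ab <- which.min(sqrt(x^2 + (1 - y)^2))  # first minimum on ties
  slope <- v / mean(v)  # discrete slope (y_i - y_{i-1}) / (x_i - x_{i-1})
  later <- which(seq_len(n) > ab & slope <= 1)
  bc <- if (length(later)) later[1] else n - 1
  bc <- max(bc, ab)
  # zero items never reach A or B
  last_pos <- max(which(v > 0))
  ab <- min(ab, last_pos)
  bc <- min(bc, last_pos)

  subset <- rep("C", n)
  subset[seq_len(bc)] <- "B"
  subset[seq_len(ab)] <- "A"
  items <- data.frame(name = names[ord], value = v, x = x, y = y,
                      subset = subset, stringsAsFactors = FALSE)
  out <- list(items = items, ab_index = ab, bc_index = bc,
              A = items$name[subset == "A"], B = items$name[subset == "B"],
              C = items$name[subset == "C"])
  class(out) <- "crs_abc"
  out
}

#' Curve coordinates of an ABC partition
#'
#' @param partition a `crs_abc` object.
#' @return data frame with columns `x` (effort), `y` (cumulative yield)
#'   and `subset`, one row per item in sorted order; the final `y` is 1.
#' @export
abc_plot_data <- function(partition) {
  stopifnot(inherits(partition, "crs_abc"))
  partition$items[c("x", "y", "subset")]
}

#' @export
print.crs_abc <- function(x, ...) {
  n <- nrow(x$items)
  cat("Computed ABC analysis of", n, "items\n")
  cat("  A (important few):  ", length(x$A), " item(s): ",
      paste(utils::head(x$A, 8), collapse = ", "),
      if (length(x$A) > 8) ", ..." else "", "\n", sep = "")
  cat("  B (intermediate):   ", length(x$B), " item(s)\n", sep = "")
  cat("  C (trivial many):   ", length(x$C), " item(s)\n", sep = "")
  invisible(x)
}

#' @export
plot.crs_abc <- function(x, ...) {
  d <- x$items
  cols <- c(A = "#D7301F", B = "#FC8D59", C = "#BDBDBD")
  graphics::plot(c(0, d$x), c(0, d$y), type = "l", xlab = "effort (fraction of items)",
                 ylab = "cumulative yield", main = "Computed ABC curve", ...)
  graphics::points(d$x, d$y, pch = 19, col = cols[d$subset])
  graphics::abline(v = d$x[x$ab_index], lty = 2, col = cols["A"])
  if (x$bc_index > x$ab_index)
    graphics::abline(v = d$x[x$bc_index], lty = 2, col = cols["B"])
  graphics::legend("bottomright", legend = c("A", "B", "C"), col = cols, pch = 19,
                   bty = "n")
  invisible(x)
}
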