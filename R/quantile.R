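#' Fit empirical quantile cut points for exposure components
#'
#' Learns, per component, the `q - 1` interior empirical quantile cut points
#' (deciles by default) from a set of concentrations — typically the training
#' split of an analysis dataset. The cut points are empirical quantiles with
#' linear interpolation between order statistics (`stats::quantile()` type 7),
#' so results are deterministic and bit-stable.
#'
#' @param x data frame or matrix of nonnegative concentrations, one column per
#'   component. Non-numeric columns named `unit_id` or `year` are ignored.
#' @param q integer number of quantile groups, `>= 2` (default 10 = deciles).
#' @param components optional character vector selecting/ordering the columns
#'   to use; defaults to all numeric columns except `unit_id`/`year`.
#' @return an object of class `"quantile_breaks"`: a list with `cuts`
#'   (a `(q-1) x p` matrix of cut points), `q`, `components`, and `source_n`
#'   (number of rows used).
#' @details Zero-variance (constant) components are retained but flagged with
#'   a warning: every cut equals the constant, so all scores are 0 and the
#'   component carries no information for weight estimation.
#' @seealso [score_quantiles()]
#' @examples
#' br <- quantile_breaks(data.frame(a = 1:10), q = 2)
#' br$cuts  # the median, 5.5
#' @export
quantile_breaks <- function(x, q = 10, components = NULL) {
  q <- as.integer(q)
  if (is.na(q) || q < 2) stop("q must be an integer >= 2")
  x <- as.data.frame(x)
  if (is.null(components)) {
    components <- setdiff(names(x)[vapply(x, is.numeric, logical(1))],
                          c("unit_id", "year"))
  }
  missing_cols <- setdiff(components, names(x))
  if (length(missing_cols))
    stop("components not found in data: ", paste(missing_cols, collapse = ", "))
  if (!length(components)) stop("no components to score")
  xm <- as.matrix(x[components])
  if (nrow(xm) < q)
    stop("insufficient rows: need at least q = ", q, " rows, got ", nrow(xm))
  if (anyNA(xm)) stop("missing values in component concentrations")
  if (any(xm < 0)) {
    bad <- components[colSums(xm < 0) > 0]
    stop("negative concentration in component(s): ",
         paste(bad, collapse = ", "))
  }
  probs <- seq_len(q - 1) / q
  cuts <- apply(xm, 2, stats::quantile, probs = probs, names = FALSE, type = 7)
  cuts <- matrix(cuts, nrow = q - 1, ncol = length(components),
                 dimnames = list(NULL, components))
  const <- components[apply(xm, 2, function(v) max(v) == min(v))]
  if (length(const))
    warning("constant component(s) score 0 everywhere and are unidentifiable ",
            "for weighting: ", paste(const, collapse = ", "))
  structure(list(cuts = cuts, q = q, components = components,
                 source_n = nrow(xm)),
            class = "quantile_breaks")
}

#' Score concentrations against fitted quantile cut points
#'
#' Assigns each concentration its integer quantile score in `0 .. q-1`: the
#' number of fitted cut points strictly below the value. Values exactly equal
#' to a cut fall in the lower bin; values beyond the fitted range clip to the
#' extreme bins, so validation-split rows can always be scored with
#' training-split breaks.
#'
#' @param x data frame or matrix holding (at least) the components named in
#'   `breaks`.
#' @param breaks a [quantile_breaks()] object.
#' @return integer matrix of scores, one column per component, with attribute
#'   `q`.
#' @export
score_quantiles <- function(x, breaks) {
  stopifnot(inherits(breaks, "quantile_breaks"))
  x <- as.data.frame(x)
  missing_cols <- setdiff(breaks$components, names(x))
  if (length(missing_cols))
    stop("component mismatch: data lacks component(s): ",
         paste(missing_cols, collapse = ", "))
  p <- length(breaks$components)
  out <- matrix(0L, nrow = nrow(x), ncol = p,
                dimnames = list(NULL, breaks$components))
  for (j in seq_len(p)) {
    comp <- breaks$components[j]
    v <- x[[comp]]
    if (anyNA(v)) stop("missing values in component ", comp)
    # count of cuts strictly below v; ties at a cut go to the lower bin
    out[, j] <- findInterval(v, breaks$cuts[, j], left.open = TRUE)
  }
  attr(out, "q") <- breaks$q
  out
}

#' @export
print.quantile_breaks <- function(x, ...) {
  cat("Quantile breaks: q =", x$q, "groups,", length(x$components),
      "components, fitted on", x$source_n, "rows\n")
  invisible(x)
}
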