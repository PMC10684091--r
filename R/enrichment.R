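#' Pearson chi-square test on a contingency table
#'
#' Computes the classic Pearson statistic `sum((O - E)^2 / E)` without
#' continuity correction (a `correct` flag enables the Yates correction for
#' 2x2 tables), with the upper-tail chi-square p-value at
#' `df = (r - 1)(c - 1)`.  All expected counts must be positive; a warning
#' is emitted when any expected count falls below 5.
#'
#' @param table r x c matrix (or coercible) of non-negative counts.
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return object of class `contingency_result`: list with `table`,
#'   `expected`, `chi2`, `df`, `p`, `p_adjusted` (NA until adjusted across
#'   a family, e.g. by [class_state_tables()]).
#' @export
chi_square <- function(table, correct = FALSE) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0)) {
    stop("zero row margin: ",
         paste(rownames(tab)[rs == 0] %||% which(rs == 0), collapse = ", "))
  }
  if (any(cs == 0)) {
    stop("zero column margin: ",
         paste(colnames(tab)[cs == 0] %||% which(cs == 0), collapse = ", "))
  }
  expected <- outer(rs, cs) / sum(tab)
  if (any(expected < 5)) {
    warning("some expected counts are below 5; the chi-square ",
            "approximation may be poor")
  }
  dev <- abs(tab - expected)
  if (correct) {
    if (!all(dim(tab) == c(2L, 2L))) {
      stop("continuity correction applies to 2x2 tables only")
    }
    dev <- pmax(0, dev - 0.5)
  }
  chi2 <- sum(dev^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  structure(list(table = tab, expected = expected, chi2 = chi2, df = df,
                 p = pchisq(chi2, df, lower.tail = FALSE),
                 p_adjusted = NA_real_),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> chi2 = %.4g, df = %d, p = %.4g%s\n",
              x$chi2, x$df, x$p,
              if (is.na(x$p_adjusted)) "" else
                sprintf(", adjusted p = %.4g", x$p_adjusted)))
  print(x$table)
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values vector of p-values in `[0, 1]` (NAs are propagated).
#' @return adjusted p-values, order-preserving with the input, monotone in
#'   the step-up sense, capped at 1 and never below the raw value.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pp <- p[ok]
  n <- length(pp)
  o <- order(pp, decreasing = TRUE)
  ro <- order(o)
  out[ok] <- pmin(1, cummin(pp[o] * n / (n:1)))[ro]
  out
}

#' Class-by-state contingency tables with family-wise BH adjustment
#'
#' Builds, for each expression state, the 2x2 table of the focal gene class
#' (LSG, including LSGs carrying a HET domain) versus other genes against
#' in-state / out-of-state, runs [chi_square()] on each, and BH-adjusts the
#' p-values across the family of tables.  HET-domain genes are excluded
#' from the "other" margin by default, matching the convention of comparing
#' lineage-specific genes against non-HET non-lineage-specific genes.
#' When the state variable is binary a single table is returned.
#'
#' @param labels named character vector gene -> class
#'   (`LSG`/`HET`/`HET_LSG`/`other`).
#' @param states named vector gene -> state, sharing the gene universe.
#' @param focal_classes classes forming the focal margin.
#' @param exclude_het drop plain HET genes from the comparison margin.
#' @return named list of `contingency_result`, one per state (or a single
#'   entry named after the second state level for binary states).
#' @export
class_state_tables <- function(labels, states,
                               focal_classes = c("LSG", "HET_LSG"),
                               exclude_het = TRUE) {
  if (is.null(names(labels)) || is.null(names(states))) {
    stop("labels and states must be named by gene id")
  }
  genes <- intersect(names(labels), names(states))
  if (length(genes) == 0) stop("labels and states share no genes")
  labels <- labels[genes]
  states <- states[genes]
  if (!any(labels %in% focal_classes)) {
    stop("focal class absent from the gene universe")
  }
  if (all(labels %in% focal_classes)) {
    stop("comparison class absent from the gene universe")
  }
  keep <- rep(TRUE, length(genes))
  if (exclude_het) keep <- labels != "HET"
  lab <- ifelse(labels[keep] %in% focal_classes, "focal", "other")
  st <- as.character(states[keep])
  state_levels <- unique(st)
  if (length(state_levels) < 2) {
    stop("states must take at least two values")
  }
  build <- function(level) {
    tab <- rbind(
      focal = c(sum(lab == "focal" & st == level),
                sum(lab == "focal" & st != level)),
      other = c(sum(lab == "other" & st == level),
                sum(lab == "other" & st != level)))
    colnames(tab) <- c(level, paste0("not_", level))
    chi_square(tab)
  }
  levels_used <- if (length(state_levels) == 2) state_levels[1] else
    state_levels
  results <- lapply(levels_used, build)
  names(results) <- levels_used
  padj <- bh_adjust(vapply(results, `[[`, numeric(1), "p"))
  for (i in seq_along(results)) results[[i]]$p_adjusted <- padj[i]
  results
}
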