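## Nested codon-model bookkeeping: degrees of freedom, 2*delta-lnL and
## chi-square P values over parsed codeml fits.  Maximum-likelihood
## estimation itself is codeml's job; fits enter via parse_codeml_lnl() or
## codeml_fit().

#' Upper-tail chi-square probability
#'
#' The regularized upper incomplete gamma function Q(df/2, x/2), the P value
#' of a likelihood-ratio statistic.
#'
#' @param x Statistic, \code{x >= 0}.
#' @param df Degrees of freedom, \code{df >= 1}.
#' @return \code{P(X >= x)} for \code{X ~ chi-square(df)}.
#' @export
chi2_upper_tail <- function(x, df) {
  if (any(x < 0)) stop("chi-square statistic must be >= 0")
  if (any(df < 1)) stop("df must be >= 1")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Likelihood-ratio test of two nested codeml fits
#'
#' Computes \code{2 * (lnL_alt - lnL_null)} and its upper-tail chi-square
#' P value.  A marginally negative statistic (within \code{tolerance}) is an
#' optimizer artifact and is clamped to 0 silently; a larger negative value
#' is clamped with a warning.  For branch-site comparisons the conventional
#' null is chi-square with \code{df = 1}; \code{mixture = TRUE} instead uses
#' the 50:50 mixture of a point mass at 0 and chi-square(1), which halves
#' the P value for positive statistics.
#'
#' @param null_fit,alt_fit \code{codeml_fit} objects (or bare lists with an
#'   \code{lnL} element); the models must be nested.
#' @param df Degrees of freedom of the comparison (1 for two-ratio vs M0 and
#'   model A vs null model A; [free_ratio_df()] for free-ratio vs M0).
#' @param tolerance Negative-statistic tolerance (default \code{1e-6}).
#' @param mixture Use the 50:50 mixture null (branch-site tests only).
#' @return An \code{lrt_result}: list with \code{stat}, \code{df}, \code{p}
#'   and a possible \code{warning}.
#' @examples
#' lrt(codeml_fit(-2042.0968), codeml_fit(-2038.4530), df = 1)
#' @export
lrt <- function(null_fit, alt_fit, df, tolerance = 1e-6, mixture = FALSE) {
  if (df < 1) stop("df must be >= 1")
  stat <- 2 * (alt_fit$lnL - null_fit$lnL)
  warning_msg <- NULL
  if (stat < 0) {
    if (stat < -tolerance) {
      warning_msg <- paste0("alternative lnL below null lnL by ",
                            format(-stat / 2), "; optimizer artifact, ",
                            "statistic clamped to 0")
      warning(warning_msg)
    }
    stat <- 0
  }
  p <- chi2_upper_tail(stat, df)
  if (mixture) p <- if (stat == 0) 1 else p / 2
  structure(list(stat = stat, df = df, p = p, warning = warning_msg),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: 2*dlnL = %.4f, df = %d, P = %.6g\n", x$stat, x$df, x$p))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Degrees of freedom of the free-ratio vs one-ratio comparison
#'
#' An unrooted bifurcating tree of \code{n} taxa has \code{2n - 3} branches;
#' the free-ratio model fits one omega per branch against M0's single
#' omega, so the comparison has \code{(2n - 3) - 1} degrees of freedom.
#'
#' @param n_taxa Number of taxa, \code{>= 3}.
#' @return Integer degrees of freedom.
#' @examples
#' free_ratio_df(6)  # 8
#' @export
free_ratio_df <- function(n_taxa) {
  if (n_taxa < 3) stop("free-ratio df needs n_taxa >= 3")
  as.integer(2L * n_taxa - 3L) - 1L
}

#' Model comparison table over codeml fits
#'
#' Renders the fits and their nested comparisons in the conventional layout
#' (model, lnL, omega estimates, 2*dlnL, P value).
#'
#' @param fits Named list of \code{codeml_fit} objects.
#' @param comparisons List of comparisons, each a list with elements
#'   \code{null}, \code{alt} (names into \code{fits}) and \code{df}.
#' @return A \code{model_table} data frame: one row per fit, with the
#'   comparison statistic and P value attached to the alternative model's
#'   row.
#' @export
model_table <- function(fits, comparisons = list()) {
  for (cmp in comparisons) {
    missing_fit <- setdiff(c(cmp$null, cmp$alt), names(fits))
    if (length(missing_fit)) {
      stop("comparison references missing fit(s): ",
           paste(missing_fit, collapse = ", "))
    }
  }
  fmt_omega <- function(f) {
    om <- c(f$omega0, f$omega1, f$omega2)
    lab <- c("w0", "w1", "w2")
    keep <- !is.na(om)
    if (!any(keep)) return("")
    paste(sprintf("%s = %s", lab[keep], format(om[keep])), collapse = ", ")
  }
  tab <- data.frame(
    model = names(fits),
    lnL = vapply(fits, function(f) f$lnL, 1),
    omega = vapply(fits, fmt_omega, ""),
    comparison = "", stat = NA_real_, df = NA_integer_, p = NA_real_,
    stringsAsFactors = FALSE
  )
  for (cmp in comparisons) {
    r <- lrt(fits[[cmp$null]], fits[[cmp$alt]], df = cmp$df)
    i <- match(cmp$alt, tab$model)
    tab$comparison[i] <- paste(cmp$null, "vs", cmp$alt)
    tab$stat[i] <- r$stat
    tab$df[i] <- r$df
    tab$p[i] <- r$p
  }
  rownames(tab) <- NULL
  class(tab) <- c("model_table", "data.frame")
  tab
}

#' @export
print.model_table <- function(x, ...) {
  out <- x
  out$lnL <- sprintf("%.4f", out$lnL)
  out$stat <- ifelse(is.na(out$stat), "", sprintf("%.4f", out$stat))
  out$p <- ifelse(is.na(out$p), "", sprintf("%.6g", out$p))
  out$df <- ifelse(is.na(out$df), "", out$df)
  print.data.frame(out, row.names = FALSE, right = FALSE)
  invisible(x)
}
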