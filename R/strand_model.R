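#' Poisson log-probability mass at an integer rate
#'
#' Log of \eqn{\Pr[Y = y \mid \lambda]} for a Poisson count. The zero-rate
#' boundary is exact: probability 1 when \code{y == 0}, probability 0 (log
#' \code{-Inf}) when \code{y > 0}. All arithmetic is in log space (via the
#' log-gamma factorial), so large counts do not overflow.
#'
#' @param y Non-negative integer count (vectorised).
#' @param lam Non-negative rate (vectorised).
#' @return Numeric vector of log-probabilities.
#' @examples
#' poisson_log_pmf(1, 1)   # -1
#' poisson_log_pmf(0, 0)   # 0: an empty process emits nothing
#' @export
poisson_log_pmf <- function(y, lam) {
  if (any(y < 0) || any(lam < 0))
    stop("'y' and 'lam' must be non-negative")
  if (any(y != floor(y)))
    stop("'y' must be an integer count")
  stats::dpois(y, lam, log = TRUE)
}

#' Likelihood set of integer Poisson rates
#'
#' The set of candidate rates \eqn{\lambda} whose likelihood ratio against the
#' maximum-likelihood rate over the candidates is at least \code{alpha}:
#' \eqn{LS_\alpha = \{\lambda : l(\lambda)/l(\Lambda) \ge \alpha\}}. Because
#' the Poisson likelihood is unimodal in \eqn{\lambda} for a fixed count, the
#' result is always a contiguous integer range. The ratio is compared as a
#' log difference against \code{log(alpha)}, with the boundary included
#' (\dQuote{>=}).
#'
#' @param y Observed non-negative integer count.
#' @param candidates Contiguous non-negative integer vector of candidate
#'   rates. \code{y} itself need not be among them.
#' @param alpha Likelihood-ratio cutoff in (0, 1); default 0.1.
#' @return Integer vector, the (contiguous) subset of \code{candidates}
#'   retained.
#' @examples
#' likelihood_set(60, 40:60, alpha = 0.1)  # 45..60
#' likelihood_set(40, 40:60, alpha = 0.1)  # 40..55
#' @export
likelihood_set <- function(y, candidates, alpha = 0.1) {
  if (length(candidates) == 0L)
    stop("'candidates' must be a nonempty contiguous integer set")
  candidates <- as.integer(candidates)
  if (length(candidates) > 1L && any(diff(candidates) != 1L))
    stop("'candidates' must be contiguous integers")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single value in (0, 1)")
  if (length(y) != 1L || y < 0 || y != floor(y))
    stop("'y' must be a single non-negative integer")
  ll <- poisson_log_pmf(y, candidates)
  candidates[ll - max(ll) >= log(alpha)]
}

#' Classify one peak as plus-, minus- or double-stranded
#'
#' Applies the likelihood-set decision rule to the first-mate strand counts of
#' one methylation peak. Candidate rates are every integer from
#' \code{min(y_plus, y_minus)} to \code{max(y_plus, y_minus)}. A likelihood
#' set is built for each strand count over that shared range; if the two sets
#' intersect there is a rate plausible for both strands and the peak is called
#' \code{"both"} (double-stranded methylation), otherwise the strand with the
#' larger count wins. Equal counts always intersect, so no tie branch exists.
#'
#' Peaks whose total depth falls below \code{min_depth} (or with no reads at
#' all) are reported as \code{"unclassified"} with \code{low_depth_flag} set;
#' their likelihood sets are still computed and returned, so no peak silently
#' vanishes.
#'
#' @param y_plus,y_minus Non-negative integer counts of first-mate reads
#'   aligned forward / reverse-complement within the peak.
#' @param alpha Likelihood-ratio cutoff, default 0.1.
#' @param min_depth Minimum total first-mate depth for a confident call;
#'   default 0 (no gating).
#' @param peak_id Optional identifier carried through to the result.
#' @return An object of class \code{"likelihood_set_result"}: a list with
#'   elements \code{peak_id}, \code{y_plus}, \code{y_minus}, \code{y_total},
#'   \code{theta} (\code{y_plus/y_total}, \code{NA} when depth is 0),
#'   \code{alpha}, \code{candidate_lambdas}, \code{ls_plus}, \code{ls_minus},
#'   \code{intersection}, \code{strand_class} (one of \code{"plus"},
#'   \code{"minus"}, \code{"both"}, \code{"unclassified"}) and
#'   \code{low_depth_flag}.
#' @examples
#' classify_peak(60, 40)        # both: LS sets {45..60} and {40..55} intersect
#' classify_peak(100, 10)       # plus: sets are disjoint
#' @export
classify_peak <- function(y_plus, y_minus, alpha = 0.1, min_depth = 0,
                          peak_id = NA_character_) {
  stopifnot(length(y_plus) == 1L, length(y_minus) == 1L,
            y_plus >= 0, y_minus >= 0,
            y_plus == floor(y_plus), y_minus == floor(y_minus),
            min_depth >= 0)
  y_plus <- as.integer(y_plus)
  y_minus <- as.integer(y_minus)
  y_total <- y_plus + y_minus

  candidates <- seq.int(min(y_plus, y_minus), max(y_plus, y_minus))
  ls_plus <- likelihood_set(y_plus, candidates, alpha)
  ls_minus <- likelihood_set(y_minus, candidates, alpha)
  inter <- intersect(ls_plus, ls_minus)

  low_depth <- y_total < min_depth || y_total == 0L
  class_ <- if (low_depth) {
    "unclassified"
  } else if (length(inter) > 0L) {
    "both"
  } else if (y_plus > y_minus) {
    "plus"
  } else {
    "minus"
  }

  structure(list(
    peak_id = peak_id,
    y_plus = y_plus,
    y_minus = y_minus,
    y_total = y_total,
    theta = if (y_total > 0L) y_plus / y_total else NA_real_,
    alpha = alpha,
    candidate_lambdas = candidates,
    ls_plus = ls_plus,
    ls_minus = ls_minus,
    intersection = inter,
    strand_class = class_,
    low_depth_flag = low_depth
  ), class = "likelihood_set_result")
}

#' @export
print.likelihood_set_result <- function(x, ...) {
  rng <- function(s) if (length(s)) sprintf("{%d..%d}", min(s), max(s)) else "{}"
  cat("Likelihood-set strand classification\n")
  if (!is.na(x$peak_id)) cat("  peak:        ", x$peak_id, "\n", sep = "")
  cat(sprintf("  counts:      y+ = %d, y- = %d (total %d, theta = %s)\n",
              x$y_plus, x$y_minus, x$y_total,
              ifelse(is.na(x$theta), "NA", format(x$theta))))
  cat(sprintf("  alpha:       %g\n", x$alpha))
  cat(sprintf("  LS(plus):    %s\n", rng(x$ls_plus)))
  cat(sprintf("  LS(minus):   %s\n", rng(x$ls_minus)))
  cat(sprintf("  intersection: %s\n", rng(x$intersection)))
  cat(sprintf("  class:       %s%s\n", x$strand_class,
              if (x$low_depth_flag) " (low depth)" else ""))
  invisible(x)
}
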