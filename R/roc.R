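#' Orient continuous scores so that higher means more damaging
#'
#' Prediction tools disagree on score polarity: SIFT and PROVEAN emit low
#' scores for damaging variants, the probabilistic tools high ones. All ROC
#' machinery works on oriented scores (higher = more damaging); this
#' negates scores for \code{low_is_damaging} tools. In \code{"auto"} mode
#' the orientation giving AUC >= 0.5 against the supplied truths is chosen
#' and reported, which mirrors how ROC software auto-detects direction —
#' but note an auto-oriented AUC can never drop below 0.5, so genuinely
#' anti-predictive tools are hidden; replication configs therefore fix
#' polarity explicitly.
#'
#' @param scores Numeric scores (NA allowed).
#' @param polarity \code{"high_is_damaging"}, \code{"low_is_damaging"} or
#'   \code{"auto"}.
#' @param truths Required for \code{"auto"}:
#'   \code{"pathogenic"}/\code{"benign"} labels.
#' @return List with \code{scores} (oriented) and \code{direction} (the
#'   polarity applied).
#' @export
orient_scores <- function(scores, polarity = c("high_is_damaging",
                                               "low_is_damaging", "auto"),
                          truths = NULL) {
  polarity <- match.arg(polarity)
  if (polarity == "auto") {
    if (is.null(truths)) stop("auto orientation needs truth labels", call. = FALSE)
    a <- auc_mann_whitney(scores, truths)
    polarity <- if (is.na(a) || a >= 0.5) "high_is_damaging" else "low_is_damaging"
  }
  oriented <- if (polarity == "low_is_damaging") -scores else scores
  list(scores = oriented, direction = polarity)
}

# Tie-corrected Mann-Whitney AUC on already-oriented scores:
# P(score_pos > score_neg) + 0.5 P(equal), via midranks.
auc_mann_whitney <- function(scores, truths) {
  ok <- !is.na(scores)
  scores <- scores[ok]; truths <- truths[ok]
  pos <- truths == "pathogenic"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve with trapezoidal AUC
#'
#' Operating points are generated at every distinct oriented score plus the
#' two infinite endpoints; at threshold \eqn{t} a variant is called
#' damaging when its oriented score is \eqn{\ge t}, so curves are
#' bit-reproducible. The trapezoidal area equals the tie-corrected
#' Mann-Whitney statistic \eqn{U/(n_{pos} n_{neg})} (ties score one half),
#' and the curve runs from (0,0) to (1,1).
#'
#' @param scores Numeric scores; missing values excluded pairwise with
#'   their truths.
#' @param truths \code{"pathogenic"}/\code{"benign"} labels.
#' @param polarity Passed to [orient_scores()]; the replication default is
#'   a fixed declared polarity per tool.
#' @param stratum Label used in error messages and the result.
#' @return Object of class \code{roc_result}: list with
#'   \code{operating_points} (data.frame threshold / sensitivity /
#'   one_minus_specificity), \code{auc}, \code{direction}, \code{n_pos},
#'   \code{n_neg}, \code{stratum}.
#' @export
roc_curve <- function(scores, truths, polarity = "high_is_damaging",
                      stratum = "all") {
  ok <- !is.na(scores) & !is.na(truths)
  scores <- scores[ok]; truths <- as.character(truths)[ok]
  orn <- orient_scores(scores, polarity, truths)
  s <- orn$scores
  pos <- truths == "pathogenic"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop(sprintf("stratum '%s' has a single truth class (%d pathogenic, %d benign): ROC undefined",
                 stratum, n_pos, n_neg), call. = FALSE)
  }
  thr <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(t) sum(s >= t & pos) / n_pos, numeric(1))
  fpr  <- vapply(thr, function(t) sum(s >= t & !pos) / n_neg, numeric(1))
  auc <- auc_mann_whitney(s, truths)
  structure(
    list(operating_points = data.frame(threshold = thr, sensitivity = sens,
                                       one_minus_specificity = fpr),
         auc = auc, direction = orn$direction,
         n_pos = n_pos, n_neg = n_neg, stratum = stratum,
         oriented_scores = s, truths = truths),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result [%s]: AUC %.3f (%d pathogenic / %d benign, direction %s)\n",
              x$stratum, x$auc, x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance of the Mann-Whitney AUC through DeLong's
#' placement-value (structural components) estimator: each pathogenic
#' variant contributes the fraction of benign variants it outranks and vice
#' versa; the AUC variance is
#' \eqn{S_{10}/n_{pos} + S_{01}/n_{neg}} with the empirical variances of
#' the two placement sets. The interval is the normal approximation
#' \eqn{AUC \pm z \cdot se}, clipped to \[0, 1\]. With perfect separation
#' the variance collapses to zero and a zero-width interval is returned
#' with \code{degenerate = TRUE}.
#'
#' @param roc A [roc_curve()] result.
#' @param level Confidence level (default 0.95).
#' @return List with \code{ci_low}, \code{ci_high}, \code{se},
#'   \code{level}, \code{degenerate}.
#' @export
delong_ci <- function(roc, level = 0.95) {
  stopifnot(inherits(roc, "roc_result"))
  if (roc$n_pos < 2 || roc$n_neg < 2) {
    stop("DeLong variance needs at least 2 variants in each truth class",
         call. = FALSE)
  }
  s <- roc$oriented_scores
  pos <- roc$truths == "pathogenic"
  x <- s[pos]; y <- s[!pos]
  m <- length(x); n <- length(y)
  # midrank placements (fast O(N log N) form of the pairwise comparisons)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n          # placement of each positive
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m  # placement of each negative
  auc <- mean(v10)   # identical to the trapezoidal/Mann-Whitney value
  s10 <- stats::var(v10); s01 <- stats::var(v01)
  se <- sqrt(s10 / m + s01 / n)
  if (!is.finite(se) || se == 0) {
    if (auc %in% c(0, 1)) {
      warning("degenerate DeLong variance: perfect separation, zero-width interval")
    }
    return(list(ci_low = auc, ci_high = auc, se = 0, level = level,
                degenerate = TRUE))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(ci_low = max(0, auc - z * se), ci_high = min(1, auc + z * se),
       se = se, level = level, degenerate = FALSE)
}
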