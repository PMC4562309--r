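#' 2x2 truth table of an association rule
#'
#' Counts of genomes cross-classified by antecedent truth (rows) and
#' consequent truth (columns): `tt` antecedent and consequent both true,
#' `tf` antecedent true / consequent false, `ft` antecedent false /
#' consequent true, `ff` both false.  Every rule statistic (support,
#' confidence, Fisher significance) derives from these four counts.
#'
#' @param tt,tf,ft,ff non-negative counts.
#' @return an object of class `truth_table`.
#' @examples
#' truth_table(154, 12, 5, 1519)
#' @export
truth_table <- function(tt, tf, ft, ff) {
  x <- c(tt = tt, tf = tf, ft = ft, ff = ff)
  if (anyNA(x) || any(x < 0) || any(x != round(x)))
    stop("truth table counts must be non-negative integers")
  structure(as.list(x), class = "truth_table")
}

#' @export
as.matrix.truth_table <- function(x, ...) {
  matrix(c(x$tt, x$tf, x$ft, x$ff), nrow = 2L, byrow = TRUE,
         dimnames = list(antecedent = c("true", "false"),
                         consequent = c("true", "false")))
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("truth_table (n = %d)\n", x$tt + x$tf + x$ft + x$ff))
  print(as.matrix(x))
  invisible(x)
}

#' Rule confidence from a truth table
#'
#' The number of cases in which the rule is correct relative to the
#' number of cases in which it is applicable: `tt / (tt + tf)`.  A rule
#' that is applicable nowhere (`tt + tf == 0`) has no confidence and an
#' error is raised rather than returning 0 or NaN.
#'
#' @param t a [truth_table()].
#' @return confidence in `[0, 1]`.
#' @examples
#' rule_confidence(truth_table(154, 12, 5, 1519))
#' @export
rule_confidence <- function(t) {
  stopifnot(inherits(t, "truth_table"))
  applicable <- t$tt + t$tf
  if (applicable == 0)
    stop("rule is applicable in no genome (tt + tf = 0); confidence undefined")
  t$tt / applicable
}

#' Truth table of the opposite rule
#'
#' The opposite rule predicts the negated consequent from the same
#' antecedent, which swaps the consequent columns of the truth table:
#' `(tt, tf, ft, ff) -> (tf, tt, ff, ft)`.  A two-sided Fisher test
#' assigns the same p-value to a rule and its opposite, which is why
#' significance alone never certifies the direction of an implication.
#'
#' @param t a [truth_table()].
#' @return the swapped [truth_table()].
#' @examples
#' opposite_rule(truth_table(154, 12, 5, 1519))
#' @export
opposite_rule <- function(t) {
  stopifnot(inherits(t, "truth_table"))
  truth_table(t$tf, t$tt, t$ff, t$ft)
}
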