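#' Two-sided Fisher exact test, stable at extreme tail masses
#'
#' Exact significance of the association in a 2x2 truth table.  With both
#' margins fixed, the count `tt` follows a hypergeometric distribution;
#' the two-sided p-value is the sum of the point probabilities of all
#' tables at most as probable as the observed one (the point-probability,
#' or "minimum-likelihood", convention).  All point probabilities are
#' evaluated with `lgamma` in log space and summed with log-sum-exp, so
#' p-values far below the double underflow threshold of intermediate
#' factorials (e.g. 1e-196 on a 1690-genome table) are exact; the
#' comparison "at most as probable" uses a relative tolerance of 1e-12 to
#' avoid floating-point boundary flips.  A degenerate table (an empty row
#' or column margin) carries no information and returns p = 1 with
#' `degenerate = TRUE`.
#'
#' The two-sided convention has the property that a rule and its opposite
#' (see [opposite_rule()]), as well as the transposed table, receive the
#' same p-value.
#'
#' @param t a [truth_table()].
#' @return object of class `fisher_result`: list with `p` in `(0, 1]`,
#'   `log10_p` (exact even when `p` underflows), and `degenerate`.
#' @examples
#' fisher_exact_two_sided(truth_table(154, 12, 5, 1519))
#' fisher_exact_two_sided(truth_table(10, 10, 10, 10))  # p = 1
#' @export
fisher_exact_two_sided <- function(t) {
  stopifnot(inherits(t, "truth_table"))
  r <- fisher_exact_counts(t$tt, t$tf, t$ft, t$ff)
  structure(list(p = r$p, log10_p = r$log10_p, degenerate = r$degenerate),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("p = %s (log10 p = %.6f)%s\n", format_p_printed(x$log10_p),
              x$log10_p, if (x$degenerate) " [degenerate table]" else ""))
  invisible(x)
}

## Vectorised core over parallel count vectors; returns list(p, log10_p,
## degenerate).  Used by fisher_exact_two_sided() and generate_rules().
fisher_exact_counts <- function(tt, tf, ft, ff) {
  nr <- length(tt)
  p <- numeric(nr); l10 <- numeric(nr); degen <- logical(nr)
  for (i in seq_len(nr)) {
    a <- tt[i]; b <- tf[i]; c <- ft[i]; d <- ff[i]
    if (anyNA(c(a, b, c, d)) || any(c(a, b, c, d) < 0))
      stop("counts must be non-negative")
    n <- a + b + c + d
    if (n == 0) stop("empty table (total count 0)")
    r1 <- a + b; c1 <- a + c
    if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
      p[i] <- 1; l10[i] <- 0; degen[i] <- TRUE
      next
    }
    r2 <- n - r1
    lo <- max(0, c1 - r2); hi <- min(r1, c1)
    x <- lo:hi
    lp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
    lobs <- lp[a - lo + 1L]
    keep <- lp <= lobs + log1p(1e-12)
    mx <- max(lp[keep])
    lsum <- mx + log(sum(exp(lp[keep] - mx)))
    lsum <- min(lsum, 0)
    l10[i] <- lsum / log(10)
    p[i] <- exp(lsum)
  }
  list(p = p, log10_p = l10, degenerate = degen)
}

#' Rank association rules
#'
#' Orders a rule table by confidence (descending), breaking ties by
#' p-value (ascending), antecedent size (ascending), and finally the
#' antecedent label (lexicographic), so the ranking is fully
#' deterministic.
#'
#' @param rules rule `data.frame` from [generate_rules()] (columns
#'   `confidence`, `log10_p` or `p`, `size`, `antecedent`).
#' @return the same `data.frame`, reordered, with a `rank` column
#'   prepended.
#' @export
rank_rules <- function(rules) {
  stopifnot(is.data.frame(rules), "confidence" %in% names(rules))
  pkey <- if ("log10_p" %in% names(rules)) rules$log10_p else rules$p
  if (is.null(pkey)) pkey <- rep(0, nrow(rules))
  size <- if ("size" %in% names(rules)) rules$size else
    lengths(lapply(rules$antecedent, parse_itemset))
  ord <- order(-rules$confidence, pkey, size, rules$antecedent,
               method = "radix")
  out <- rules[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Pairwise co-occurrence of gene families
#'
#' The classical pairwise phylogenetic-profile baseline: for every
#' unordered pair of families, the 2x2 presence/absence table, its
#' two-sided Fisher p-value, and the direction of the association --
#' positive when the observed co-presence count exceeds the expectation
#' under independence, negative when it falls short (0 when exactly
#' equal, as for a degenerate margin).
#'
#' @param m a [profile_matrix()] with at least two families.
#' @return `data.frame` with columns `family_a`, `family_b`, `both`,
#'   `a_only`, `b_only`, `neither`, `p`, `log10_p`, `sign`.
#' @export
pairwise_cooccurrence <- function(m) {
  stopifnot(inherits(m, "profile_matrix"))
  fams <- family_ids(m)
  if (length(fams) < 2L) stop("need at least two families")
  occ <- m$occurrence
  n <- nrow(occ)
  cross <- crossprod(occ)           # co-presence counts
  tot <- diag(cross)
  pairs <- utils::combn(seq_along(fams), 2L)
  np <- ncol(pairs)
  both <- integer(np); ao <- integer(np); bo <- integer(np); ne <- integer(np)
  sgn <- integer(np)
  for (k in seq_len(np)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    both[k] <- cross[i, j]
    ao[k] <- tot[i] - both[k]
    bo[k] <- tot[j] - both[k]
    ne[k] <- n - tot[i] - tot[j] + both[k]
    sgn[k] <- sign(both[k] * n - tot[i] * tot[j])
  }
  fr <- fisher_exact_counts(both, ao, bo, ne)
  data.frame(family_a = fams[pairs[1L, ]], family_b = fams[pairs[2L, ]],
             both = both, a_only = ao, b_only = bo, neither = ne,
             p = fr$p, log10_p = fr$log10_p, sign = sgn,
             row.names = NULL, stringsAsFactors = FALSE)
}
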