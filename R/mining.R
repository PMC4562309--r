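#' Support of an item set
#'
#' Number of genomes in which every literal of the set is true.  The
#' empty set is a vacuous conjunction and has support equal to the genome
#' count.
#'
#' @param m a [profile_matrix()].
#' @param s character vector of literals (see [itemset()]); validated for
#'   contradictions.
#' @return integer count.
#' @examples
#' occ <- matrix(c(1,0, 1,1, 0,1, 0,0), nrow = 4, byrow = TRUE,
#'               dimnames = list(paste0("g", 1:4), c("a", "b")))
#' itemset_support(profile_matrix(occ), c("a", "!b"))
#' @export
itemset_support <- function(m, s) {
  stopifnot(inherits(m, "profile_matrix"))
  s <- itemset(s)
  if (length(s) == 0L) return(n_genomes(m))
  lit <- literal_columns(m, s)
  sum(rowSums(lit) == length(s))
}

## Shared level-wise Apriori engine over a packed literal universe.
## universe: character literals in canonical order; packed: word matrix.
## Returns list(idx = list of integer index vectors, support = integer,
## words = list of packed intersections), ordered by (size, lexicographic
## index order).
apriori_engine <- function(universe, packed, min_support, max_size,
                           families) {
  key_of <- function(idx) paste(idx, collapse = " ")
  seen <- new.env(parent = emptyenv(), size = 4096L)

  keep1 <- integer(0); words1 <- list(); supp1 <- integer(0)
  for (j in seq_along(universe)) {
    sp <- popcount_words(packed[, j])
    if (sp >= min_support) {
      keep1 <- c(keep1, j)
      words1[[length(words1) + 1L]] <- packed[, j]
      supp1 <- c(supp1, sp)
    }
  }
  idx <- lapply(keep1, function(j) j)
  for (i in seq_along(idx)) assign(key_of(idx[[i]]), TRUE, envir = seen)
  out_idx <- idx; out_supp <- supp1; out_words <- words1
  level_idx <- idx; level_words <- words1

  k <- 1L
  while (k < max_size && length(level_idx) > 1L) {
    prefix <- vapply(level_idx, function(v) key_of(v[-length(v)]), "")
    last <- vapply(level_idx, function(v) v[length(v)], 0L)
    groups <- split(seq_along(level_idx), factor(prefix, levels = unique(prefix)))
    new_idx <- list(); new_words <- list(); new_supp <- integer(0)
    for (grp in groups) {
      if (length(grp) < 2L) next
      for (ii in seq_len(length(grp) - 1L)) {
        i <- grp[ii]
        for (jj in seq((ii + 1L), length(grp))) {
          j <- grp[jj]
          a <- last[i]; b <- last[j]
          if (families[a] == families[b]) next  # contradictory pair
          cand <- c(level_idx[[i]], b)
          if (k >= 2L) {  # prune: every k-subset must be frequent
            ok <- TRUE
            for (drop in seq_len(k - 1L)) {
              if (!exists(key_of(cand[-drop]), envir = seen, inherits = FALSE)) {
                ok <- FALSE; break
              }
            }
            if (!ok) next
          }
          w <- bitwAnd(level_words[[i]], packed[, b])
          sp <- popcount_words(w)
          if (sp >= min_support) {
            new_idx[[length(new_idx) + 1L]] <- cand
            new_words[[length(new_words) + 1L]] <- w
            new_supp <- c(new_supp, sp)
          }
        }
      }
    }
    if (!length(new_idx)) break
    ord <- order(vapply(new_idx, function(v)
      paste(sprintf("%06d", v), collapse = " "), ""), method = "radix")
    new_idx <- new_idx[ord]; new_words <- new_words[ord]
    new_supp <- new_supp[ord]
    for (v in new_idx) assign(key_of(v), TRUE, envir = seen)
    out_idx <- c(out_idx, new_idx)
    out_supp <- c(out_supp, new_supp)
    out_words <- c(out_words, new_words)
    level_idx <- new_idx; level_words <- new_words
    k <- k + 1L
  }
  list(idx = out_idx, support = out_supp, words = out_words)
}

## Canonicalise a literal universe against a matrix; returns list with
## the ordered universe, its packed columns and family vector.
prepare_universe <- function(m, literal_universe) {
  if (is.null(literal_universe)) {
    fams <- family_ids(m)
    literal_universe <- c(fams, paste0("!", fams))
  }
  literal_universe <- unique(literal_universe)
  literal_universe <- literal_universe[literal_order(literal_universe)]
  if (length(literal_universe) == 0L)
    stop("empty literal universe")
  cols <- literal_columns(m, literal_universe)
  list(universe = literal_universe,
       packed = pack_columns(cols),
       families = literal_family(literal_universe))
}

#' Mine frequent literal sets (Apriori)
#'
#' Level-wise enumeration of all contradiction-free literal sets of size
#' at most `max_size` whose support (number of genomes satisfying every
#' literal) is at least `min_support`.  Candidate generation joins
#' frequent sets sharing a prefix, drops pairs of opposite literals of
#' the same family, and prunes candidates with an infrequent subset
#' (support is anti-monotonic).  Output order is deterministic: by set
#' size, then lexicographic in canonical literal order.
#'
#' @param m a [profile_matrix()].
#' @param min_support minimum genome count, `>= 1`.
#' @param max_size maximum literals per set, `>= 1`.
#' @param literal_universe character vector of literals to mine over;
#'   default: presence and absence literals of every family.
#' @return `data.frame` with list column `items`, and columns `label`,
#'   `size`, `support`.
#' @examples
#' occ <- matrix(rbinom(24, 1, 0.5), nrow = 6,
#'               dimnames = list(paste0("g", 1:6), c("a", "b", "c", "d")))
#' mine_frequent_itemsets(profile_matrix(occ), min_support = 2, max_size = 2)
#' @export
mine_frequent_itemsets <- function(m, min_support, max_size,
                                   literal_universe = NULL) {
  stopifnot(inherits(m, "profile_matrix"),
            length(min_support) == 1L, min_support >= 1,
            length(max_size) == 1L, max_size >= 1)
  u <- prepare_universe(m, literal_universe)
  res <- apriori_engine(u$universe, u$packed, min_support, max_size,
                        u$families)
  items <- lapply(res$idx, function(v) u$universe[v])
  data.frame(
    items = I(items),
    label = vapply(items, format_itemset, ""),
    size = lengths(items),
    support = res$support,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Truth table of a rule on a profile matrix
#'
#' Scores the rule "antecedent implies consequent" in every genome and
#' counts the four outcomes.  An empty antecedent is vacuously true, so
#' all genomes fall in the `tt`/`tf` row.
#'
#' @param m a [profile_matrix()].
#' @param antecedent character vector of literals (may be empty).
#' @param consequent single literal.
#' @return a [truth_table()].
#' @export
rule_truth_table <- function(m, antecedent, consequent) {
  stopifnot(inherits(m, "profile_matrix"), length(consequent) == 1L)
  antecedent <- itemset(antecedent)
  if (literal_family(consequent) %in% literal_family(antecedent))
    stop("consequent family also appears in the antecedent")
  cons <- literal_columns(m, consequent)[, 1L] == 1L
  ant <- if (length(antecedent) == 0L) {
    rep(TRUE, n_genomes(m))
  } else {
    lit <- literal_columns(m, antecedent)
    rowSums(lit) == length(antecedent)
  }
  truth_table(sum(ant & cons), sum(ant & !cons),
              sum(!ant & cons), sum(!ant & !cons))
}

#' Generate association rules with a fixed consequent
#'
#' Mines frequent antecedent item sets (the consequent's family is
#' excluded from the antecedent universe), emits one rule per frequent
#' set, computes each rule's full 2x2 truth table, and keeps rules whose
#' confidence `tt / (tt + tf)` reaches `min_confidence`.  `min_support`
#' applies to the antecedent item set (the number of genomes where the
#' rule is applicable); the reported rule `support` is `tt`, the number
#' of genomes where the rule is applicable and correct.  Fisher
#' significance is attached with [fisher_exact_two_sided()].
#'
#' @param m a [profile_matrix()].
#' @param consequent single literal, positive unless
#'   `allow_negated_consequent = TRUE`.
#' @param min_support minimum antecedent support; default
#'   `max(2, ceiling(0.005 * n_genomes(m)))`.
#' @param max_antecedent maximum antecedent size (default 5).
#' @param min_confidence minimum confidence in `[0, 1]` (default 0).
#' @param literal_universe optional antecedent literal universe; the
#'   consequent's family is removed from it automatically.
#' @param compute_p attach Fisher p-values (default `TRUE`).
#' @param allow_negated_consequent permit an absence literal as
#'   consequent (default `FALSE`).
#' @return `data.frame` with columns `antecedent` (label), a list column
#'   `items`, `consequent`, `size`, `tt`, `tf`, `ft`, `ff`, `support`,
#'   `confidence`, and (if `compute_p`) `p` and `log10_p`.
#' @examples
#' occ <- matrix(c(1,1,1, 1,1,1, 0,0,1, 0,0,0), nrow = 4, byrow = TRUE,
#'               dimnames = list(paste0("g", 1:4), c("a", "b", "c")))
#' generate_rules(profile_matrix(occ), "c", min_support = 2,
#'                max_antecedent = 2)
#' @export
generate_rules <- function(m, consequent, min_support = NULL,
                           max_antecedent = 5, min_confidence = 0,
                           literal_universe = NULL, compute_p = TRUE,
                           allow_negated_consequent = FALSE) {
  stopifnot(inherits(m, "profile_matrix"), length(consequent) == 1L,
            min_confidence >= 0, min_confidence <= 1, max_antecedent >= 1)
  if (literal_negated(consequent) && !allow_negated_consequent)
    stop("negated consequent '", consequent,
         "' requires allow_negated_consequent = TRUE")
  cons_fam <- literal_family(consequent)
  if (!cons_fam %in% family_ids(m))
    stop("consequent family not in matrix: ", cons_fam)
  if (is.null(min_support))
    min_support <- max(2L, ceiling(0.005 * n_genomes(m)))
  u <- prepare_universe(m, literal_universe)
  keep <- u$families != cons_fam
  if (!any(keep)) stop("empty antecedent literal universe")
  u$universe <- u$universe[keep]
  u$packed <- u$packed[, keep, drop = FALSE]
  u$families <- u$families[keep]

  res <- apriori_engine(u$universe, u$packed, min_support, max_antecedent,
                        u$families)
  n <- n_genomes(m)
  cons_words <- pack_columns(literal_columns(m, consequent))[, 1L]
  cons_total <- popcount_words(cons_words)
  nr <- length(res$idx)
  tt <- integer(nr)
  for (i in seq_len(nr))
    tt[i] <- popcount_words(bitwAnd(res$words[[i]], cons_words))
  applicable <- res$support
  tf <- applicable - tt
  ft <- cons_total - tt
  ff <- n - applicable - ft
  confidence <- tt / applicable
  sel <- confidence >= min_confidence
  items <- lapply(res$idx[sel], function(v) u$universe[v])
  out <- data.frame(
    antecedent = vapply(items, format_itemset, ""),
    items = I(items),
    consequent = rep_len(consequent, length(items)),
    size = lengths(items),
    tt = tt[sel], tf = tf[sel], ft = ft[sel], ff = ff[sel],
    support = tt[sel],
    confidence = confidence[sel],
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (compute_p && nrow(out)) {
    fr <- fisher_exact_counts(out$tt, out$tf, out$ft, out$ff)
    out$p <- fr$p
    out$log10_p <- fr$log10_p
  } else if (compute_p) {
    out$p <- numeric(0)
    out$log10_p <- numeric(0)
  }
  out
}
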