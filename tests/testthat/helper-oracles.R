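# Brute-force oracles and fixture builders shared across the suite.
# Every oracle evaluates its quantity by direct enumeration / row scan,
# independently of the package's bit-packed mining and log-space Fisher
# paths.

make_profile <- function(cells, genomes = NULL, families = NULL) {
  occ <- as.matrix(cells)
  if (is.null(genomes)) genomes <- sprintf("g%02d", seq_len(nrow(occ)))
  if (is.null(families)) families <- sprintf("f%02d", seq_len(ncol(occ)))
  dimnames(occ) <- list(genomes, families)
  profile_matrix(occ)
}

random_profile <- function(n, nfam, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  occ <- matrix(rbinom(n * nfam, 1L, p), n, nfam)
  make_profile(occ)
}

# TRUE/FALSE per genome for a literal vector, by plain row scan
oracle_holds <- function(m, lits) {
  occ <- m$occurrence
  if (length(lits) == 0L) return(rep(TRUE, nrow(occ)))
  res <- rep(TRUE, nrow(occ))
  for (l in lits) {
    fam <- sub("^!", "", l)
    v <- occ[, fam] == 1L
    if (startsWith(l, "!")) v <- !v
    res <- res & v
  }
  res
}

# all contradiction-free subsets of a literal universe, sizes 1..max_size
oracle_enumerate_itemsets <- function(universe, max_size) {
  out <- list()
  for (k in seq_len(min(max_size, length(universe)))) {
    combos <- utils::combn(universe, k, simplify = FALSE)
    for (s in combos) {
      fams <- sub("^!", "", s)
      if (anyDuplicated(fams)) next
      out[[length(out) + 1L]] <- s
    }
  }
  out
}

# reference frequent-itemset miner: full enumeration + row scan
oracle_frequent <- function(m, min_support, max_size, universe = NULL) {
  if (is.null(universe)) {
    fams <- family_ids(m)
    universe <- c(fams, paste0("!", fams))
  }
  sets <- oracle_enumerate_itemsets(universe, max_size)
  keep <- list(); supp <- integer(0)
  for (s in sets) {
    sp <- sum(oracle_holds(m, s))
    if (sp >= min_support) {
      keep[[length(keep) + 1L]] <- itemset(s)
      supp <- c(supp, sp)
    }
  }
  lab <- vapply(keep, paste, "", collapse = "&")
  ord <- order(lengths(keep), lab, method = "radix")
  data.frame(label = lab[ord], support = supp[ord],
             stringsAsFactors = FALSE)
}

# reference rule generator over all contradiction-free antecedents
oracle_rules <- function(m, consequent, min_support, max_antecedent,
                         min_confidence) {
  fams <- setdiff(family_ids(m), sub("^!", "", consequent))
  universe <- c(fams, paste0("!", fams))
  sets <- oracle_enumerate_itemsets(universe, max_antecedent)
  cons <- oracle_holds(m, consequent)
  rows <- list()
  for (s in sets) {
    ant <- oracle_holds(m, s)
    app <- sum(ant)
    if (app < min_support) next
    tt <- sum(ant & cons)
    conf <- tt / app
    if (conf < min_confidence) next
    rows[[length(rows) + 1L]] <- data.frame(
      antecedent = paste(itemset(s), collapse = "&"),
      tt = tt, tf = app - tt, ft = sum(!ant & cons),
      ff = sum(!ant & !cons), confidence = conf,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  df[order(df$antecedent, method = "radix"), , drop = FALSE]
}

# reference two-sided Fisher p: direct sum of dhyper point masses
# (no log-space, no lgamma path shared with the implementation)
oracle_fisher <- function(tt, tf, ft, ff, tol = 1e-12) {
  r1 <- tt + tf; r2 <- ft + ff; c1 <- tt + ft
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  x <- max(0, c1 - r2):min(r1, c1)
  px <- dhyper(x, c1, n - c1, r1)
  pobs <- dhyper(tt, c1, n - c1, r1)
  min(1, sum(px[px <= pobs * (1 + tol)]))
}

random_truth_table <- function(max_cell = 60) {
  truth_table(sample.int(max_cell, 1L), sample.int(max_cell, 1L),
              sample.int(max_cell, 1L), sample.int(max_cell, 1L))
}
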