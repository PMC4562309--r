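#' Published urate-oxidase rule table (packaged fixture)
#'
#' The six association rules implicating COG3748 (*puuD*) as consequent,
#' with their printed 2x2 truth tables over 1690 complete genomes,
#' confidences and one-significant-digit p-values, as shipped in
#' `inst/extdata/table1_rules.tsv`.  The antecedents are nested: each
#' row's literal set contains the next row's.  These truth tables are
#' the reference fixture for confidence, significance and ranking
#' checks.
#'
#' @return `data.frame` with columns `antecedent`, a list column `items`
#'   (parsed literals), `consequent`, `tt`, `tf`, `ft`, `ff`,
#'   `confidence` and `p_printed`, one row per rule in published order.
#' @examples
#' fx <- table1_fixture()
#' fx$tt + fx$tf + fx$ft + fx$ff  # every row totals the same genome count
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_rules.tsv", package = "profrules",
                      mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8",
                          colClasses = c(antecedent = "character",
                                         consequent = "character",
                                         p_printed = "character"))
  df$items <- I(lapply(df$antecedent, parse_itemset))
  df[, c("antecedent", "items", "consequent", "tt", "tf", "ft", "ff",
         "confidence", "p_printed")]
}

#' The planted highest-confidence rule of a simulator configuration
#'
#' For a chosen alternative family `consequent`, the generative model of
#' [pathway_sim_config()] plants the implication "all downstream genes
#' present and all other alternatives absent implies `consequent`".
#' Returns that antecedent as a canonical item set.
#'
#' @param cfg a [pathway_sim_config()].
#' @param consequent name of one alternative family of `cfg`.
#' @return character vector of literals.
#' @examples
#' planted_rule_antecedent(pathway_sim_config(), "puuD")
#' @export
planted_rule_antecedent <- function(cfg, consequent) {
  stopifnot(inherits(cfg, "pathway_sim_config"))
  if (!consequent %in% names(cfg$weights))
    stop("'", consequent, "' is not an alternative family of this config")
  others <- setdiff(names(cfg$weights), consequent)
  itemset(c(cfg$downstream, paste0("!", others)))
}

#' Planted-rule recovery experiment
#'
#' Simulates `n_runs` independent matrices from `cfg`, mines rules with
#' the given thresholds and consequent, ranks them, and reports for each
#' run whether the top-ranked rule is exactly the planted rule (see
#' [planted_rule_antecedent()]).  The support floor defaults to 7.5% of
#' the genomes -- below the planted rule's expected applicability
#' (about 9.4% under the default configuration) but high enough to
#' exclude the low-support, high-variance antecedents that dominate the
#' top of a confidence ranking by chance.
#'
#' @param cfg a [pathway_sim_config()].
#' @param consequent alternative family to mine towards.
#' @param n_runs number of simulated matrices.
#' @param seed integer; run `i` uses seed `seed + i - 1`.
#' @param min_support,min_confidence,max_antecedent mining thresholds.
#' @return logical vector of length `n_runs`: planted rule top-ranked.
#' @export
planted_rule_recovery <- function(cfg, consequent = "puuD", n_runs = 100,
                                  seed = 1,
                                  min_support = ceiling(0.075 * cfg$n_genomes),
                                  min_confidence = 0.5,
                                  max_antecedent = 5) {
  stopifnot(inherits(cfg, "pathway_sim_config"))
  planted <- format_itemset(planted_rule_antecedent(cfg, consequent))
  vapply(seq_len(n_runs), function(i) {
    m <- simulate_pathway_profiles(cfg, seed = seed + i - 1L)
    rules <- generate_rules(m, consequent, min_support = min_support,
                            max_antecedent = max_antecedent,
                            min_confidence = min_confidence)
    if (nrow(rules) == 0L) return(FALSE)
    ranked <- rank_rules(rules)
    ranked$antecedent[1L] == planted
  }, logical(1L))
}
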