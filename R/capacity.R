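#' Filter genomes by a boolean expression over gene families
#'
#' Selects the genomes in which a logical expression over family presence
#' evaluates to `TRUE`.  Family identifiers act as logical variables
#' (`TRUE` = present); expressions may combine them with `&`, `|`, `!`
#' and parentheses, e.g. `(urah & urad) | uox`.  Genome order is
#' preserved.  The expression can be given as a one-sided formula, a
#' quoted call, or a character string; every name it mentions must be a
#' family of the matrix.
#'
#' @param m a [profile_matrix()].
#' @param expr one-sided formula (`~ (urah & urad) | uox`), quoted call,
#'   character string, or a single logical constant.
#' @return the `profile_matrix` restricted to the selected genomes.
#' @examples
#' occ <- matrix(c(1,1,0, 0,0,1, 1,0,0), nrow = 3, byrow = TRUE,
#'               dimnames = list(paste0("g", 1:3), c("urah","urad","uox")))
#' m <- profile_matrix(occ)
#' genome_ids(filter_genomes(m, ~ (urah & urad) | uox))
#' @export
filter_genomes <- function(m, expr) {
  stopifnot(inherits(m, "profile_matrix"))
  e <- if (inherits(expr, "formula")) {
    expr[[length(expr)]]
  } else if (is.character(expr)) {
    str2lang(expr)
  } else if (is.call(expr) || is.name(expr) || is.logical(expr)) {
    expr
  } else stop("'expr' must be a formula, call, string or logical constant")
  if (is.logical(e)) {
    stopifnot(length(e) == 1L, !is.na(e))
    return(if (e) m else subset_genomes(m, logical(nrow(m$occurrence))))
  }
  vars <- all.vars(e)
  unknown <- setdiff(vars, family_ids(m))
  if (length(unknown))
    stop("unknown family id(s) in expression: ",
         paste(unknown, collapse = ", "))
  env <- list2env(setNames(
    lapply(vars, function(v) m$occurrence[, v] == 1L), vars),
    parent = baseenv())
  keep <- eval(e, env)
  if (!is.logical(keep) || length(keep) != nrow(m$occurrence) || anyNA(keep))
    stop("expression did not evaluate to one logical value per genome")
  subset_genomes(m, keep)
}

#' Capacity scheme: downstream genes and alternative explainer genes
#'
#' Describes the logic of a pathway whose first reaction step can be
#' carried out by any one of several non-homologous enzymes
#' ("explainers"), while later steps are shared ("downstream" genes).  In
#' the urate oxidation pathway the downstream genes are *urah* (HIU
#' hydrolase) and *urad* (OHCU decarboxylase) and the explainers are the
#' alternative urate oxidases *uox*, *hpxO*, *hpyO* and COG3748 (*puuD*).
#'
#' @param downstream character vector of downstream family ids.
#' @param explainers character vector of alternative first-step family
#'   ids; order is kept for reporting.
#' @return an object of class `capacity_scheme`.
#' @export
capacity_scheme <- function(downstream = c("urah", "urad"),
                            explainers = c("uox", "hpxO", "hpyO", "COG3748")) {
  stopifnot(is.character(downstream), length(downstream) >= 1L,
            is.character(explainers), length(explainers) >= 1L)
  if (length(intersect(downstream, explainers)))
    stop("downstream and explainer families must be disjoint")
  structure(list(downstream = downstream, explainers = explainers),
            class = "capacity_scheme")
}

#' Classify genomes by pathway capacity
#'
#' For every genome reports the set of explainer families present, and
#' two flags: `unexplained` -- all downstream genes present but no
#' explainer (the residue class pointing at a still-missing gene) -- and
#' `downstream_incomplete` -- some but not all downstream genes present.
#' Genomes carrying several explainers keep all of them (multi-label; no
#' priority is imposed).
#'
#' @param m a [profile_matrix()].
#' @param scheme a [capacity_scheme()].
#' @return `data.frame` with one row per genome: `genome_id`, a list
#'   column `labels` (explainer names plus flags), `n_explainers`,
#'   `unexplained`, `downstream_incomplete`.
#' @export
classify_capacity <- function(m, scheme) {
  stopifnot(inherits(m, "profile_matrix"), inherits(scheme, "capacity_scheme"))
  fams <- c(scheme$downstream, scheme$explainers)
  missing <- setdiff(fams, family_ids(m))
  if (length(missing))
    stop("scheme family missing from matrix: ", paste(missing, collapse = ", "))
  down <- m$occurrence[, scheme$downstream, drop = FALSE] == 1L
  expl <- m$occurrence[, scheme$explainers, drop = FALSE] == 1L
  all_down <- rowSums(down) == length(scheme$downstream)
  any_down <- rowSums(down) > 0L
  n_expl <- rowSums(expl)
  unexplained <- all_down & n_expl == 0L
  incomplete <- any_down & !all_down
  labels <- lapply(seq_len(nrow(expl)), function(i) {
    l <- scheme$explainers[expl[i, ]]
    if (unexplained[i]) l <- c(l, "unexplained")
    if (incomplete[i]) l <- c(l, "downstream_incomplete")
    l
  })
  data.frame(genome_id = genome_ids(m),
             labels = I(labels),
             n_explainers = n_expl,
             unexplained = unexplained,
             downstream_incomplete = incomplete,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-tabulate capacity labels against a metadata grouping
#'
#' Counts capacity labels (see [classify_capacity()]) within groups
#' defined by a per-genome metadata key, e.g. monoderm vs diderm membrane
#' class.  A genome carrying several labels is counted once per label;
#' genomes without a value for the key are grouped as `"unknown"`.
#'
#' @param m a [profile_matrix()].
#' @param scheme a [capacity_scheme()].
#' @param group_key name of a metadata column; `NULL` pools all genomes
#'   into a single `"all"` group.
#' @return a contingency `table` of label x group.
#' @export
summarize_by_class <- function(m, scheme, group_key = NULL) {
  cls <- classify_capacity(m, scheme)
  group <- if (is.null(group_key)) {
    rep("all", n_genomes(m))
  } else {
    if (is.null(m$metadata) || !group_key %in% names(m$metadata))
      stop("metadata column '", group_key, "' not found")
    g <- as.character(m$metadata[[group_key]])
    g[is.na(g) | g == ""] <- "unknown"
    g
  }
  nlab <- lengths(cls$labels)
  tab <- table(label = unlist(cls$labels),
               group = rep(group, nlab))
  tab
}

#' Order genome identifiers by the leaf order of a species tree
#'
#' Returns the genome identifiers reordered to follow the tips of a
#' phylogenetic tree as drawn (cladewise traversal).  Genomes absent from
#' the tree are appended last in their input order, with a warning that
#' lists them.
#'
#' @param ids character vector of genome identifiers.
#' @param tree an [ape::read.tree()] `phylo` object, or a path to a
#'   Newick file.
#' @return reordered character vector, same length as `ids`.
#' @export
order_genomes_by_tree <- function(ids, tree) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  tr <- ape::reorder.phylo(tree, "cladewise")
  tips <- tr$edge[, 2L][tr$edge[, 2L] <= length(tr$tip.label)]
  leaf_order <- tr$tip.label[tips]
  matched <- leaf_order[leaf_order %in% ids]
  unmatched <- setdiff(ids, leaf_order)
  if (length(unmatched))
    warning("genome(s) absent from tree, appended in input order: ",
            paste(utils::head(unmatched, 10L), collapse = ", "))
  c(matched, ids[ids %in% unmatched])
}
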