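#' Binary genome x gene-family profile matrix
#'
#' The container for phylogenetic profiles: a genomes x families matrix of
#' 0/1 occurrence calls plus optional per-genome metadata (species name,
#' membrane class, ...).  Every cell must be exactly 0 or 1 -- missing
#' values are rejected rather than imputed, because silent imputation
#' would corrupt downstream rule counts.
#'
#' @param occurrence numeric or logical matrix with unique row names
#'   (genome identifiers) and unique column names (family identifiers);
#'   all cells 0 or 1.
#' @param metadata optional `data.frame` of per-genome annotations, either
#'   with row names matching the genome identifiers or with a `genome_id`
#'   column.
#' @return an object of class `profile_matrix`.
#' @examples
#' occ <- matrix(c(1, 0, 1, 0, 0, 1), nrow = 2, byrow = TRUE,
#'               dimnames = list(c("gA", "gB"), c("urah", "urad", "uox")))
#' profile_matrix(occ)
#' @export
profile_matrix <- function(occurrence, metadata = NULL) {
  if (!is.matrix(occurrence))
    stop("'occurrence' must be a matrix")
  if (is.logical(occurrence)) storage.mode(occurrence) <- "integer"
  if (anyNA(occurrence))
    stop("occurrence matrix contains missing values; cells must be 0 or 1")
  if (!all(occurrence %in% c(0, 1)))
    stop("occurrence matrix contains non-binary cells; cells must be 0 or 1")
  storage.mode(occurrence) <- "integer"
  gid <- rownames(occurrence)
  if (is.null(gid) && nrow(occurrence) == 0L) gid <- character(0)
  fid <- colnames(occurrence)
  if (is.null(gid) || is.null(fid))
    stop("occurrence matrix must carry genome row names and family column names")
  if (ncol(occurrence) == 0L)
    stop("empty profile matrix (no families)")
  if (anyDuplicated(gid))
    stop("duplicate genome id: '", gid[duplicated(gid)][1L], "'")
  if (anyDuplicated(fid))
    stop("duplicate family id: '", fid[duplicated(fid)][1L], "'")
  if (any(startsWith(fid, "!")))
    stop("family ids must not start with '!' (reserved for negation literals)")
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if ("genome_id" %in% names(metadata)) {
      rownames(metadata) <- metadata$genome_id
    }
    missing <- setdiff(gid, rownames(metadata))
    if (length(missing))
      stop("metadata lacks rows for genomes: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    metadata <- metadata[gid, , drop = FALSE]
  }
  structure(list(occurrence = occurrence, metadata = metadata),
            class = "profile_matrix")
}

#' @rdname profile_matrix
#' @param m a `profile_matrix`.
#' @export
genome_ids <- function(m) rownames(m$occurrence) %||% character(0)

#' @rdname profile_matrix
#' @export
family_ids <- function(m) colnames(m$occurrence)

#' @rdname profile_matrix
#' @export
n_genomes <- function(m) nrow(m$occurrence)

#' @export
dim.profile_matrix <- function(x) dim(x$occurrence)

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d genomes x %d families\n",
              nrow(x$occurrence), ncol(x$occurrence)))
  cat("families:", paste(utils::head(family_ids(x), 8L), collapse = ", "),
      if (ncol(x$occurrence) > 8L) "..." else "", "\n")
  if (!is.null(x$metadata))
    cat("metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

## row subset preserving metadata and order
subset_genomes <- function(m, keep) {
  occ <- m$occurrence[keep, , drop = FALSE]
  md <- if (is.null(m$metadata)) NULL else m$metadata[keep, , drop = FALSE]
  profile_matrix(occ, md)
}

#' Keep the first genome per species
#'
#' Optional deduplication for matrices in which several genomes belong to
#' the same species: keeps the first genome (input order) for every
#' distinct value of `species_key` in the metadata.  Off unless called
#' explicitly; a message reports how many genomes were dropped.
#'
#' @param m a [profile_matrix()].
#' @param species_key metadata column holding the species assignment.
#' @return a `profile_matrix` with one genome per species.
#' @export
dedupe_species <- function(m, species_key = "species") {
  if (is.null(m$metadata) || !species_key %in% names(m$metadata))
    stop("metadata column '", species_key, "' not found")
  keep <- !duplicated(m$metadata[[species_key]])
  if (any(!keep))
    message("dedupe_species: dropped ", sum(!keep),
            " genome(s) with a duplicated '", species_key, "' value")
  subset_genomes(m, keep)
}

#' Augment a profile matrix with negation literals
#'
#' Expands the occurrence matrix into a literal matrix with two columns
#' per family: the presence literal and its logical negation.  For every
#' genome and family the pair of columns sums to exactly 1.  This is the
#' input representation for rule mining with absence literals.
#'
#' @param m a [profile_matrix()].
#' @return integer matrix with `2 * n_families` columns named
#'   `f` and `!f` for every family `f`, in canonical literal order.
#' @examples
#' occ <- matrix(c(1L, 0L), ncol = 1,
#'               dimnames = list(c("gA", "gB"), "uox"))
#' augment_with_negations(profile_matrix(occ))
#' @export
augment_with_negations <- function(m) {
  stopifnot(inherits(m, "profile_matrix"))
  occ <- m$occurrence
  neg <- 1L - occ
  colnames(neg) <- paste0("!", colnames(occ))
  lit <- cbind(occ, neg)
  lit[, literal_order(colnames(lit)), drop = FALSE]
}

## literal columns for an arbitrary literal universe, in the given order
literal_columns <- function(m, literals) {
  fam <- literal_family(literals)
  unknown <- setdiff(fam, family_ids(m))
  if (length(unknown))
    stop("unknown family id(s): ", paste(unknown, collapse = ", "))
  occ <- m$occurrence[, fam, drop = FALSE]
  neg <- literal_negated(literals)
  if (any(neg)) occ[, neg] <- 1L - occ[, neg, drop = FALSE]
  colnames(occ) <- literals
  occ
}
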