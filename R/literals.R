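#' Presence/absence literals
#'
#' A literal is a gene family together with a polarity: the family is
#' present, or the family is absent.  Literals are encoded as plain
#' character strings, with a `"!"` prefix marking negation (absence), the
#' notation used throughout rule listings: `"urah"` means *urah present*,
#' `"!uox"` means *uox absent*.
#'
#' @param family character vector of family identifiers.
#' @param negated logical vector; `TRUE` encodes the absence literal.
#' @return character vector of encoded literals.
#' @examples
#' literal(c("urah", "uox"), c(FALSE, TRUE))
#' @export
literal <- function(family, negated = FALSE) {
  stopifnot(is.character(family), !anyNA(family), all(nzchar(family)))
  if (any(startsWith(family, "!")))
    stop("family identifiers must not start with '!'")
  ifelse(rep_len(negated, length(family)), paste0("!", family), family)
}

#' @rdname literal
#' @param x character vector of encoded literals.
#' @export
literal_family <- function(x) sub("^!", "", x)

#' @rdname literal
#' @export
literal_negated <- function(x) startsWith(x, "!")

## Canonical literal order: family id lexicographic (C locale, stable
## across platforms), presence before absence within a family.
literal_order <- function(x) {
  order(literal_family(x), literal_negated(x), method = "radix")
}

#' Construct a contradiction-free item set
#'
#' An item set is a set of literals interpreted as a conjunction.  A set
#' containing both the presence and the absence literal of the same family
#' is contradictory (it can never hold in any genome) and is rejected.
#' Literals are deduplicated and put into canonical order (family id, then
#' presence before absence).
#'
#' @param literals character vector of literals (see [literal()]).
#' @return character vector, the canonical item set.
#' @examples
#' itemset(c("!uox", "urah", "urad"))
#' @export
itemset <- function(literals) {
  stopifnot(is.character(literals))
  literals <- unique(literals)
  fam <- literal_family(literals)
  if (anyDuplicated(fam))
    stop("contradictory item set: family '",
         fam[duplicated(fam)][1L], "' appears with both polarities")
  literals[literal_order(literals)]
}

## "a & !b & c" -> c("a","!b","c"); inverse of format_itemset()
parse_itemset <- function(label) {
  if (is.na(label) || label == "" || label == "{}") return(character(0))
  itemset(trimws(strsplit(label, "&", fixed = TRUE)[[1L]]))
}

format_itemset <- function(items) {
  if (length(items) == 0L) return("{}")
  paste(items, collapse = "&")
}
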