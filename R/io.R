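#' Read and write profile matrices as TSV
#'
#' The canonical on-disk form is UTF-8, tab-separated, a header row of
#' family identifiers and a first column of genome identifiers.  Lines
#' starting with `#` are treated as comments (the simulator embeds its
#' configuration this way) and skipped.  Cell tokens are configurable;
#' by default `1`/`0` and `Y`/`N` are accepted.
#'
#' @param path file path.
#' @param true_tokens,false_tokens character vectors of tokens read as
#'   presence / absence.
#' @return [read_profile_matrix()] returns a [profile_matrix()];
#'   `write_profile_matrix()` returns `path` invisibly.
#' @examples
#' occ <- matrix(c(1, 0, 1, 0, 0, 1), nrow = 2, byrow = TRUE,
#'               dimnames = list(c("gA", "gB"), c("f1", "f2", "f3")))
#' p <- tempfile(fileext = ".tsv")
#' write_profile_matrix(profile_matrix(occ), p)
#' read_profile_matrix(p)
#' @export
read_profile_matrix <- function(path, true_tokens = c("1", "Y"),
                                false_tokens = c("0", "N")) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = "character",
                          quote = "", fileEncoding = "UTF-8")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("format error: empty profile matrix in ", path)
  gid <- df[[1L]]
  if (anyDuplicated(gid))
    stop("format error: duplicate genome id '", gid[duplicated(gid)][1L], "'")
  fid <- colnames(df)[-1L]
  if (anyDuplicated(fid))
    stop("format error: duplicate family id '", fid[duplicated(fid)][1L], "'")
  cells <- as.matrix(df[, -1L, drop = FALSE])
  parsed <- matrix(NA_integer_, nrow(cells), ncol(cells))
  parsed[cells %in% true_tokens] <- 1L
  parsed[cells %in% false_tokens] <- 0L
  if (anyNA(parsed)) {
    bad <- which(is.na(parsed), arr.ind = TRUE)[1L, ]
    stop("format error: non-binary cell '", cells[bad[1L], bad[2L]],
         "' at genome '", gid[bad[1L]], "', family '", fid[bad[2L]], "'")
  }
  dimnames(parsed) <- list(gid, fid)
  profile_matrix(parsed)
}

#' @rdname read_profile_matrix
#' @param m a [profile_matrix()].
#' @param comments optional character vector written as leading `#` lines.
#' @export
write_profile_matrix <- function(m, path, comments = NULL) {
  stopifnot(inherits(m, "profile_matrix"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(c("genome_id", family_ids(m)), collapse = "\t"), con)
  body <- apply(m$occurrence, 1L, paste, collapse = "\t")
  writeLines(paste(genome_ids(m), body, sep = "\t"), con)
  invisible(path)
}

#' Write and read ranked-rule tables
#'
#' Rules are exchanged as TSV with one row per rule: the antecedent
#' (literals joined by `&`, `!` marking absence), the consequent, the four
#' truth-table counts, support, confidence printed at 3 decimals, the
#' p-value printed at one significant digit in scientific notation, and
#' the full-precision `log10_p` alongside.
#'
#' @param rules a rule `data.frame` as produced by [generate_rules()].
#' @param path file path.
#' @return `write_rules()` returns `path` invisibly; `read_rules()` a
#'   `data.frame`.
#' @export
write_rules <- function(rules, path) {
  out <- data.frame(
    antecedent = rules$antecedent,
    consequent = rules$consequent,
    tt = rules$tt, tf = rules$tf, ft = rules$ft, ff = rules$ff,
    support = rules$support,
    confidence = sprintf("%.3f", rules$confidence),
    p = vapply(rules$log10_p, format_p_printed, ""),
    log10_p = sprintf("%.12g", rules$log10_p),
    stringsAsFactors = FALSE
  )
  if ("rank" %in% names(rules)) out <- cbind(rank = rules$rank, out)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          colClasses = NA)
  num <- intersect(c("tt", "tf", "ft", "ff", "support", "confidence",
                     "log10_p", "rank"), names(df))
  for (cl in num) df[[cl]] <- as.numeric(df[[cl]])
  df$antecedent <- as.character(df$antecedent)
  df$consequent <- as.character(df$consequent)
  df
}
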