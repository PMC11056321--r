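#' Read a labeled graph from TSV
#'
#' The interchange dialect: UTF-8 text, comment lines starting with `#`, no
#' header; data rows are `head<TAB>tail<TAB>label[<TAB>multiplicity]` with
#' multiplicity defaulting to 1. Validation errors carry line numbers.
#'
#' @param path File path.
#' @return A `labeled_graph` (merged form).
#' @export
read_graph_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) stop("no data rows in ", path)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    p <- parts[[i]]
    ln <- keep[i]
    if (length(p) < 3 || length(p) > 4) {
      stop(sprintf("%s:%d: expected 3 or 4 tab-separated fields, got %d",
                   path, ln, length(p)))
    }
    if (nchar(p[3]) != 1) {
      stop(sprintf("%s:%d: label must be one character, got '%s'",
                   path, ln, p[3]))
    }
    mult <- if (length(p) == 4) suppressWarnings(as.integer(p[4])) else 1L
    if (is.na(mult) || mult < 1) {
      stop(sprintf("%s:%d: multiplicity must be a positive integer", path, ln))
    }
    rows[[i]] <- data.frame(head = p[1], tail = p[2], label = p[3],
                            mult = mult)
  }
  labeled_graph(do.call(rbind, rows))
}

#' Write a labeled graph to TSV
#'
#' Rows are sorted (head, tail, label), so writing is canonical and
#' `write_graph_tsv(read_graph_tsv(f), f)` is byte-stable for canonical
#' files.
#'
#' @param g A `labeled_graph`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(g, path) {
  stopifnot(inherits(g, "labeled_graph"))
  e <- g$edges
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%s\t%s\t%s\t%d", e$head, e$tail, e$label, e$mult), con)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path File path.
#' @return Data frame with columns `id` and `seq` in file order.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  data.frame(id = sub("\\s.*$", "", names(ss)),
             seq = toupper(as.character(ss)))
}

# sequence sanity check before de Bruijn construction
check_nucleotide <- function(seq) {
  bad <- gsub("[ACGT]", "", seq)
  if (nzchar(bad)) {
    stop("sequence contains non-ACGT characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  invisible(seq)
}
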