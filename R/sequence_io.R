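# Reading and writing sequences, label tables and cluster assignments.
#
# Sequences are carried through the package as a named character vector:
# names are the ids (first whitespace-delimited token of the FASTA header),
# values are the residues, upper-cased on input. Only IUPAC nucleotide
# characters (ACGT, ambiguity codes, N) are accepted.

.IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N")

.check_sequences <- function(x, arg = "sequences") {
  if (!is.character(x) || length(x) == 0L)
    stop(arg, " must be a non-empty named character vector of DNA sequences")
  if (is.null(names(x)) || any(names(x) == "") || anyDuplicated(names(x)))
    stop(arg, " must have unique, non-empty names (sequence ids)")
  if (any(nchar(x) == 0L))
    stop(arg, " contains an empty sequence")
  invisible(x)
}

.validate_residues <- function(x) {
  bad <- grepl(sprintf("[^%s]", paste(.IUPAC_CHARS, collapse = "")), x)
  if (any(bad))
    stop("sequence(s) ", paste(utils::head(names(x)[bad], 3), collapse = ", "),
         " contain characters outside the IUPAC nucleotide alphabet")
  invisible(x)
}

#' Read DNA sequences from a FASTA file
#'
#' Parses a FASTA file into a named character vector of upper-case residue
#' strings. The id of each record is the first whitespace-delimited token of
#' its header line, matching the convention used by most sequence tooling so
#' that ids can be cross-referenced against label tables. Multi-line record
#' bodies are concatenated and record order is preserved. Characters outside
#' the IUPAC nucleotide alphabet (ACGT, ambiguity codes, N) are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector; names are sequence ids, values are
#'   upper-case residue strings.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x some description", "ACGT", ">y", "TT", "TT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA file '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  res <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(res) <- ids
  .validate_residues(res)
  .check_sequences(res)
  res
}

#' Write DNA sequences to a FASTA file
#'
#' @param sequences Named character vector of residue strings.
#' @param path Output file path.
#' @param width Line width for wrapping sequence bodies.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path, width = 80L) {
  .check_sequences(sequences)
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a two-column label table
#'
#' Reads a tab- or comma-delimited table with columns (sequence id, label).
#' The delimiter is detected from the first line. A header line is skipped
#' when its first field is one of `id`, `sequence`, `sequence_id`, `seqid`
#' (case-insensitive). Ground-truth labels read this way are only ever used
#' post hoc for evaluation, never during clustering.
#'
#' @param path Path to the label file.
#' @return A data frame with character columns `id` and `label`. An empty
#'   file yields a zero-row table.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(id = character(), label = character(),
                      stringsAsFactors = FALSE))
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop("label file must have exactly two columns; line(s) ",
         paste(utils::head(which(nf != 2L), 3), collapse = ", "),
         " have ", paste(unique(nf[nf != 2L]), collapse = "/"))
  tab <- data.frame(id = trimws(vapply(parts, `[[`, "", 1L)),
                    label = trimws(vapply(parts, `[[`, "", 2L)),
                    stringsAsFactors = FALSE)
  if (tolower(tab$id[[1L]]) %in% c("id", "sequence", "sequence_id", "seqid"))
    tab <- tab[-1L, , drop = FALSE]
  if (anyDuplicated(tab$id))
    stop("duplicate id(s) in label file: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  rownames(tab) <- NULL
  tab
}

#' Write cluster assignments to a delimited file
#'
#' Writes a tab-separated table with columns `id`, `cluster` and, when a
#' probability matrix is supplied, one `p<cluster>` column per cluster.
#' Probabilities are rounded to six decimal places.
#'
#' @param path Output file path.
#' @param ids Character vector of sequence ids.
#' @param clusters Integer vector of cluster indices (same length as `ids`).
#' @param probabilities Optional numeric matrix, one row per id and one
#'   column per cluster, rows summing to one.
#' @return Invisibly, `path`.
#' @export
write_assignments <- function(path, ids, clusters, probabilities = NULL) {
  if (length(ids) != length(clusters))
    stop("ids and clusters must have the same length")
  tab <- data.frame(id = as.character(ids), cluster = as.integer(clusters),
                    stringsAsFactors = FALSE)
  if (!is.null(probabilities)) {
    probabilities <- as.matrix(probabilities)
    if (nrow(probabilities) != length(ids))
      stop("probabilities must have one row per id")
    pr <- round(probabilities, 6L)
    colnames(pr) <- paste0("p", seq_len(ncol(pr)))
    tab <- cbind(tab, as.data.frame(pr))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read cluster assignments written by [write_assignments()]
#'
#' @param path Path to an assignments file.
#' @return A data frame with columns `id`, `cluster` and any probability
#'   columns present.
#' @export
read_assignments <- function(path) {
  if (!file.exists(path)) stop("assignments file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(id = "character"))
  if (!all(c("id", "cluster") %in% names(tab)))
    stop("assignments file must have 'id' and 'cluster' columns")
  tab
}
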