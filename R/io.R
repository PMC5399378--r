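#' Read and write sequence records
#'
#' Thin wrappers over Biostrings for FASTA/FASTQ.  Records are plain data
#' frames with columns `id` (first whitespace-delimited token of the
#' header), `description` (remainder of the header, possibly empty) and
#' `sequence`.  The input alphabet is preserved (`U` vs `T`); use
#' [as_rna()] / [as_dna()] to normalize.  FASTQ qualities are discarded:
#' nothing downstream consumes them.
#'
#' @param path file path.
#' @return data frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  .stringset_to_records(x)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fastq")
  .stringset_to_records(x)
}

.stringset_to_records <- function(x) {
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- toupper(as.character(x))
  bad <- grepl("[^ACGTUN]", seqs)
  if (any(bad))
    stop("inconsistent alphabet in record(s): ",
         paste(utils::head(id[bad], 3), collapse = ", "))
  data.frame(id = id, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' @rdname read_fasta
#' @param records data frame as returned by [read_fasta()], or a named
#'   character vector of sequences.
#' @param width line-wrap width for the sequence lines.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records))
    records <- data.frame(id = names(records), description = "",
                          sequence = unname(records))
  hdr <- ifelse(nzchar(records$description),
                paste(records$id, records$description), records$id)
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a genome FASTA into a named vector of scaffold sequences
#' @inheritParams read_fasta
#' @return named character vector, one element per scaffold.
#' @export
read_genome <- function(path) {
  r <- read_fasta(path)
  stats::setNames(r$sequence, r$id)
}

#' Read and write BED intervals
#'
#' BED is 0-based half-open, which is also the internal convention, so the
#' coordinates pass through unchanged.  Columns beyond the first six are
#' preserved in `extra`.
#'
#' @param path file path.
#' @return data frame with columns `scaffold`, `start`, `end`, `name`,
#'   `score`, `strand` (missing BED columns are filled with defaults).
#' @export
read_bed <- function(path) {
  d <- data.table::fread(path, header = FALSE, sep = "\t",
                         data.table = FALSE)
  if (ncol(d) < 3L) stop("unreadable BED file: fewer than 3 columns")
  names(d)[1:3] <- c("scaffold", "start", "end")
  d$name <- if (ncol(d) >= 4L) as.character(d[[4L]]) else "."
  d$score <- if (ncol(d) >= 5L) d[[5L]] else "."
  d$strand <- if (ncol(d) >= 6L) as.character(d[[6L]]) else "+"
  if (any(d$start < 0L | d$start >= d$end))
    stop("BED interval with start >= end or negative start")
  d[, c("scaffold", "start", "end", "name", "score", "strand")]
}

#' @rdname read_bed
#' @param intervals data frame with at least `scaffold`, `start`, `end`;
#'   optional `name`, `score`, `strand`.
#' @export
write_bed <- function(intervals, path) {
  d <- data.frame(
    scaffold = intervals$scaffold,
    start = intervals$start,
    end = intervals$end,
    name = if (!is.null(intervals$name)) intervals$name else ".",
    score = if (!is.null(intervals$score)) intervals$score else ".",
    strand = if (!is.null(intervals$strand)) intervals$strand else "+")
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Returns one row per feature with internal 0-based half-open coordinates
#' (GFF3 is 1-based inclusive on disk).  Only the columns the pipeline
#' consumes are kept.
#'
#' @param path GFF3 file path.
#' @param feature_types optional character vector; keep only these `type`s.
#' @return data frame with columns `scaffold`, `start`, `end`, `strand`,
#'   `type`, `id`.
#' @export
read_gff3 <- function(path, feature_types = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), strand = character(),
                      type = character(), id = character()))
  d <- utils::read.delim(text = lines, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(d) != 9L) stop("unreadable GFF3: expected 9 tab-separated columns")
  id <- sub("^.*ID=([^;]+).*$", "\\1", d[[9L]])
  id[!grepl("ID=", d[[9L]])] <- NA_character_
  out <- data.frame(scaffold = d[[1L]], start = d[[4L]] - 1L, end = d[[5L]],
                    strand = d[[7L]], type = d[[3L]], id = id,
                    stringsAsFactors = FALSE)
  if (!is.null(feature_types)) out <- out[out$type %in% feature_types, ]
  rownames(out) <- NULL
  out
}

#' @rdname read_gff3
#' @param models data frame with `scaffold`, `start`, `end`, `strand`,
#'   `type`, `id` (internal coordinates).
#' @param source value for the GFF3 source column.
#' @export
write_gff3 <- function(models, path, source = "mirforge") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     models$scaffold, source, models$type,
                     models$start + 1L, models$end, models$strand,
                     models$id))
  writeLines(lines, path)
  invisible(path)
}

#' Write a prediction report TSV
#'
#' Stable column set shared by all tracks: `id`, `locus`, `track`,
#' `precursor_seq`, `structure`, `mfe`, `pass_all`, `mature_5p`,
#' `mature_3p`, `family_seed`, `conservation_class`.  Missing fields are
#' written as `NA`.
#'
#' @param candidates candidate data frame (see [apply_filters()]).
#' @param path output path.
#' @export
write_report_tsv <- function(candidates, path) {
  cols <- c("id", "locus", "track", "precursor_seq", "structure", "mfe",
            "pass_all", "mature_5p", "mature_3p", "family_seed",
            "conservation_class")
  out <- as.data.frame(candidates)
  for (cc in setdiff(cols, names(out))) out[[cc]] <- NA
  utils::write.table(out[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
read_report_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
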