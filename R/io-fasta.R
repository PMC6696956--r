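#' Genome record
#'
#' A single replicon or phage sequence: an id, an uppercase DNA sequence over
#' `{A,C,G,T,N}`, and a free-text description.
#'
#' @param id sequence identifier, unique within a file.
#' @param sequence DNA string; lowercase input is uppercased. `U` is rejected
#'   (RNA is out of scope).
#' @param description optional free-text description.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop2("id must be a non-empty string")
  }
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop2("sequence must be a non-empty string (record '", id, "')")
  }
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    stop2("illegal character '", substr(sequence, bad, bad),
          "' at position ", bad, " in record '", id, "'")
  }
  structure(list(id = id, sequence = sequence,
                 description = as.character(description)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s bp)%s\n", x$id,
              format(nchar(x$sequence), big.mark = ","),
              if (nzchar(x$description)) paste0(" ", x$description) else ""))
  invisible(x)
}

#' Read a FASTA file
#'
#' Parses FASTA via Biostrings and validates each record against the
#' `genome_record` contract: non-empty sequence, alphabet `{A,C,G,T,N}`
#' (lowercase uppercased, `U` rejected), unique ids.
#'
#' @param path path to a FASTA file.
#' @return A list of [genome_record()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop2("empty FASTA file: ", path)
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(ids)) {
    stop2("duplicate FASTA id(s): ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mapply(function(id, s, d) genome_record(id, s, d),
         ids, as.character(set), desc,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write genome records to FASTA
#'
#' @param records a `genome_record` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  stopifnot(length(records) > 0L)
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  nm <- vapply(records, `[[`, "", "id")
  desc <- vapply(records, `[[`, "", "description")
  names(seqs) <- ifelse(nzchar(desc), paste(nm, desc), nm)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
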