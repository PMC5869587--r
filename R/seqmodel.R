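#' Core sequence data model and I/O
#'
#' A protein set is a plain `data.frame` with columns `id`, `sequence` and the
#' optional metadata columns `taxon` and `clade`, one row per protein. All
#' sequences are upper-case strings over the 20 standard amino acids plus the
#' ambiguity character `X`. Every coordinate in the package is 1-based and
#' inclusive; "k-th residue from the C-terminus" means position
#' `nchar(sequence) - k + 1`, so k = 1 is the last residue.
#'
#' @name seqmodel
NULL

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")

# Validate and canonicalise one raw sequence string: upper-case, strip a
# single terminal '*' stop character, reject everything else outside the
# 21-letter alphabet.
canonicalize_sequence <- function(seq, id) {
  seq <- toupper(seq)
  seq <- sub("\\*$", "", seq)
  if (!nzchar(seq)) {
    stop("sequence for id '", id, "' is empty", call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    stop("sequence for id '", id, "' contains invalid character(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  seq
}

new_protein_set <- function(id, sequence, taxon = NA_character_,
                            clade = NA_character_) {
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0) {
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  data.frame(id = as.character(id), sequence = as.character(sequence),
             taxon = rep_len(as.character(taxon), length(id)),
             clade = rep_len(as.character(clade), length(id)),
             stringsAsFactors = FALSE)
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased on read and a single terminal `*` (stop) is
#' stripped; any other character outside the 20 amino acids plus `X` is an
#' error naming the offending record. Duplicate record ids are an error.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped sequence lines).
#' @return A `data.frame` with columns `id`, `sequence`, `taxon`, `clade`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0) stop("FASTA file '", path, "' contains no records",
                             call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA file '", path, "' has an empty header",
                              call. = FALSE)
  seqs <- as.character(set)
  seqs <- mapply(canonicalize_sequence, seqs, ids, USE.NAMES = FALSE)
  new_protein_set(ids, seqs)
}

#' Write a protein set to FASTA
#'
#' @param x A protein set `data.frame` (columns `id`, `sequence`).
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(is.data.frame(x), all(c("id", "sequence") %in% names(x)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", x$sequence[i])
    writeLines(c(paste0(">", x$id[i]), sub("\n$", "", body)), con, sep = "\n")
  }
  invisible(path)
}

#' Read a per-sequence metadata table
#'
#' Expects a tab-separated file with the exact header
#' `id<TAB>taxon<TAB>clade`. Rows with a different number of columns are an
#' error reporting the offending line number.
#'
#' @param path Path to the metadata TSV.
#' @return A `data.frame` with columns `id`, `taxon`, `clade` (possibly with
#'   zero rows).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) == 0) stop("metadata file '", path, "' is empty",
                               call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (!identical(fields[[1]], c("id", "taxon", "clade"))) {
    stop("metadata file '", path,
         "' must start with header 'id\\ttaxon\\tclade'", call. = FALSE)
  }
  nf <- lengths(fields)
  bad <- setdiff(which(nf != 3L), 1L)
  if (length(bad) > 0) {
    stop("malformed metadata row at line ", bad[1], " (expected 3 columns, got ",
         nf[bad[1]], ")", call. = FALSE)
  }
  if (length(fields) == 1) {
    return(data.frame(id = character(), taxon = character(),
                      clade = character(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, fields[-1])
  dup <- unique(m[, 1][duplicated(m[, 1])])
  if (length(dup) > 0) stop("duplicate metadata id(s): ",
                            paste(dup, collapse = ", "), call. = FALSE)
  data.frame(id = m[, 1], taxon = m[, 2], clade = m[, 3],
             stringsAsFactors = FALSE)
}

#' Write a metadata table
#'
#' @param x `data.frame` with columns `id`, `taxon`, `clade`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(x, path) {
  stopifnot(all(c("id", "taxon", "clade") %in% names(x)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("id\ttaxon\tclade",
               paste(x$id, x$taxon, x$clade, sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Attach taxon/clade metadata to a protein set
#'
#' Ids absent from the metadata table keep `NA` metadata.
#'
#' @param x Protein set `data.frame`.
#' @param meta Metadata `data.frame` from [read_metadata()].
#' @return `x` with `taxon`/`clade` filled in where available.
#' @export
join_metadata <- function(x, meta) {
  idx <- match(x$id, meta$id)
  hit <- !is.na(idx)
  x$taxon[hit] <- meta$taxon[idx[hit]]
  x$clade[hit] <- meta$clade[idx[hit]]
  x
}
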