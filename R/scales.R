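#' Shipped scales, weight tables and motif fingerprints
#'
#' All scorer parameters ship as plain-text tab-separated files under
#' `inst/extdata` and can be replaced by user files of the same layout via the
#' pipeline configuration. Motif fingerprints use a small pattern syntax:
#' literal amino-acid letters, `x` for "any residue except X", and square
#' brackets for alternatives (e.g. `GxxxxGK[ST]`). The ambiguity character `X`
#' never matches any motif position, including wildcards: an unknown residue
#' can never be evidence for a motif.
#'
#' @name scales
NULL

pkg_extdata <- function(file) {
  system.file("extdata", file, package = "rhebanchor", mustWork = TRUE)
}

#' Kyte-Doolittle hydropathy scale
#'
#' @param path Optional path to a replacement two-column TSV (`aa`,
#'   `hydropathy`). `X` is assigned hydropathy 0.
#' @return Named numeric vector over the 21-letter alphabet.
#' @export
kd_hydropathy <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("kyte_doolittle.tsv")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  setNames(tab$hydropathy, tab$aa)
}

# Mean hydropathy of a character vector of residues (empty -> NaN guarded by
# callers).
mean_hydropathy <- function(chars, scale = kd_hydropathy()) {
  h <- scale[chars]
  h[is.na(h)] <- 0
  mean(h)
}

#' Myristoylation position-weight table
#'
#' Long-format table (`pos`, `aa`, `weight`) covering positions 2-9 of the
#' N-terminus; unlisted (position, residue) pairs have weight 0.
#'
#' @param path Optional replacement table path.
#' @return `data.frame` with columns `pos`, `aa`, `weight`.
#' @export
myr_pwm <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("myr_pwm.tsv")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Palmitoylation context weight table
#'
#' Per-residue weights summed over the +/-9 window around a candidate
#' cysteine (the site itself excluded).
#'
#' @param path Optional replacement table path.
#' @return Named numeric vector of per-residue weights.
#' @export
palm_weights <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("palm_weights.tsv")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  setNames(tab$weight, tab$aa)
}

#' Motif fingerprint patterns
#'
#' @param path Optional replacement table path (`name`, `pattern`).
#' @return Named character vector of patterns in fingerprint syntax.
#' @export
fingerprints <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("fingerprints.tsv")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  setNames(tab$pattern, tab$name)
}

# Convert fingerprint syntax to a POSIX regex in which the wildcard excludes
# the ambiguity character X.
fingerprint_regex <- function(pattern) {
  out <- character()
  chars <- strsplit(pattern, "")[[1]]
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      out <- c(out, "[^X]")
      i <- i + 1
    } else if (ch == "[") {
      j <- i
      while (chars[j] != "]") j <- j + 1
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1
    } else {
      out <- c(out, ch)
      i <- i + 1
    }
  }
  paste(out, collapse = "")
}

# All match start positions of a fingerprint in a sequence (non-overlapping,
# left to right). Returns integer(0) when absent.
match_fingerprint <- function(seq, pattern) {
  m <- gregexpr(fingerprint_regex(pattern), seq)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# Width of a fingerprint match (patterns here are fixed-width).
fingerprint_width <- function(pattern) {
  nchar(gsub("\\[[A-Z]+\\]", "#", pattern))
}
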