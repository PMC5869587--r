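#' Domain and diagnostic-residue scanners
#'
#' Lightweight fingerprint-based detection of the GTPase domain (via the G1,
#' G3 and G4 nucleotide-binding boxes with Ras-fold spacing constraints), the
#' Rheb-diagnostic arginine of the first beta-strand, and the two N-terminal
#' phosphoinositide-binding modules (PX and FYVE). Fingerprints ship as a
#' plain-text pattern file and can be replaced via configuration; no profile
#' HMMs are used.
#'
#' @name domains
NULL

#' Scan for the GTPase domain via G-box motifs
#'
#' Searches, in order, G1 (`GxxxxGK[ST]`, the P-loop), G3 (`DxxG`) starting
#' 40-110 residues after the end of G1, and G4 (`[NT]KxD`) starting 10-60
#' residues after the end of G3. All three are required. The reported span is
#' padded by 10 residues upstream of G1 and 40 downstream of G4 (clipped to
#' the sequence) to approximate the full domain extent; the padding errs
#' towards over-exclusion so that no palmitoylation site is ever called inside
#' the folded domain.
#'
#' @param sequence Amino-acid string.
#' @param patterns Fingerprint set, see [fingerprints()].
#' @return A one-row `data.frame` with columns `kind` (`"GTPASE"`), `start`,
#'   `end`, plus attribute `"evidence"` (`data.frame` of motif name,
#'   start, end), or `NULL` when no consistent G1/G3/G4 triple exists.
#' @export
scan_gtpase <- function(sequence, patterns = fingerprints()) {
  n <- nchar(sequence)
  g1w <- fingerprint_width(patterns[["G1"]])
  g3w <- fingerprint_width(patterns[["G3"]])
  g4w <- fingerprint_width(patterns[["G4"]])
  for (g1 in match_fingerprint(sequence, patterns[["G1"]])) {
    g1_end <- g1 + g1w - 1L
    g3s <- match_fingerprint(sequence, patterns[["G3"]])
    g3s <- g3s[g3s - g1_end >= 40L & g3s - g1_end <= 110L]
    for (g3 in g3s) {
      g3_end <- g3 + g3w - 1L
      g4s <- match_fingerprint(sequence, patterns[["G4"]])
      g4s <- g4s[g4s - g3_end >= 10L & g4s - g3_end <= 60L]
      if (length(g4s) > 0) {
        g4 <- g4s[1]
        hit <- data.frame(kind = "GTPASE",
                          start = max(1L, g1 - 10L),
                          end = min(n, g4 + g4w - 1L + 40L),
                          stringsAsFactors = FALSE)
        attr(hit, "evidence") <- data.frame(
          motif = c("G1", "G3", "G4"),
          start = c(g1, g3, g4),
          end = c(g1_end, g3_end, g4 + g4w - 1L),
          stringsAsFactors = FALSE)
        return(hit)
      }
    }
  }
  NULL
}

#' Rheb-likeness diagnostics
#'
#' Rheb orthologs carry a highly characteristic arginine in the first
#' beta-strand of the GTPase domain, absent from other Ras-family members.
#' Since the beta-1 strand immediately precedes the P-loop in the Ras fold,
#' the arginine is searched within the `arg_window` residues immediately
#' before the G1 motif start; the position closest to G1 is reported. A
#' protein is Rheb-like iff it has a GTPase hit and the diagnostic arginine.
#'
#' @param sequence Amino-acid string.
#' @param gtpase_hit Result of [scan_gtpase()] (or `NULL`).
#' @param arg_window Search window upstream of G1 (default 10).
#' @return List with `has_g_boxes`, `diagnostic_arginine` (position or `NA`),
#'   `is_rheb_like`.
#' @export
diagnose_rheb <- function(sequence, gtpase_hit, arg_window = 10L) {
  if (is.null(gtpase_hit)) {
    return(list(has_g_boxes = FALSE, diagnostic_arginine = NA_integer_,
                is_rheb_like = FALSE))
  }
  ev <- attr(gtpase_hit, "evidence")
  g1_start <- ev$start[ev$motif == "G1"]
  lo <- max(1L, g1_start - arg_window)
  hi <- g1_start - 1L
  arg <- NA_integer_
  if (hi >= lo) {
    chars <- strsplit(substr(sequence, lo, hi), "")[[1]]
    w <- which(chars == "R")
    if (length(w) > 0) arg <- lo + max(w) - 1L
  }
  list(has_g_boxes = TRUE, diagnostic_arginine = arg,
       is_rheb_like = !is.na(arg))
}

#' Scan for N-terminal PX and FYVE domains
#'
#' Both modules are searched only within the `window` residues immediately
#' N-terminal to the GTPase span (they always precede the GTPase domain in
#' this protein family). A FYVE hit requires the zinc-binding core fingerprint
#' (`RRHHCRxCG`) plus at least two additional `CxxC` cysteine pairs in the
#' window; a PX hit requires the `RR[FY]SDF` fingerprint. The reported span is
#' the searched window. At most one hit of each kind is returned.
#'
#' @param sequence Amino-acid string.
#' @param gtpase_hit Result of [scan_gtpase()]; `NULL` yields no hits.
#' @param window Window size upstream of the GTPase span (default 60).
#' @param patterns Fingerprint set, see [fingerprints()].
#' @return `data.frame` with columns `kind` (`"PX"`/`"FYVE"`), `start`, `end`
#'   (possibly zero rows).
#' @export
scan_px_fyve <- function(sequence, gtpase_hit, window = 60L,
                         patterns = fingerprints()) {
  empty <- data.frame(kind = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(gtpase_hit) || gtpase_hit$start <= 1L) return(empty)
  lo <- max(1L, gtpase_hit$start - window)
  hi <- gtpase_hit$start - 1L
  win <- substr(sequence, lo, hi)
  hits <- empty
  core <- match_fingerprint(win, patterns[["FYVE_CORE"]])
  if (length(core) > 0) {
    core_span <- c(core[1], core[1] + fingerprint_width(patterns[["FYVE_CORE"]]) - 1L)
    cxxc <- match_fingerprint(win, patterns[["CXXC"]])
    cxxc_w <- fingerprint_width(patterns[["CXXC"]])
    extra <- sum(cxxc + cxxc_w - 1L < core_span[1] | cxxc > core_span[2])
    if (extra >= 2L) {
      hits <- rbind(hits, data.frame(kind = "FYVE", start = lo, end = hi,
                                     stringsAsFactors = FALSE))
    }
  }
  if (length(match_fingerprint(win, patterns[["PX_CORE"]])) > 0) {
    hits <- rbind(hits, data.frame(kind = "PX", start = lo, end = hi,
                                   stringsAsFactors = FALSE))
  }
  hits
}

#' Split a sequence into N-terminal, domain and C-terminal regions
#'
#' @param sequence Amino-acid string.
#' @param gtpase_hit Result of [scan_gtpase()].
#' @return List with `n_terminal` and `c_terminal`, each either
#'   `c(start, end)` or `NULL`; both `NULL` when there is no GTPase hit (the
#'   protein is then unclassifiable downstream).
#' @export
define_regions <- function(sequence, gtpase_hit) {
  if (is.null(gtpase_hit)) return(list(n_terminal = NULL, c_terminal = NULL))
  n <- nchar(sequence)
  list(
    n_terminal = if (gtpase_hit$start > 1L) c(1L, gtpase_hit$start - 1L),
    c_terminal = if (gtpase_hit$end < n) c(gtpase_hit$end + 1L, n)
  )
}
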