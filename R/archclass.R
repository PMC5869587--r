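#' Membrane-attachment architecture classification
#'
#' Combines all detector outputs for one protein into an annotation object
#' and maps it to one of twelve architecture classes (A-L), `UNANCHORED`, or
#' `UNCLASSIFIED`. Classes are defined purely by the set of N-terminal
#' devices (PX, FYVE, MYR = predicted myristoylation, PALM_N = at least one
#' predicted N-terminal palmitoylation site) and C-terminal devices (CAAX,
#' PALM_C, TM = at least one transmembrane segment in the C-terminal region,
#' WMOTIF):
#'
#' | class | N-terminal            | C-terminal      |
#' |-------|-----------------------|-----------------|
#' | A     | none                  | CAAX            |
#' | B     | PX                    | CAAX            |
#' | C     | FYVE                  | CAAX            |
#' | D     | FYVE + MYR + PALM_N   | none            |
#' | E     | FYVE + MYR            | none            |
#' | F     | FYVE                  | none            |
#' | G     | MYR + PALM_N          | none            |
#' | H     | MYR                   | none            |
#' | I     | PALM_N                | CAAX            |
#' | J     | any                   | CAAX + PALM_C   |
#' | K     | any                   | TM              |
#' | L     | none                  | WMOTIF          |
#'
#' No devices at all maps to `UNANCHORED`; any other combination, or a
#' protein that is not Rheb-like, maps to `UNCLASSIFIED`. Class J admits any
#' N-terminal devices because its two known members differ in the presence of
#' N-myristoylation; classes J and K are keyed on their C-terminal device set
#' alone. A CaaX box always takes precedence over a W-motif (enforced already
#' at detection), and PALM_C is only meaningful alongside a CaaX box.
#'
#' @name archclass
NULL

N_DEVICES <- c("PX", "FYVE", "MYR", "PALM_N")
C_DEVICES <- c("CAAX", "PALM_C", "TM", "WMOTIF")

ARCH_TABLE <- list(
  A = list(n = character(), c = "CAAX"),
  B = list(n = "PX", c = "CAAX"),
  C = list(n = "FYVE", c = "CAAX"),
  D = list(n = c("FYVE", "MYR", "PALM_N"), c = character()),
  E = list(n = c("FYVE", "MYR"), c = character()),
  F = list(n = "FYVE", c = character()),
  G = list(n = c("MYR", "PALM_N"), c = character()),
  H = list(n = "MYR", c = character()),
  I = list(n = "PALM_N", c = "CAAX"),
  L = list(n = character(), c = "WMOTIF")
)

#' Map device sets to an architecture class label
#'
#' The deterministic lookup underlying [classify()]; exposed so that the
#' mapping can be checked exhaustively over all device-set combinations.
#'
#' @param n_devices Character vector, subset of `PX`, `FYVE`, `MYR`, `PALM_N`.
#' @param c_devices Character vector, subset of `CAAX`, `PALM_C`, `TM`,
#'   `WMOTIF`.
#' @return A single class label.
#' @export
architecture_label <- function(n_devices, c_devices) {
  n <- sort(unique(n_devices))
  c_ <- sort(unique(c_devices))
  if (setequal(c_, c("CAAX", "PALM_C"))) return("J")
  if (setequal(c_, "TM")) return("K")
  for (lab in names(ARCH_TABLE)) {
    if (setequal(n, ARCH_TABLE[[lab]]$n) && setequal(c_, ARCH_TABLE[[lab]]$c))
      return(lab)
  }
  if (length(n) == 0 && length(c_) == 0) return("UNANCHORED")
  "UNCLASSIFIED"
}

#' Annotate one protein with all membrane-attachment features
#'
#' Runs every detector with a shared configuration and assembles the full
#' evidence record: GTPase/PX/FYVE domain hits, Rheb diagnostics, CaaX box,
#' myristoylation call, palmitoylation sites, transmembrane segments, W-motif
#' and the flanking regions.
#'
#' @param sequence Amino-acid string.
#' @param id Record identifier carried through to reports.
#' @param config Pipeline configuration, see [rheb_config()].
#' @return An object of class `rheb_annotation` (a list).
#' @export
annotate_protein <- function(sequence, id = "protein", config = rheb_config()) {
  patterns <- fingerprints(config$pattern_file)
  scale <- kd_hydropathy(config$hydropathy_file)
  gtpase <- scan_gtpase(sequence, patterns)
  diag <- diagnose_rheb(sequence, gtpase, config$arg_window)
  pxfyve <- scan_px_fyve(sequence, gtpase, config$fyve_window, patterns)
  hits <- pxfyve
  if (!is.null(gtpase)) hits <- rbind(gtpase[, c("kind", "start", "end")], hits)
  caax <- detect_caax(sequence)
  myr <- predict_myristoylation(sequence, myr_pwm(config$myr_pwm_file),
                                config$myr_vote_threshold)
  palm <- find_palmitoylation_sites(sequence, hits, caax,
                                    palm_weights(config$palm_weight_file),
                                    scale, config$palm_vote_threshold,
                                    config$palm_flank)
  tm <- call_tm_segments(sequence, config$tm_window, config$tm_threshold,
                         config$tm_merge_gap, config$tm_min_length, scale)
  wmotif <- detect_w_motif(sequence, caax, config$wmotif_window)
  structure(list(
    id = id, sequence = sequence, length = nchar(sequence),
    gtpase = gtpase, rheb_diagnostics = diag, domain_hits = hits,
    caax = caax, myr = myr, palm = palm, tm = tm, wmotif = wmotif,
    regions = define_regions(sequence, gtpase)
  ), class = "rheb_annotation")
}

# Derive the two device sets from an annotation.
device_sets <- function(ann) {
  n_dev <- character()
  if (any(ann$domain_hits$kind == "PX")) n_dev <- c(n_dev, "PX")
  if (any(ann$domain_hits$kind == "FYVE")) n_dev <- c(n_dev, "FYVE")
  if (ann$myr$predicted) n_dev <- c(n_dev, "MYR")
  if (any(ann$palm$predicted & ann$palm$region == "N_TERMINAL"))
    n_dev <- c(n_dev, "PALM_N")
  c_dev <- character()
  if (!is.null(ann$caax)) c_dev <- c(c_dev, "CAAX")
  if (any(ann$palm$predicted & ann$palm$region == "C_TERMINAL"))
    c_dev <- c(c_dev, "PALM_C")
  gend <- if (is.null(ann$gtpase)) Inf else ann$gtpase$end
  if (nrow(ann$tm) > 0 && any(ann$tm$start > gend)) c_dev <- c(c_dev, "TM")
  if (!is.null(ann$wmotif)) c_dev <- c(c_dev, "WMOTIF")
  list(n = n_dev, c = c_dev)
}

#' Classify an annotated protein into an architecture class
#'
#' @param ann A `rheb_annotation` from [annotate_protein()].
#' @return List with `class_label`, `n_devices`, `c_devices`, and a
#'   human-readable `rationale` string.
#' @export
classify <- function(ann) {
  stopifnot(inherits(ann, "rheb_annotation"))
  dev <- device_sets(ann)
  if (!ann$rheb_diagnostics$is_rheb_like) {
    return(list(class_label = "UNCLASSIFIED", n_devices = dev$n,
                c_devices = dev$c,
                rationale = "not Rheb-like (missing G boxes or beta-1 arginine)"))
  }
  lab <- architecture_label(dev$n, dev$c)
  list(class_label = lab, n_devices = dev$n, c_devices = dev$c,
       rationale = sprintf("N-devices {%s}; C-devices {%s} -> %s",
                           paste(dev$n, collapse = ","),
                           paste(dev$c, collapse = ","), lab))
}

#' Count distinct N-terminal device configurations
#'
#' The number of distinct N-terminal device sets among a collection of
#' architecture calls (duplicated configurations collapse).
#'
#' @param calls List of results from [classify()].
#' @return Integer count (0 for empty input).
#' @export
count_distinct_n_terminal_configs <- function(calls) {
  if (length(calls) == 0) return(0L)
  keys <- vapply(calls, function(x)
    paste(sort(unique(x$n_devices)), collapse = "+"), "")
  length(unique(keys))
}

#' Distinct lipid-modification types of an annotated protein
#'
#' The set of lipid modifications implied by the annotation: prenylation
#' (CaaX box), myristoylation (predicted N-terminal glycine), palmitoylation
#' (any predicted site, N- or C-terminal).
#'
#' @param ann A `rheb_annotation`.
#' @return Character vector of modification type names.
#' @export
lipid_modification_types <- function(ann) {
  types <- character()
  if (!is.null(ann$caax)) types <- c(types, "prenylation")
  if (ann$myr$predicted) types <- c(types, "myristoylation")
  if (any(ann$palm$predicted)) types <- c(types, "palmitoylation")
  types
}

#' Annotate and classify a whole protein set
#'
#' @param proteins Protein set `data.frame` from [read_fasta()].
#' @param config Pipeline configuration, see [rheb_config()].
#' @return List with `table` (one summary row per protein, the columns of the
#'   pipeline TSV) and `annotations` (named list of `rheb_annotation`
#'   objects with a `call` element appended).
#' @export
annotate_set <- function(proteins, config = rheb_config()) {
  anns <- list()
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    id <- proteins$id[i]
    res <- tryCatch({
      ann <- annotate_protein(proteins$sequence[i], id, config)
      call <- classify(ann)
      ann$call <- call
      anns[[id]] <<- ann
      n_palm <- sum(ann$palm$predicted & ann$palm$region == "N_TERMINAL")
      c_palm <- sum(ann$palm$predicted & ann$palm$region == "C_TERMINAL")
      data.frame(
        id = id, class_label = call$class_label,
        n_devices = paste(call$n_devices, collapse = "+"),
        c_devices = paste(call$c_devices, collapse = "+"),
        caax = !is.null(ann$caax),
        myr_votes = sum(ann$myr$votes),
        n_palm_count = n_palm, c_palm_count = c_palm,
        tm_count = nrow(ann$tm),
        fyve = any(ann$domain_hits$kind == "FYVE"),
        px = any(ann$domain_hits$kind == "PX"),
        w_count = if (is.null(ann$wmotif)) 0L else ann$wmotif$count,
        rheb_like = ann$rheb_diagnostics$is_rheb_like,
        stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(id = id, class_label = "UNCLASSIFIED", n_devices = "",
                 c_devices = "", caax = NA, myr_votes = NA_integer_,
                 n_palm_count = NA_integer_, c_palm_count = NA_integer_,
                 tm_count = NA_integer_, fyve = NA, px = NA,
                 w_count = NA_integer_, rheb_like = NA,
                 stringsAsFactors = FALSE)
    })
    res
  })
  list(table = do.call(rbind, rows), annotations = anns)
}
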