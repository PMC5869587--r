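#' Pipeline configuration and end-to-end drivers
#'
#' The whole pipeline is driven by a single flat configuration list holding
#' every detector threshold and the optional replacement paths for the
#' shipped data tables. Defaults reproduce all shipped worked examples.
#' Configurations can be read from a YAML file; unknown keys are rejected so
#' that typos cannot silently fall back to defaults.
#'
#' @name cli_pipeline
NULL

#' Default pipeline configuration
#'
#' @param ... Named overrides of individual defaults. Unknown names are an
#'   error.
#' @return Named list of configuration values:
#' \describe{
#'   \item{myr_vote_threshold}{positive scorers required for a
#'     myristoylation call (default 2 of 3)}
#'   \item{palm_vote_threshold}{positive scorers required for a
#'     palmitoylation call (default 3)}
#'   \item{palm_flank}{palmitoylation context half-window and minimum flank
#'     (default 9 residues)}
#'   \item{tm_window, tm_threshold, tm_merge_gap, tm_min_length}{transmembrane
#'     caller parameters (defaults 19, 1.6, 5, 15)}
#'   \item{wmotif_window}{terminal window for the tryptophan motif
#'     (default 10)}
#'   \item{fyve_window}{window upstream of the GTPase span searched for
#'     PX/FYVE fingerprints (default 60)}
#'   \item{arg_window}{window upstream of G1 searched for the diagnostic
#'     arginine (default 10)}
#'   \item{pattern_file, hydropathy_file, myr_pwm_file, palm_weight_file}{
#'     optional replacement data tables (`NULL` = shipped defaults)}
#'   \item{seed}{seed for any randomised step (default 1)}
#' }
#' @export
rheb_config <- function(...) {
  cfg <- list(
    myr_vote_threshold = 2L,
    palm_vote_threshold = 3L,
    palm_flank = 9L,
    tm_window = 19L,
    tm_threshold = 1.6,
    tm_merge_gap = 5L,
    tm_min_length = 15L,
    wmotif_window = 10L,
    fyve_window = 60L,
    arg_window = 10L,
    pattern_file = NULL,
    hydropathy_file = NULL,
    myr_pwm_file = NULL,
    palm_weight_file = NULL,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override the defaults of [rheb_config()];
#' unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(rheb_config, vals)
}

#' Annotate and classify a FASTA file end to end
#'
#' Reads sequences (and optional metadata), runs every detector and the
#' classifier on each record, and writes `architectures.tsv` (one summary
#' row per record) plus `architectures.json` (full evidence traces) into
#' `out_dir`. A record whose annotation fails is reported as `UNCLASSIFIED`
#' and the run continues.
#'
#' @param fasta Path to the input FASTA.
#' @param out_dir Output directory (created if needed).
#' @param metadata Optional path to a metadata TSV.
#' @param config Configuration list, see [rheb_config()].
#' @return The summary `data.frame`, invisibly.
#' @export
run_annotate <- function(fasta, out_dir, metadata = NULL,
                         config = rheb_config()) {
  proteins <- read_fasta(fasta)
  if (!is.null(metadata)) proteins <- join_metadata(proteins, read_metadata(metadata))
  res <- annotate_set(proteins, config)
  tab <- res$table
  tab$taxon <- proteins$taxon[match(tab$id, proteins$id)]
  tab$clade <- proteins$clade[match(tab$id, proteins$id)]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_(tab, file.path(out_dir, "architectures.tsv"))
  traces <- lapply(res$annotations, annotation_trace)
  jsonlite::write_json(traces, file.path(out_dir, "architectures.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(tab)
}

# JSON-friendly evidence trace of one annotation
annotation_trace <- function(ann) {
  list(
    id = ann$id, length = ann$length,
    class_label = ann$call$class_label,
    n_devices = ann$call$n_devices, c_devices = ann$call$c_devices,
    rationale = ann$call$rationale,
    rheb_diagnostics = ann$rheb_diagnostics,
    domain_hits = ann$domain_hits,
    caax = ann$caax,
    myristoylation = list(eligible = ann$myr$eligible,
                          votes = as.list(ann$myr$votes),
                          predicted = ann$myr$predicted),
    palmitoylation_sites = ann$palm,
    tm_segments = ann$tm,
    w_motif = ann$wmotif
  )
}

#' Reconstruct gain/loss events from a tree and state matrix
#'
#' Runs Dollo parsimony on every presence/absence column (values in
#' \{0, 1, ?\}) and Fitch parsimony on every multistate column, and writes
#' `events.tsv` (per-character summary) and `events.json` (full
#' reconstructions) into `out_dir`.
#'
#' @param tree_file Path to a rooted newick tree.
#' @param states_file Path to a tip-state TSV (see [read_states()]).
#' @param out_dir Output directory.
#' @return The per-character summary `data.frame`, invisibly.
#' @export
run_events <- function(tree_file, states_file, out_dir) {
  tree <- read_newick(tree_file)
  states <- read_states(states_file)
  missing_tips <- setdiff(rownames(states), tree$tip.label)
  if (length(missing_tips) > 0) {
    stop("tip(s) in state table but not in tree: ",
         paste(missing_tips, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  recs <- list()
  for (ch in names(states)) {
    col <- setNames(states[[ch]], rownames(states))
    vals <- setdiff(unique(col), "?")
    if (all(vals %in% c("0", "1"))) {
      rec <- dollo_reconstruct(tree, col)
      rows[[ch]] <- data.frame(character = ch, method = "dollo",
                               gain_node = rec$gain_label,
                               n_losses = rec$n_losses,
                               n_changes = NA_integer_,
                               stringsAsFactors = FALSE)
    } else {
      rec <- fitch_count(tree, col)
      rows[[ch]] <- data.frame(character = ch, method = "fitch",
                               gain_node = NA_character_,
                               n_losses = NA_integer_,
                               n_changes = rec$n_changes,
                               stringsAsFactors = FALSE)
    }
    recs[[ch]] <- rec
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  total <- sum(tab$n_losses, na.rm = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_(tab, file.path(out_dir, "events.tsv"))
  jsonlite::write_json(
    list(per_character = recs, total_losses = total),
    file.path(out_dir, "events.json"), auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE, force = TRUE)
  attr(tab, "total_losses") <- total
  invisible(tab)
}

#' Generate a synthetic exemplar bundle
#'
#' Writes `exemplars.fasta`, `exemplars_meta.tsv` and `ground_truth.json`
#' for the requested architecture classes into `out_dir`.
#'
#' @param out_dir Output directory.
#' @param classes Architecture classes to plant (default all twelve).
#' @param seed Integer seed.
#' @param mutation_rate Filler substitution rate.
#' @return The protein set `data.frame`, invisibly.
#' @export
run_simulate <- function(out_dir, classes = LETTERS[1:12], seed = 1L,
                         mutation_rate = 0) {
  ex <- rheb_exemplars(seed, classes, mutation_rate)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ex$proteins, file.path(out_dir, "exemplars.fasta"))
  meta <- data.frame(id = ex$proteins$id,
                     taxon = sprintf("synthetic taxon %s", ex$proteins$id),
                     clade = "synthetic")
  write_metadata(meta, file.path(out_dir, "exemplars_meta.tsv"))
  truths <- lapply(ex$truths, function(t)
    t[c("class_label", "n_devices", "c_devices", "motifs")])
  jsonlite::write_json(truths, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ex$proteins)
}

# deterministic TSV writer: UTF-8, Unix newlines, no quoting surprises
write_tsv_ <- function(tab, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = "\t"), con)
  for (i in seq_len(nrow(tab))) {
    writeLines(paste(vapply(tab[i, ], as.character, ""), collapse = "\t"), con)
  }
  invisible(path)
}
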