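#' Terminal lipid-anchor detectors
#'
#' Detectors for the four terminal anchor signals: the C-terminal CaaX
#' prenylation box, N-terminal glycine myristoylation, S-palmitoylation of
#' cysteines, and the tremellomycete-style tryptophan-rich C-terminal motif.
#'
#' Myristoylation and palmitoylation calls follow an ensemble-vote design:
#' several deterministic surrogate scorers each give a verdict and a site is
#' called only when enough scorers agree (at least 2 of 3 for myristoylation,
#' at least 3 of the non-abstaining scorers, out of 5, for palmitoylation).
#' Cysteines inside conserved domains (GTPase, FYVE, PX) and the CaaX cysteine
#' itself are excluded a priori from palmitoylation, the former because the
#' folded domain buries them, the latter because it is almost certainly
#' prenylated. All detectors are pure functions of their inputs.
#'
#' @name anchors
NULL

# Residues accepted at the two "a" positions of a strict aliphatic CaaX box.
CAAX_ALIPHATIC <- c("A", "V", "L", "I", "F", "M", "C", "S", "T")

#' Detect a C-terminal CaaX prenylation box
#'
#' A CaaX box is called iff the residue exactly 4th from the C-terminus is a
#' cysteine; prenyltransferases only modify C-terminally located cysteines,
#' so internal cysteines never yield a box. The box is flagged `strict` when
#' both following residues are aliphatic (A, V, L, I, F, M, C, S, T); the
#' default call is deliberately permissive about the "aa" residues so that
#' divergent boxes are still reported, with strictness recorded.
#'
#' @param sequence Amino-acid string.
#' @return A list with `cys_position`, `aa_residues`, `x_residue`, `strict`,
#'   or `NULL` when no box is present (including sequences shorter than 4).
#' @export
detect_caax <- function(sequence) {
  n <- nchar(sequence)
  if (n < 4) return(NULL)
  tail4 <- strsplit(substr(sequence, n - 3, n), "")[[1]]
  if (tail4[1] != "C") return(NULL)
  list(cys_position = n - 3L,
       aa_residues = paste(tail4[2:3], collapse = ""),
       x_residue = tail4[4],
       strict = all(tail4[2:3] %in% CAAX_ALIPHATIC))
}

#' Predict N-terminal myristoylation by ensemble vote
#'
#' Only a glycine at position 2 of the full-length sequence (immediately after
#' the initiator methionine) is a candidate: internal glycines can only be
#' myristoylated after proteolytic exposure, for which there is no evidence in
#' this protein family, so they are never evaluated. An eligible N-terminus is
#' scored by three deterministic surrogate scorers:
#'
#' * S1 (pattern): position 3 is not in \{E, D, R, K, H, P, F, Y, W\} and
#'   position 7 is not proline. An `X` at a constrained position fails.
#' * S2 (weight matrix): the shipped position-weight table summed over
#'   positions 2-9 is positive.
#' * S3 (composition): at least one of \{S, T, A, G, C, N\} at position 6
#'   or 7.
#'
#' The site is predicted iff at least `vote_threshold` scorers are positive.
#'
#' @param sequence Amino-acid string.
#' @param pwm Weight table, see [myr_pwm()].
#' @param vote_threshold Minimum positive votes (default 2 of 3).
#' @return List with `eligible`, `votes` (named logical of length 3),
#'   `predicted`.
#' @export
predict_myristoylation <- function(sequence, pwm = myr_pwm(),
                                   vote_threshold = 2L) {
  chars <- strsplit(sequence, "")[[1]]
  at <- function(i) if (i <= length(chars)) chars[i] else ""
  eligible <- length(chars) >= 2 && chars[1] == "M" && chars[2] == "G"
  votes <- c(S1 = FALSE, S2 = FALSE, S3 = FALSE)
  if (eligible) {
    votes["S1"] <- !(at(3) %in% c("E", "D", "R", "K", "H", "P", "F", "Y", "W",
                                  "X", "")) && at(7) != "P"
    score <- 0
    for (p in 2:9) {
      w <- pwm$weight[pwm$pos == p & pwm$aa == at(p)]
      if (length(w) == 1) score <- score + w
    }
    votes["S2"] <- score > 0
    votes["S3"] <- any(c(at(6), at(7)) %in% c("S", "T", "A", "G", "C", "N"))
  }
  list(eligible = eligible, votes = votes,
       predicted = eligible && sum(votes) >= vote_threshold)
}

#' Score all cysteines for S-palmitoylation
#'
#' Every cysteine yields one row. Exclusions are applied first: a cysteine
#' inside any detected domain span is excluded with reason `IN_DOMAIN`; the
#' CaaX cysteine is excluded with reason `CAAX_CYS`. Remaining cysteines are
#' scored by five deterministic surrogate scorers over the +/-9-residue
#' context window (the site itself excluded, clipped at the termini):
#'
#' * P1: mean Kyte-Doolittle hydropathy of the window >= 0.5
#' * P2: at least 2 basic residues (K, R, H) in the window
#' * P3: shipped per-residue weight table sums to > 0 over the window
#' * P4: no proline immediately after the cysteine and fewer than 4 acidic
#'   residues (D, E) in the window
#' * P5: `P1 AND P2`, but abstains when the cysteine has fewer than `flank`
#'   residues on either side (mirroring predictors that cannot evaluate
#'   near-terminal sites)
#'
#' A site is predicted iff at least `vote_threshold` of the non-abstaining
#' scorers vote positive. `region` places the site relative to the GTPase
#' domain span (`N_TERMINAL` before it, `C_TERMINAL` after it, otherwise
#' `INTERNAL`).
#'
#' @param sequence Amino-acid string.
#' @param domain_hits `data.frame` with columns `kind`, `start`, `end` (as
#'   returned by the domain scanners), or `NULL`.
#' @param caax Result of [detect_caax()] for this sequence, or `NULL`.
#' @param weights Per-residue weight vector, see [palm_weights()].
#' @param scale Hydropathy scale, see [kd_hydropathy()].
#' @param vote_threshold Minimum positive votes (default 3).
#' @param flank Window half-width and minimum flank for P5 (default 9).
#' @return `data.frame` with one row per cysteine: `position`, `region`,
#'   `P1`..`P5` (`"yes"`/`"no"`/`"abstain"`), `n_positive`, `n_voting`,
#'   `excluded`, `exclusion_reason`, `predicted`.
#' @export
find_palmitoylation_sites <- function(sequence, domain_hits = NULL,
                                      caax = NULL, weights = palm_weights(),
                                      scale = kd_hydropathy(),
                                      vote_threshold = 3L, flank = 9L) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  cys <- which(chars == "C")
  empty <- data.frame(position = integer(), region = character(),
                      P1 = character(), P2 = character(), P3 = character(),
                      P4 = character(), P5 = character(),
                      n_positive = integer(), n_voting = integer(),
                      excluded = logical(), exclusion_reason = character(),
                      predicted = logical(), stringsAsFactors = FALSE)
  if (length(cys) == 0) return(empty)

  gspan <- NULL
  if (!is.null(domain_hits) && nrow(domain_hits) > 0) {
    g <- domain_hits[domain_hits$kind == "GTPASE", , drop = FALSE]
    if (nrow(g) > 0) gspan <- c(g$start[1], g$end[1])
  }

  rows <- lapply(cys, function(pos) {
    region <- "INTERNAL"
    if (!is.null(gspan)) {
      if (pos < gspan[1]) region <- "N_TERMINAL"
      else if (pos > gspan[2]) region <- "C_TERMINAL"
    }
    excluded <- FALSE
    reason <- "none"
    if (!is.null(domain_hits) && nrow(domain_hits) > 0 &&
        any(pos >= domain_hits$start & pos <= domain_hits$end)) {
      excluded <- TRUE
      reason <- "IN_DOMAIN"
    } else if (!is.null(caax) && pos == caax$cys_position) {
      excluded <- TRUE
      reason <- "CAAX_CYS"
    }
    win_idx <- setdiff(max(1, pos - flank):min(n, pos + flank), pos)
    win <- chars[win_idx]
    p1 <- mean_hydropathy(win, scale) >= 0.5
    p2 <- sum(win %in% c("K", "R", "H")) >= 2
    w <- weights[win]
    w[is.na(w)] <- 0
    p3 <- sum(w) > 0
    p4 <- (pos == n || chars[pos + 1] != "P") &&
      sum(win %in% c("D", "E")) < 4
    p5_abstains <- (pos - 1) < flank || (n - pos) < flank
    p5 <- if (p5_abstains) NA else (p1 && p2)
    verdicts <- c(P1 = p1, P2 = p2, P3 = p3, P4 = p4, P5 = p5)
    n_voting <- sum(!is.na(verdicts))
    n_positive <- sum(verdicts, na.rm = TRUE)
    data.frame(position = pos, region = region,
               P1 = vote_str(p1), P2 = vote_str(p2), P3 = vote_str(p3),
               P4 = vote_str(p4), P5 = vote_str(p5),
               n_positive = n_positive, n_voting = n_voting,
               excluded = excluded, exclusion_reason = reason,
               predicted = !excluded && n_positive >= vote_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

vote_str <- function(v) {
  if (is.na(v)) "abstain" else if (v) "yes" else "no"
}

#' Detect a C-terminal tryptophan-rich motif
#'
#' Called iff the sequence has no CaaX box and its last `window` residues
#' contain exactly 2 or 3 tryptophans. A CaaX box takes precedence: a
#' prenylatable C-terminus is never reported as a W-motif.
#'
#' @param sequence Amino-acid string (length >= `window`).
#' @param caax Result of [detect_caax()]; computed from `sequence` if missing.
#' @param window Size of the terminal window (default 10).
#' @return List with `tryptophan_positions` (1-based, absolute) and `count`,
#'   or `NULL`.
#' @export
detect_w_motif <- function(sequence, caax = detect_caax(sequence),
                           window = 10L) {
  n <- nchar(sequence)
  if (n < window || !is.null(caax)) return(NULL)
  tail_start <- n - window + 1L
  chars <- strsplit(substr(sequence, tail_start, n), "")[[1]]
  pos <- tail_start - 1L + which(chars == "W")
  if (!(length(pos) %in% c(2L, 3L))) return(NULL)
  list(tryptophan_positions = pos, count = length(pos))
}
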