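#' Seeded synthetic-sequence and tip-state generator
#'
#' Builds Ras-family GTPase scaffolds with planted membrane-attachment
#' devices and known ground truth, plus simulated gain/loss tip states on a
#' tree. The generator is the package's testbed: every architecture class has
#' a deterministic exemplar whose planted device coordinates are recorded, so
#' detector and classifier behaviour can be checked against construction-time
#' truth rather than against external data.
#'
#' Filler positions are drawn from a deliberately inert alphabet
#' (A, E, Q, S, T, K, N, V, L, D) that excludes the residues required by any
#' shipped fingerprint (C, G, R, H, F, W) and the strongly hydrophobic I/M,
#' so that no motif, domain fingerprint, CaaX box, tryptophan motif or
#' transmembrane window can arise by chance; a rejection-resampling pass
#' backstops the remaining boundary cases. Point substitutions (for
#' robustness studies) touch filler positions only and draw from the same
#' alphabet; planted critical positions are never mutated.
#'
#' @name synthgen
NULL

FILLER_ALPHABET <- c("A", "E", "Q", "S", "T", "K", "N", "V", "L", "D")

# planted building blocks (fixed strings; coordinates recorded at assembly)
G1_MOTIF <- "GDSGVGKS"
G3_MOTIF <- "DTAG"
G4_MOTIF <- "NKKD"
MYR_START <- "MGNSSDKE"               # E. longa-derived myristoylation start
ACYL_START <- "MGCLSKCLIKSATLVA"      # dual acylation: Gly-2 + Cys-3/Cys-7
PALM_START <- "MSCLSKCLIKSATLVA"      # palmitoylation only (no Gly-2)
FYVE_CORE <- "RRHHCRNCG"
PX_CORE <- "RRFSDF"
CAAX_BOX <- "CVVM"
TM_BLOCK <- "LLILVVAGLIVLLIVAGLLIV"   # 21 residues, mean KD ~ 3.4
TM_LOOP <- "KSKDEKSKDEKSKDEKS"        # 17 charged residues between blocks
TM_SPACER <- "SKDESTCQESKDESKD"       # pre-TM linker; relict CaaX Cys at 7
TM_END <- "KSKDEKSK"
J_TAIL_2C <- "ATLVKSAKSTTCLVKCLIKVASAK"  # Cys 9 and 13 upstream of CaaX Cys
J_TAIL_1C <- "ATLVKSAKSTTALVKCLIKVASAK"
W_TAIL_3 <- "SNGSWGWWAK"
W_TAIL_2 <- "SNGSAGWWAK"

# --- piece buffer -----------------------------------------------------------
# Sequences are assembled from pieces; each piece is either planted (fixed
# string, protected from mutation except where noted) or filler. Named pieces
# have their final coordinates recorded as ground-truth motifs.

new_buf <- function() list(chars = character(), protected = logical(),
                           motifs = list())

add_planted <- function(buf, string, name = NULL, protect = TRUE) {
  chars <- strsplit(string, "")[[1]]
  start <- length(buf$chars) + 1L
  buf$chars <- c(buf$chars, chars)
  buf$protected <- c(buf$protected, rep(protect, length(chars)))
  if (!is.null(name)) {
    buf$motifs[[length(buf$motifs) + 1L]] <-
      list(name = name, start = start, end = start + length(chars) - 1L)
  }
  buf
}

add_filler <- function(buf, n) {
  buf$chars <- c(buf$chars, sample(FILLER_ALPHABET, n, replace = TRUE))
  buf$protected <- c(buf$protected, rep(FALSE, n))
  buf
}

finalize_buf <- function(buf) {
  seq <- paste(buf$chars, collapse = "")
  motifs <- do.call(rbind, lapply(buf$motifs, function(m) {
    data.frame(name = m$name, start = m$start, end = m$end,
               seq = substr(seq, m$start, m$end), stringsAsFactors = FALSE)
  }))
  if (is.null(motifs)) {
    motifs <- data.frame(name = character(), start = integer(),
                         end = integer(), seq = character(),
                         stringsAsFactors = FALSE)
  }
  list(sequence = seq, protected = buf$protected, motifs = motifs)
}

# Resample filler positions inside spurious fingerprint matches until none
# remain. A match is spurious if it is not exactly a recorded planted motif
# occurrence of the same pattern and it touches at least one filler position.
reject_resample <- function(buf, patterns = fingerprints(), max_iter = 50L) {
  for (iter in seq_len(max_iter)) {
    seq <- paste(buf$chars, collapse = "")
    planted_starts <- vapply(buf$motifs, function(m) m$start, 1L)
    names(planted_starts) <- vapply(buf$motifs, function(m) m$name, "")
    dirty <- integer()
    for (pname in names(patterns)) {
      w <- fingerprint_width(patterns[[pname]])
      for (s in match_fingerprint(seq, patterns[[pname]])) {
        ok <- any(names(planted_starts) == pname & planted_starts == s)
        span <- s:(s + w - 1L)
        if (!ok && any(!buf$protected[span])) {
          dirty <- c(dirty, span[!buf$protected[span]])
        }
      }
    }
    if (length(dirty) == 0) return(buf)
    dirty <- unique(dirty)
    buf$chars[dirty] <- sample(FILLER_ALPHABET, length(dirty), replace = TRUE)
  }
  stop("rejection resampling did not converge", call. = FALSE)
}

# --- scaffold ---------------------------------------------------------------

# internal: scaffold as a buffer, without the hypervariable tail
scaffold_body <- function() {
  buf <- new_buf()
  buf <- add_planted(buf, "M")
  buf <- add_filler(buf, 10)
  buf <- add_planted(buf, "R", "DIAG_R")   # beta-1 arginine, 2 before G1
  buf <- add_filler(buf, 1)
  buf <- add_planted(buf, G1_MOTIF, "G1")
  buf <- add_filler(buf, 59)
  buf <- add_planted(buf, G3_MOTIF, "G3")
  buf <- add_filler(buf, 29)
  buf <- add_planted(buf, G4_MOTIF, "G4")
  buf <- add_filler(buf, 45)
  buf
}

#' Generate a bare GTPase scaffold
#'
#' A ~174-residue Rheb-like core: the diagnostic beta-1 arginine two residues
#' before a planted G1 P-loop, G3 and G4 boxes at fixed offsets satisfying
#' the scanner's spacing constraints, inert filler elsewhere, and a
#' 12-residue hypervariable tail. The bare scaffold carries no
#' membrane-attachment device at all.
#'
#' @param seed Integer seed; the same seed always yields the same scaffold.
#' @return List with `record` (one-row protein set `data.frame`) and `truth`
#'   (ground-truth list: `motifs` coordinates, `protected` mask,
#'   `n_devices`/`c_devices` both empty).
#' @export
make_scaffold <- function(seed) {
  with_seed_(seed, {
    buf <- scaffold_body()
    buf <- add_filler(buf, 12)   # hypervariable tail
    buf <- reject_resample(buf)
    fin <- finalize_buf(buf)
    list(record = new_protein_set(paste0("scaffold_s", seed), fin$sequence),
         truth = list(class_label = "UNANCHORED", n_devices = character(),
                      c_devices = character(), motifs = fin$motifs,
                      protected = fin$protected))
  })
}

fyve_block <- function(buf, lead_m = FALSE) {
  if (lead_m) {
    buf <- add_planted(buf, "M")
    buf <- add_filler(buf, 5)
  } else {
    buf <- add_filler(buf, 6)
  }
  buf <- add_planted(buf, FYVE_CORE, "FYVE_CORE")
  buf <- add_filler(buf, 5)
  buf <- add_planted(buf, "CAEC", "CXXC_1")
  buf <- add_filler(buf, 1)
  buf <- add_planted(buf, "CSTC", "CXXC_2")
  buf <- add_filler(buf, 31)
  buf
}

px_block <- function(buf, lead_m = FALSE) {
  if (lead_m) {
    buf <- add_planted(buf, "M")
    buf <- add_filler(buf, 5)
  } else {
    buf <- add_filler(buf, 6)
  }
  buf <- add_planted(buf, PX_CORE, "PX_CORE")
  buf <- add_filler(buf, 48)
  buf
}

#' Generate an exemplar with a planted architecture
#'
#' Starts from the scaffold of [make_scaffold()] and plants, per class, the
#' N-terminal device block (myristoylation start, dual-acylation start,
#' FYVE or PX fingerprint block) and/or the C-terminal device (CaaX box,
#' palmitoylatable pre-CaaX cysteines, four-transmembrane extension with the
#' relict internal CaaX cysteine, or tryptophan-rich tail), then applies
#' seeded point substitutions at `mutation_rate` to filler positions only.
#'
#' @param class_label One of `"A"`..`"L"`.
#' @param seed Integer seed.
#' @param mutation_rate Per-residue substitution probability on filler
#'   positions, in \[0, 0.2\].
#' @param j_palm_count For class J: 1 or 2 planted pre-CaaX cysteines
#'   (default 2, the *Thecamonas*-style variant).
#' @param j_myr For class J: plant the myristoylation start (default `TRUE`).
#' @param l_w_count For class L: 2 or 3 tail tryptophans (default 3).
#' @param id Record id (default derived from class and seed).
#' @return List with `record` and `truth` as in [make_scaffold()]; `truth`
#'   additionally records the planted device sets and motif coordinates.
#' @export
plant_architecture <- function(class_label, seed, mutation_rate = 0,
                               j_palm_count = 2L, j_myr = TRUE,
                               l_w_count = 3L, id = NULL) {
  if (!(class_label %in% LETTERS[1:12])) {
    stop("unknown architecture class: ", class_label, call. = FALSE)
  }
  stopifnot(mutation_rate >= 0, mutation_rate <= 0.2)
  with_seed_(seed, {
    buf <- new_buf()
    n_dev <- character()
    c_dev <- character()

    # N-terminal device block (replaces the scaffold's initiator Met)
    if (class_label %in% c("D", "G")) {
      buf <- add_planted(buf, ACYL_START, "ACYL_START")
      n_dev <- c(n_dev, "MYR", "PALM_N")
    } else if (class_label == "I") {
      buf <- add_planted(buf, PALM_START, "PALM_START")
      n_dev <- c(n_dev, "PALM_N")
    } else if (class_label %in% c("E", "H") || (class_label == "J" && j_myr)) {
      buf <- add_planted(buf, MYR_START, "MYR_START")
      n_dev <- c(n_dev, "MYR")
    }
    if (class_label %in% c("C", "D", "E", "F")) {
      buf <- fyve_block(buf, lead_m = length(buf$chars) == 0L)
      n_dev <- c(n_dev, "FYVE")
    } else if (class_label == "B") {
      buf <- px_block(buf, lead_m = TRUE)
      n_dev <- c(n_dev, "PX")
    }
    if (length(buf$chars) == 0L) buf <- add_planted(buf, "M")

    # scaffold body minus its initiator Met
    body <- scaffold_body()
    offset <- length(buf$chars) - 1L   # body position 1 (the Met) is dropped
    buf$chars <- c(buf$chars, body$chars[-1])
    buf$protected <- c(buf$protected, body$protected[-1])
    for (m in body$motifs) {
      buf$motifs[[length(buf$motifs) + 1L]] <-
        list(name = m$name, start = m$start + offset, end = m$end + offset)
    }

    # C-terminal device (in place of the hypervariable tail)
    if (class_label %in% c("A", "B", "C", "I")) {
      buf <- add_filler(buf, 8)
      buf <- add_planted(buf, CAAX_BOX, "CAAX")
      c_dev <- c(c_dev, "CAAX")
    } else if (class_label == "J") {
      tail <- if (j_palm_count == 2L) J_TAIL_2C else J_TAIL_1C
      buf <- add_planted(buf, tail, "J_TAIL")
      buf <- add_planted(buf, CAAX_BOX, "CAAX")
      c_dev <- c(c_dev, "CAAX", "PALM_C")
    } else if (class_label == "K") {
      buf <- add_planted(buf, TM_SPACER, "TM_SPACER")
      for (i in 1:4) {
        buf <- add_planted(buf, TM_BLOCK, paste0("TM", i))
        if (i < 4) buf <- add_planted(buf, TM_LOOP)
      }
      buf <- add_planted(buf, TM_END)
      c_dev <- c(c_dev, "TM")
    } else if (class_label == "L") {
      buf <- add_filler(buf, 2)
      buf <- add_planted(buf, if (l_w_count == 3L) W_TAIL_3 else W_TAIL_2,
                         "W_MOTIF")
      c_dev <- c(c_dev, "WMOTIF")
    } else {
      buf <- add_filler(buf, 12)   # plain hypervariable tail (classes D-H)
    }

    buf <- reject_resample(buf)

    # point substitutions on filler positions only
    if (mutation_rate > 0) {
      mutable <- which(!buf$protected)
      hit <- mutable[stats::runif(length(mutable)) < mutation_rate]
      for (i in hit) {
        buf$chars[i] <- sample(setdiff(FILLER_ALPHABET, buf$chars[i]), 1)
      }
    }

    fin <- finalize_buf(buf)
    stopifnot(all(fin$motifs$seq ==
                    substring(fin$sequence, fin$motifs$start, fin$motifs$end)))
    if (is.null(id)) id <- sprintf("exemplar_%s_s%d", class_label, seed)
    list(record = new_protein_set(id, fin$sequence),
         truth = list(class_label = class_label,
                      n_devices = sort(n_dev), c_devices = sort(c_dev),
                      motifs = fin$motifs, protected = fin$protected,
                      mutation_rate = mutation_rate))
  })
}

#' Generate one exemplar per architecture class
#'
#' @param seed Integer seed.
#' @param classes Classes to generate (default all twelve).
#' @param mutation_rate Passed to [plant_architecture()].
#' @param ... Further arguments passed to [plant_architecture()].
#' @return List with `proteins` (protein set `data.frame`) and `truths`
#'   (named list of ground-truth lists, one per class).
#' @export
rheb_exemplars <- function(seed, classes = LETTERS[1:12], mutation_rate = 0,
                           ...) {
  out <- lapply(classes, function(cl)
    plant_architecture(cl, seed, mutation_rate, ...))
  proteins <- do.call(rbind, lapply(out, function(x) x$record))
  truths <- lapply(out, function(x) x$truth)
  names(truths) <- proteins$id
  list(proteins = proteins, truths = truths)
}

#' Simulate presence/absence tip states under gain and loss
#'
#' The character is gained on the edge leading to `gain_node` and then lost
#' independently on each descendant edge with probability `loss_prob`;
#' losses are absorbing, so no loss is recorded below an earlier loss and the
#' planted loss edges are never nested.
#'
#' @param tree An `ape::phylo` tree.
#' @param gain_node Node number (or tip/node label) on whose parent edge the
#'   character is gained.
#' @param loss_prob Per-edge loss probability in \[0, 1\].
#' @param seed Integer seed.
#' @return List with `states` (named 0/1 integer vector over all tips),
#'   `gain_node`, and `loss_edges` (`data.frame` of `parent`, `child`).
#' @export
simulate_tip_states <- function(tree, gain_node, loss_prob, seed) {
  validate_tree(tree)
  stopifnot(loss_prob >= 0, loss_prob <= 1)
  if (is.character(gain_node)) {
    all_labels <- c(tree$tip.label,
                    if (!is.null(tree$node.label)) tree$node.label)
    idx <- match(gain_node, tree$tip.label)
    if (is.na(idx) && !is.null(tree$node.label)) {
      nidx <- match(gain_node, tree$node.label)
      if (!is.na(nidx)) idx <- ape::Ntip(tree) + nidx
    }
    if (is.na(idx)) stop("gain node '", gain_node, "' not found in tree",
                         call. = FALSE)
    gain_node <- idx
  }
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  if (gain_node < 1 || gain_node > n_nodes) {
    stop("gain node ", gain_node, " not in tree", call. = FALSE)
  }
  with_seed_(seed, {
    kids <- node_children(tree)
    ntip <- ape::Ntip(tree)
    alive <- logical(n_nodes)
    alive[gain_node] <- TRUE
    losses <- list()
    visit <- gain_node
    while (length(visit) > 0) {
      node <- visit[1]; visit <- visit[-1]
      for (ch in kids[[node]]) {
        if (stats::runif(1) < loss_prob) {
          losses[[length(losses) + 1L]] <- c(node, ch)
        } else {
          alive[ch] <- TRUE
          visit <- c(visit, ch)
        }
      }
    }
    loss_df <- if (length(losses) == 0) {
      data.frame(parent = integer(), child = integer())
    } else {
      m <- do.call(rbind, losses)
      data.frame(parent = m[, 1], child = m[, 2])
    }
    list(states = setNames(as.integer(alive[seq_len(ntip)]), tree$tip.label),
         gain_node = gain_node, loss_edges = loss_df)
  })
}
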