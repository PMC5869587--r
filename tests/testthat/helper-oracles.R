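# Independent oracle implementations used to cross-check the package.
# These are deliberately written in a different style (explicit loops, no
# shared helpers) so that agreement is meaningful.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte-Doolittle values typed independently of the shipped table.
KD_ORACLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2, X = 0)

random_seq <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# naive CaaX check: is the 4th character from the end a cysteine?
naive_caax <- function(seq) {
  n <- nchar(seq)
  if (n < 4) return(FALSE)
  substr(seq, n - 3, n - 3) == "C"
}

# naive qualifying-center finder for the TM caller
naive_tm_centers <- function(seq, window = 19, threshold = 1.6) {
  chars <- strsplit(seq, "")[[1]]
  half <- (window - 1) / 2
  out <- integer()
  if (length(chars) < window) return(out)
  for (center in (half + 1):(length(chars) - half)) {
    total <- 0L  # tenths, so the window sum is exact
    for (j in (center - half):(center + half)) {
      total <- total + as.integer(round(10 * KD_ORACLE[[chars[j]]]))
    }
    if (total / (window * 10) >= threshold) out <- c(out, center)
  }
  out
}

# naive full TM segment caller (runs, +/- half expansion, merge, length filter)
naive_tm_segments <- function(seq, window = 19, threshold = 1.6,
                              merge_gap = 5, min_length = 15) {
  centers <- naive_tm_centers(seq, window, threshold)
  if (length(centers) == 0) return(cbind(start = integer(), end = integer()))
  half <- (window - 1) / 2
  n <- nchar(seq)
  segs <- list()
  run_start <- centers[1]
  prev <- centers[1]
  for (c_ in centers[-1]) {
    if (c_ != prev + 1) {
      segs[[length(segs) + 1]] <- c(run_start, prev)
      run_start <- c_
    }
    prev <- c_
  }
  segs[[length(segs) + 1]] <- c(run_start, prev)
  spans <- t(sapply(segs, function(s) c(max(1, s[1] - half), min(n, s[2] + half))))
  merged <- spans[1, , drop = FALSE]
  if (nrow(spans) > 1) {
    for (i in 2:nrow(spans)) {
      last <- nrow(merged)
      if (spans[i, 1] - merged[last, 2] - 1 < merge_gap) {
        merged[last, 2] <- max(merged[last, 2], spans[i, 2])
      } else {
        merged <- rbind(merged, spans[i, ])
      }
    }
  }
  keep <- merged[, 2] - merged[, 1] + 1 >= min_length
  m <- merged[keep, , drop = FALSE]
  colnames(m) <- c("start", "end")
  m
}

# all nodes below (and including) a node, from the edge matrix
.descend <- function(edge, node) {
  out <- node
  frontier <- node
  while (length(frontier) > 0) {
    kids <- edge[edge[, 1] %in% frontier, 2]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

# Brute-force Dollo: enumerate all 0/1 labelings of internal nodes and of
# ?-tips, keep those with exactly one gain (root birth or a single 0->1
# edge), and return the minimum number of 1->0 edges.
brute_dollo_losses <- function(tree, states) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  root <- ntip + 1
  st <- setNames(rep("?", ntip), tree$tip.label)
  st[names(states)] <- as.character(states)
  fixed <- integer(0)
  free <- integer(0)
  lab <- integer(n_nodes)
  for (i in 1:ntip) {
    if (st[i] == "?") free <- c(free, i) else lab[i] <- as.integer(st[i])
  }
  free <- c(free, (ntip + 1):n_nodes)
  best <- Inf
  for (mask in 0:(2^length(free) - 1)) {
    lab[free] <- bitwAnd(bitwShiftR(mask, seq_along(free) - 1), 1)
    gains <- lab[root]
    losses <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- lab[tree$edge[e, 1]]
      ch <- lab[tree$edge[e, 2]]
      if (p == 0 && ch == 1) gains <- gains + 1
      if (p == 1 && ch == 0) losses <- losses + 1
    }
    if (gains <= 1 && losses < best) best <- losses
  }
  best
}

# Brute-force Fitch: enumerate internal (and ?-tip) labelings over the
# observed alphabet, count edges whose endpoints differ, minimize.
brute_fitch_changes <- function(tree, states) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  st <- setNames(rep("?", ntip), tree$tip.label)
  st[names(states)] <- as.character(states)
  alphabet <- sort(unique(st[st != "?"]))
  lab <- character(n_nodes)
  free <- integer(0)
  for (i in 1:ntip) {
    if (st[i] == "?") free <- c(free, i) else lab[i] <- st[i]
  }
  free <- c(free, (ntip + 1):n_nodes)
  k <- length(alphabet)
  best <- Inf
  idx <- rep(1, length(free))
  repeat {
    lab[free] <- alphabet[idx]
    changes <- 0
    for (e in seq_len(nrow(tree$edge))) {
      if (lab[tree$edge[e, 1]] != lab[tree$edge[e, 2]]) changes <- changes + 1
    }
    if (changes < best) best <- changes
    # increment mixed-radix counter
    j <- 1
    while (j <= length(free)) {
      idx[j] <- idx[j] + 1
      if (idx[j] <= k) break
      idx[j] <- 1
      j <- j + 1
    }
    if (j > length(free)) break
  }
  best
}
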