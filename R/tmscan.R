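#' Hydropathy-based transmembrane segment caller
#'
#' A deliberately simple sliding-window caller in the classic Kyte-Doolittle
#' style, used here to recognise the four-transmembrane C-terminal extension
#' of the Rheb-TM paralog. The mean hydropathy of every `window`-residue
#' window is assigned to its centre residue; a centre qualifies when the mean
#' reaches `threshold`; maximal runs of consecutive qualifying centres are
#' expanded by half a window on each side (clipped to the sequence), runs
#' separated by fewer than `merge_gap` residues are merged, and merged
#' segments shorter than `min_length` are discarded. `X` residues contribute
#' hydropathy 0. No topology (inside/outside) is predicted.
#'
#' @param sequence Amino-acid string.
#' @param window Odd window length, >= 7 (default 19).
#' @param threshold Minimum mean hydropathy of a qualifying window
#'   (default 1.6).
#' @param merge_gap Segments separated by fewer than this many residues are
#'   merged (default 5).
#' @param min_length Minimum reported segment length (default 15).
#' @param scale Hydropathy scale, see [kd_hydropathy()].
#' @return `data.frame` with columns `start`, `end`, `mean_hydropathy`
#'   (the mean of the qualifying window means within the segment, hence always
#'   at or above `threshold`); zero rows when no segment is called or the
#'   sequence is shorter than `window`.
#' @export
call_tm_segments <- function(sequence, window = 19L, threshold = 1.6,
                             merge_gap = 5L, min_length = 15L,
                             scale = kd_hydropathy()) {
  empty <- data.frame(start = integer(), end = integer(),
                      mean_hydropathy = numeric())
  n <- nchar(sequence)
  if (n < window) return(empty)
  half <- (window - 1L) %/% 2L
  wm <- tm_window_means(sequence, window, scale)
  centers <- wm$center
  means <- wm$mean_hydropathy
  qual <- centers[means >= threshold]
  if (length(qual) == 0) return(empty)
  qmeans <- means[match(qual, centers)]
  run_id <- cumsum(c(1L, diff(qual) != 1L))
  segs <- do.call(rbind, lapply(split(seq_along(qual), run_id), function(i) {
    data.frame(start = max(1L, min(qual[i]) - half),
               end = min(n, max(qual[i]) + half),
               mean_hydropathy = mean(qmeans[i]))
  }))
  segs <- merge_segments(segs, merge_gap)
  segs <- segs[segs$end - segs$start + 1L >= min_length, , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

#' Sliding-window hydropathy means
#'
#' The mean hydropathy of every `window`-residue window, assigned to its
#' centre residue. This is the quantity [call_tm_segments()] thresholds;
#' it is exposed so that calibration can be inspected directly.
#'
#' @param sequence Amino-acid string (length >= `window`).
#' @param window Odd window length, >= 7.
#' @param scale Hydropathy scale, see [kd_hydropathy()].
#' @return `data.frame` with columns `center`, `mean_hydropathy`.
#' @export
tm_window_means <- function(sequence, window = 19L, scale = kd_hydropathy()) {
  stopifnot(window >= 7L, window %% 2L == 1L, nchar(sequence) >= window)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  h <- scale[chars]
  h[is.na(h)] <- 0
  half <- (window - 1L) %/% 2L
  # hydropathy values are tenths; integer running sums keep window means
  # exact, so threshold ties are resolved identically everywhere
  cs <- c(0, cumsum(as.integer(round(h * 10))))
  centers <- (half + 1L):(n - half)
  data.frame(center = centers,
             mean_hydropathy = (cs[centers + half + 1L] - cs[centers - half]) /
               (window * 10))
}

# Merge sorted segments separated by < merge_gap residues; the merged score
# is the length-weighted mean of the component scores. Idempotent.
merge_segments <- function(segs, merge_gap) {
  if (nrow(segs) <= 1) return(segs)
  segs <- segs[order(segs$start), , drop = FALSE]
  out <- segs[1, , drop = FALSE]
  for (i in 2:nrow(segs)) {
    k <- nrow(out)
    if (segs$start[i] - out$end[k] - 1L < merge_gap) {
      w1 <- out$end[k] - out$start[k] + 1L
      w2 <- segs$end[i] - segs$start[i] + 1L
      out$mean_hydropathy[k] <-
        (out$mean_hydropathy[k] * w1 + segs$mean_hydropathy[i] * w2) / (w1 + w2)
      out$end[k] <- max(out$end[k], segs$end[i])
    } else {
      out <- rbind(out, segs[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}
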