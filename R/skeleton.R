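## Topology-preserving iterative thinning (Guo & Hall two-subiteration
## scheme), vectorized over the whole grid. Deletion requires connectivity
## number C == 1, so the 8-connectivity of every component is preserved.

ghNeighbors <- function(m) {
  list(p2 = shiftMat(m, -1,  0), p3 = shiftMat(m, -1,  1),
       p4 = shiftMat(m,  0,  1), p5 = shiftMat(m,  1,  1),
       p6 = shiftMat(m,  1,  0), p7 = shiftMat(m,  1, -1),
       p8 = shiftMat(m,  0, -1), p9 = shiftMat(m, -1, -1))
}

## One deletion pass. Candidates are applied in two checkerboard subfields
## with the deletion conditions recomputed in between: two 8-adjacent pixels
## are never removed on the same evaluation, so the connectivity-number
## guard (C == 1) really does preserve the topology of each component.
ghPass <- function(m, odd, parity) {
  for (par in 0:1) {
    n <- ghNeighbors(m)
    C <- (!n$p2 & (n$p3 | n$p4)) + (!n$p4 & (n$p5 | n$p6)) +
         (!n$p6 & (n$p7 | n$p8)) + (!n$p8 & (n$p9 | n$p2))
    N1 <- (n$p9 | n$p2) + (n$p3 | n$p4) + (n$p5 | n$p6) + (n$p7 | n$p8)
    N2 <- (n$p2 | n$p3) + (n$p4 | n$p5) + (n$p6 | n$p7) + (n$p8 | n$p9)
    N <- pmin(N1, N2)
    m3 <- if (odd) ((n$p2 | n$p3 | !n$p5) & n$p4)
          else     ((n$p6 | n$p7 | !n$p9) & n$p8)
    del <- (m > 0) & (C == 1) & (N >= 2) & (N <= 3) & !m3 & (parity == par)
    m[del] <- 0
  }
  m
}

thinBinary <- function(m) {
  m <- (m > 0) + 0
  parity <- (row(m) + col(m)) %% 2
  repeat {
    before <- sum(m)
    m <- ghPass(m, odd = FALSE, parity = parity)
    m <- ghPass(m, odd = TRUE, parity = parity)
    if (sum(m) == before) break
  }
  ## Guo-Hall output is one pixel thick almost everywhere; clear any residual
  ## fully-set 2x2 block by deleting one simple pixel of the block.
  repeat {
    blk <- m[-nrow(m), -ncol(m)] * m[-1, -ncol(m)] * m[-nrow(m), -1] * m[-1, -1]
    idx <- which(blk > 0, arr.ind = TRUE)
    if (!nrow(idx)) break
    r <- idx[1, 1]; c <- idx[1, 2]
    removed <- FALSE
    for (off in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
      cand <- m
      cand[r + off[1], c + off[2]] <- 0
      if (isSimpleDeletion(m, r + off[1], c + off[2])) { m <- cand; removed <- TRUE; break }
    }
    if (!removed) m[r, c] <- 0  # degenerate; forced break of the block
  }
  m
}

## A deletion is "simple" if it neither splits nor shortens topology locally:
## connectivity number of the pixel equals 1 and it is not an endpoint.
isSimpleDeletion <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  val <- function(rr, cc) if (rr < 1 || rr > nr || cc < 1 || cc > nc) 0 else m[rr, cc]
  p2 <- val(r - 1, c);     p3 <- val(r - 1, c + 1)
  p4 <- val(r,     c + 1); p5 <- val(r + 1, c + 1)
  p6 <- val(r + 1, c);     p7 <- val(r + 1, c - 1)
  p8 <- val(r,     c - 1); p9 <- val(r - 1, c - 1)
  C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
       (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
  nb <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  C == 1 && nb >= 2
}

neighborCount <- function(m) {
  shiftMat(m, -1, 0) + shiftMat(m, 1, 0) + shiftMat(m, 0, -1) +
    shiftMat(m, 0, 1) + shiftMat(m, -1, -1) + shiftMat(m, -1, 1) +
    shiftMat(m, 1, -1) + shiftMat(m, 1, 1)
}

## Remove short terminal branches (< maxLen px) hanging off junctions.
## Open line ends that never reach a junction are left alone.
pruneSpurs <- function(m, maxLen = 3L) {
  if (maxLen < 1L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  fgNeighborsOf <- function(i, exclude = -1L) {
    r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      ii <- (cc - 1L) * nr + rr
      if (m[ii] > 0 && ii != exclude) out <- c(out, ii)
    }
    out
  }
  repeat {
    nb <- neighborCount(m)
    ends <- which(m > 0 & nb == 1)
    removedAny <- FALSE
    for (e in ends) {
      if (m[e] == 0) next
      path <- integer(0)
      cur <- e; prev <- -1L
      isSpur <- FALSE
      for (step in seq_len(maxLen)) {
        path <- c(path, cur)
        nbr <- fgNeighborsOf(cur, exclude = prev)
        if (length(nbr) == 0) break            # isolated open end: keep
        if (length(nbr) >= 2) {                # cur itself sits on a junction
          path <- path[path != cur]; isSpur <- TRUE; break
        }
        nxt <- nbr[1]
        if (length(fgNeighborsOf(nxt)) >= 3) { isSpur <- TRUE; break }
        prev <- cur; cur <- nxt
      }
      if (isSpur && length(path)) { m[path] <- 0; removedAny <- TRUE }
    }
    if (!removedAny) break
  }
  m
}

#' Skeletonize a binary vessel map by iterative thinning
#'
#' Iteratively thins the segmented vessels until only connected centerlines
#' with a thickness of one pixel remain, using the Guo-Hall two-subiteration
#' thinning scheme. Deletion is gated on the local connectivity number, so
#' the 8-connected component structure of the input is preserved. Terminal
#' spurs shorter than \code{pruneSpurLen} pixels that branch off junctions
#' are pruned afterwards (set \code{pruneSpurLen = 0} to disable).
#'
#' @param x a [VesselMap-class], or a binary matrix.
#' @param pruneSpurLen prune terminal branches shorter than this many pixels
#'   (default 3; 0 disables pruning).
#' @param scanWidthMm scan width, required when \code{x} is a bare matrix.
#' @return a [SkeletonMap-class].
#' @examples
#' bar <- matrix(0, 30, 30); bar[14:18, 3:28] <- 1
#' sum(pixels(skeletonizeMap(bar, scanWidthMm = 3)))
#' @export
skeletonizeMap <- function(x, pruneSpurLen = 3L, scanWidthMm = NULL) {
  if (is(x, "VesselMap")) {
    m <- x@pixels
    sw <- x@scanWidthMm
  } else {
    m <- asMatrix(x)
    sw <- if (is.null(scanWidthMm)) 1 else scanWidthMm
  }
  sk <- thinBinary(m)
  if (pruneSpurLen > 0L) sk <- pruneSpurs(sk, as.integer(pruneSpurLen))
  new("SkeletonMap", pixels = sk, scanWidthMm = sw)
}
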