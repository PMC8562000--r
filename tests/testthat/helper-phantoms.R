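## Shared phantom fixtures, generated once per test run and memoized.

.phantomCache <- new.env(parent = emptyenv())

cachedPhantom <- function(..., .key = NULL) {
  args <- list(...)
  key <- if (is.null(.key)) paste(deparse(args), collapse = "") else .key
  if (is.null(.phantomCache[[key]]))
    .phantomCache[[key]] <- generatePhantom(do.call(phantomParams, args))
  .phantomCache[[key]]
}

## small fast phantom for structural checks
smallPhantom <- function(seed, targetVad = 0.3, fazAreaMm2 = 0.08,
                         noiseSigma = 0.05, ...) {
  cachedPhantom(imageSidePx = 122L, scanWidthMm = 1.0,
                fazAreaMm2 = fazAreaMm2, nSeedVessels = 10L,
                targetVad = targetVad, noiseSigma = noiseSigma,
                rngSeed = seed, ...)
}

## full-size phantom matching the instrument geometry
fullPhantom <- function(seed, targetVad = 0.32, noiseSigma = 0.05,
                        fazAreaMm2 = 0.3, fazNoiseLevel = 0.05, ...) {
  cachedPhantom(targetVad = targetVad, noiseSigma = noiseSigma,
                fazAreaMm2 = fazAreaMm2, fazNoiseLevel = fazNoiseLevel,
                rngSeed = seed, ...)
}

rotate90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

diceCoef <- function(a, b) 2 * sum(a * b) / (sum(a) + sum(b))

## independent exhaustive 256-bin Otsu search (between-class variance)
otsuExhaustiveBin <- function(m) {
  b <- pmin(floor(m * 256), 255)
  h <- tabulate(b + 1, 256)
  lv <- 0:255
  best <- -1; bt <- 0L
  for (t in 0:254) {
    w0 <- sum(h[1:(t + 1)]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(lv[1:(t + 1)] * h[1:(t + 1)]) / w0
    mu1 <- sum(lv[(t + 2):256] * h[(t + 2):256]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; bt <- t }
  }
  bt
}

## brute-force AUC: concordant pairs count 1, ties 1/2
aucBruteForce <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## all permutations of 1..n (small n)
allPerms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- allPerms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}
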