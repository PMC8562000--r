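#' @import methods
#' @importFrom stats rnorm runif rbinom quantile sd cor pt rlnorm
#' @importFrom utils head write.csv
NULL

clip01 <- function(x) pmin(pmax(x, 0), 1)

## out[r, c] = m[r + dr, c + dc]; zero outside (pad value configurable)
shiftMat <- function(m, dr, dc, pad = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(pad, nr, nc)
  rs <- max(1, 1 - dr):min(nr, nr - dr)
  cs <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

## Run expr with a private RNG stream; global .Random.seed is untouched.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Label connected components of a binary grid
#'
#' 8-connected (default) or 4-connected labelling of the foreground pixels of
#' a binary matrix. Labels are positive integers in first-encounter order;
#' background pixels receive 0.
#'
#' @param mask binary matrix (nonzero = foreground).
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels, same dimensions as \code{mask}.
#' @export
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask > 0)
  lab <- matrix(0L, nr, nc)
  if (!length(fg)) return(lab)
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_along(fg)
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  rr <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  edges <- vector("list", length(shifts))
  for (k in seq_along(shifts)) {
    s <- shifts[[k]]
    r2 <- rr + s[1]; c2 <- cc + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- id[j] > 0L
    edges[[k]] <- cbind(id[fg[ok]][keep], id[j][keep])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(el) && nrow(el))
    g <- igraph::add_edges(g, as.vector(t(el)))
  memb <- igraph::components(g)$membership
  lab[fg] <- as.integer(memb)
  lab
}

## pixel sizes of all components (named by label)
componentSizes <- function(lab) {
  tab <- tabulate(lab[lab > 0L])
  tab
}

asMatrix <- function(x) {
  if (is(x, "Image")) x <- EBImage::imageData(x)
  as.matrix(x)
}

## matrix -> EBImage Image (grayscale)
asImage <- function(m) EBImage::Image(m)

## rotate a matrix by k*90 degrees counterclockwise
rot90 <- function(m, k = 1) {
  k <- k %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}
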