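#' Evaluate code with a temporary RNG seed
#'
#' Runs \code{code} under \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so seeded generators do not perturb the global stream.
#'
#' @param seed integer seed, or \code{NULL} to use the current stream.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive a child seed from a parent seed and an offset, kept within the
# 32-bit integer range R requires of set.seed().
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

#' Label connected components of a binary image
#'
#' Thin wrapper over \code{EBImage::bwlabel} (4-connected) that optionally
#' merges labels across diagonal adjacencies to yield 8-connected components,
#' the foreground convention used throughout this package.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  if (connectivity == 4 || max(lab) <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # pairs of labels touching diagonally
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  # union-find over label ids
  parent <- seq_len(max(lab))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(pairs))) {
    a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_along(parent), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

# Foreground centroid (row, col) of a logical matrix, in pixel units.
mask_centroid <- function(grid) {
  idx <- which(grid, arr.ind = TRUE)
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

# Boundary pixels: foreground with at least one 4-neighbour outside the
# foreground (image border counts as outside).
boundary_mask <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- grid
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  nb <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  core & !nb
}

# Haldane map function: distance in cM -> recombination fraction.
haldane_r <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2
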