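# position grid for one LG: markers plus pseudomarkers at `step` cM
lg_grid <- function(pos, step) {
  if (step <= 0) return(list(pos = pos, is_marker = rep(TRUE, length(pos))))
  grid <- sort(unique(c(pos, seq(min(pos), max(pos), by = step))))
  # collapse grid points indistinguishable from a marker
  keep <- rep(TRUE, length(grid))
  for (i in seq_along(grid))
    if (!any(abs(pos - grid[i]) < 1e-9) &&
        any(abs(pos - grid[i]) < 1e-6)) keep[i] <- FALSE
  grid <- grid[keep]
  list(pos = grid,
       is_marker = vapply(grid, function(g) any(abs(pos - g) < 1e-9), logical(1)))
}

# 4x4 transition matrix over classes (ac, ad, bc, bd) for a gap of d cM:
# Kronecker product of the maternal and paternal 2x2 Haldane transitions.
fourway_transition <- function(d_cm) {
  r <- haldane_r(d_cm)
  t2 <- matrix(c(1 - r, r, r, 1 - r), 2, 2)
  t2 %x% t2
}

#' Four-way genotype probabilities along the genome
#'
#' Forward-backward hidden-Markov smoothing per individual per linkage
#' group. Hidden states are the four genotype classes (ac, ad, bc, bd);
#' transitions between positions \eqn{d} cM apart are the Kronecker product
#' of two 2x2 Haldane transitions (maternal and paternal meioses
#' independent); emissions give probability \eqn{1 - e} to the observed
#' class and \eqn{e/3} to each other class, with uniform emission at missing
#' genotypes and pseudomarkers.
#'
#' @param cross a \code{fourway_cross} (codes 0--4).
#' @param step pseudomarker spacing, cM (default 1; 0 = markers only).
#' @param error_rate genotyping error rate \eqn{e} (default \code{1e-4}).
#' @return Object of class \code{"genoprobs"}: per linkage group a list with
#'   \code{pos}, \code{is_marker} and \code{probs} (n x positions x 4 array;
#'   each row of the class dimension sums to 1).
#' @export
calc_genoprob <- function(cross, step = 1, error_rate = 1e-4) {
  stopifnot(inherits(cross, "fourway_cross"),
            all(cross$geno %in% 0:4), error_rate >= 0, error_rate < 1)
  n <- nrow(cross$geno)
  out <- list()
  for (g in unique(cross$map$lg)) {
    sel <- which(cross$map$lg == g)
    pos <- cross$map$pos[sel]
    if (is.unsorted(pos)) stop("marker positions not nondecreasing in LG ", g)
    grid <- lg_grid(pos, step)
    np <- length(grid$pos)
    # emission matrices per position: n x 4
    emis <- vector("list", np)
    for (k in seq_len(np)) {
      if (grid$is_marker[k]) {
        mk <- sel[which.min(abs(pos - grid$pos[k]))]
        obs <- cross$geno[, mk]
        E <- matrix(1, n, 4)
        typed <- obs > 0L
        if (any(typed)) {
          E[typed, ] <- error_rate / 3
          E[cbind(which(typed), obs[typed])] <- 1 - error_rate
        }
        emis[[k]] <- E
      } else emis[[k]] <- matrix(1, n, 4)
    }
    trans <- lapply(seq_len(np - 1L), function(k)
      fourway_transition(grid$pos[k + 1] - grid$pos[k]))
    # forward
    alpha <- vector("list", np)
    a <- emis[[1]] * 0.25
    alpha[[1]] <- a / rowSums(a)
    for (k in seq_len(np - 1L)) {
      a <- (alpha[[k]] %*% trans[[k]]) * emis[[k + 1]]
      alpha[[k + 1]] <- a / rowSums(a)
    }
    # backward
    beta <- matrix(1, n, 4)
    probs <- array(NA_real_, c(n, np, 4))
    pr <- alpha[[np]] * beta
    probs[, np, ] <- pr / rowSums(pr)
    if (np > 1L) for (k in (np - 1L):1L) {
      beta <- (beta * emis[[k + 1]]) %*% t(trans[[k]])
      beta <- beta / rowSums(beta)
      pr <- alpha[[k]] * beta
      probs[, k, ] <- pr / rowSums(pr)
    }
    out[[as.character(g)]] <- list(pos = grid$pos, is_marker = grid$is_marker,
                                   probs = probs)
  }
  structure(list(lg = out, step = step, error_rate = error_rate,
                 ids = cross$ids),
            class = "genoprobs")
}

#' @export
print.genoprobs <- function(x, ...) {
  np <- sum(vapply(x$lg, function(l) length(l$pos), integer(1)))
  cat(sprintf("<genoprobs: %d individuals, %d positions on %d linkage groups, step %g cM>\n",
              dim(x$lg[[1]]$probs)[1], np, length(x$lg), x$step))
  invisible(x)
}

# flatten a genoprobs object into a per-position list of design blocks:
# list of (lg, pos, P) where P = n x 3 matrix of class-probability contrasts
# (class 1 dropped as reference)
genoprob_positions <- function(gp) {
  out <- list()
  for (g in names(gp$lg)) {
    l <- gp$lg[[g]]
    for (k in seq_along(l$pos))
      out[[length(out) + 1L]] <- list(lg = as.integer(g), pos = l$pos[k],
                                      P = l$probs[, k, 2:4, drop = TRUE])
  }
  out
}
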