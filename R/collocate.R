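#' Collocate QTL across years
#'
#' QTL of the same trait on the same linkage group are grouped when every
#' pair of peaks lies within \code{window_cm} (complete-linkage clustering
#' cut at the window, so the criterion is a strict pairwise \code{<=}).
#' Groups must span at least \code{min_years} distinct years: 3 recovers the
#' all-years consensus set, 2 the secondary set. An interval-overlap mode
#' groups QTL whose support intervals pairwise overlap instead.
#'
#' @param qtl data frame with columns \code{trait}, \code{year}, \code{lg},
#'   \code{pos} (and \code{ci_lo}, \code{ci_hi} for the interval mode).
#' @param window_cm collocation window, cM (default 8; peak mode only).
#' @param min_years minimum distinct years per group (default 2).
#' @param mode \code{"peak"} (default, peak distance) or \code{"interval"}
#'   (1.5-LOD interval overlap).
#' @return Data frame of class \code{"collocation_report"}: one row per
#'   group with \code{trait}, \code{lg}, \code{pos_mean}, \code{n_qtl},
#'   \code{n_years}, \code{years} (comma-separated). Empty when fewer than
#'   two years of models are present.
#' @export
collocate <- function(qtl, window_cm = 8, min_years = 2,
                      mode = c("peak", "interval")) {
  mode <- match.arg(mode)
  stopifnot(all(c("trait", "year", "lg", "pos") %in% names(qtl)))
  empty <- data.frame(trait = character(0), lg = integer(0),
                      pos_mean = numeric(0), n_qtl = integer(0),
                      n_years = integer(0), years = character(0))
  if (nrow(qtl) == 0L || length(unique(qtl$year)) < 2L)
    return(structure(empty, class = c("collocation_report", "data.frame")))
  out <- list()
  for (tr in unique(qtl$trait)) for (g in unique(qtl$lg[qtl$trait == tr])) {
    sub <- qtl[qtl$trait == tr & qtl$lg == g, , drop = FALSE]
    grp <- if (nrow(sub) == 1L) 1L else {
      D <- if (mode == "peak") stats::dist(sub$pos) else {
        n <- nrow(sub)
        m <- matrix(0, n, n)
        for (i in seq_len(n - 1)) for (j in (i + 1):n)
          m[i, j] <- m[j, i] <-
            as.numeric(!(sub$ci_lo[i] <= sub$ci_hi[j] &
                         sub$ci_lo[j] <= sub$ci_hi[i]))
        stats::as.dist(m)
      }
      h <- if (mode == "peak") window_cm else 0.5
      stats::cutree(stats::hclust(D, method = "complete"), h = h)
    }
    for (k in unique(grp)) {
      mem <- sub[grp == k, , drop = FALSE]
      yrs <- sort(unique(mem$year))
      if (length(yrs) >= min_years)
        out[[length(out) + 1L]] <- data.frame(
          trait = tr, lg = g, pos_mean = mean(mem$pos), n_qtl = nrow(mem),
          n_years = length(yrs), years = paste(yrs, collapse = ","))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  structure(res, class = c("collocation_report", "data.frame"))
}

#' Stepwise QTL mapping with covariates in a complete diallel
#'
#' For every ordered (trait, covariate) pair with distinct traits, runs the
#' additive stepwise selection per year with the covariate included,
#' collocates the resulting QTL across all years, and flags groups absent
#' from the univariate (no-covariate) all-year results as novel.
#'
#' @param gp_by_year named list of \code{genoprobs} (one per year), or a
#'   single \code{genoprobs} shared across years.
#' @param traits data frame with \code{id}, \code{year} and one numeric
#'   column per trait (e.g. BLUPs), rows aligned per year to the genotype
#'   probabilities.
#' @param trait_set character vector of trait columns to cross.
#' @param n_perm,alpha permutation settings per trait/covariate/year
#'   combination.
#' @param window_cm collocation window (default 8).
#' @param seed integer seed.
#' @param ... passed to \code{\link{stepwise_additive}}.
#' @return Data frame: \code{trait}, \code{covariate}, \code{lg},
#'   \code{pos_mean}, \code{n_years}, \code{novel}.
#' @export
covariate_diallel <- function(gp_by_year, traits, trait_set,
                              n_perm = 200, alpha = 0.05, window_cm = 8,
                              seed = 1, ...) {
  stopifnot(length(trait_set) >= 2L,
            all(trait_set %in% names(traits)))
  if (anyDuplicated(trait_set))
    stop("trait used as its own covariate: trait_set must be distinct")
  years <- sort(unique(traits$year))
  get_gp <- function(y) if (inherits(gp_by_year, "genoprobs")) gp_by_year
                        else gp_by_year[[as.character(y)]]
  run_years <- function(tr, cv) {
    rows <- list()
    for (y in years) {
      sub <- traits[traits$year == y, , drop = FALSE]
      cov <- if (is.null(cv)) NULL else sub[[cv]]
      if (!is.null(cv) && cv == tr) stop("trait used as its own covariate")
      pen <- perm_threshold(get_gp(y), sub[[tr]], cov, n_perm = n_perm,
                            alpha = alpha,
                            seed = child_seed(seed, y * 37 + match(tr, trait_set)))
      m <- stepwise_additive(get_gp(y), sub[[tr]], cov, pen, ...)
      if (nrow(m$qtls))
        rows[[length(rows) + 1L]] <- cbind(trait = tr, year = y, m$qtls)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  # univariate reference: all-year collocated groups per trait
  uni <- list()
  for (tr in trait_set) {
    q <- run_years(tr, NULL)
    if (!is.null(q))
      uni[[tr]] <- collocate(q, window_cm, min_years = length(years))
  }
  out <- list()
  for (tr in trait_set) for (cv in setdiff(trait_set, tr)) {
    q <- run_years(tr, cv)
    if (is.null(q)) next
    gr <- collocate(q, window_cm, min_years = length(years))
    if (nrow(gr) == 0L) next
    ref <- uni[[tr]]
    gr$novel <- vapply(seq_len(nrow(gr)), function(i) {
      if (is.null(ref) || nrow(ref) == 0L) return(TRUE)
      !any(ref$lg == gr$lg[i] & abs(ref$pos_mean - gr$pos_mean[i]) <= window_cm)
    }, logical(1))
    gr$covariate <- cv
    out[[length(out) + 1L]] <-
      gr[, c("trait", "covariate", "lg", "pos_mean", "n_years", "novel")]
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(trait = character(0), covariate = character(0), lg = integer(0),
               pos_mean = numeric(0), n_years = integer(0), novel = logical(0))
}
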