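#' Build a linkage map
#'
#' @param n_lg number of linkage groups (study default 12).
#' @param length_cm length of each group, cM (recycled).
#' @param spacing_cm marker spacing, cM.
#' @return Data frame of class \code{"linkage_map"}: \code{marker},
#'   \code{lg}, \code{pos} (cM, nondecreasing within each group).
#' @export
sim_linkage_map <- function(n_lg = 12, length_cm = 80, spacing_cm = 1) {
  length_cm <- rep_len(length_cm, n_lg)
  rows <- lapply(seq_len(n_lg), function(g) {
    pos <- seq(0, length_cm[g], by = spacing_cm)
    data.frame(marker = sprintf("M%d_%d", g, seq_along(pos)),
               lg = g, pos = pos)
  })
  structure(do.call(rbind, rows), class = c("linkage_map", "data.frame"))
}

#' A study-scale linkage map
#'
#' 12 linkage groups carrying 976 markers in total, emulating the density of
#' the consensus map underlying the four-way cross (roughly one marker per
#' cM over ~80 cM groups).
#' @return A \code{\link{sim_linkage_map}} data frame with 976 markers.
#' @export
study_map <- function() {
  # 12 groups; 976 = 8*82 + 4*80 markers
  n_mark <- c(rep(82, 8), rep(80, 4))
  rows <- lapply(1:12, function(g) {
    pos <- seq(0, 81, length.out = n_mark[g])
    data.frame(marker = sprintf("M%d_%d", g, seq_along(pos)), lg = g,
               pos = round(pos, 3))
  })
  structure(do.call(rbind, rows), class = c("linkage_map", "data.frame"))
}

#' Simulate offspring of a four-way cross
#'
#' Each offspring inherits one maternal allele (\code{a}/\code{b}) and one
#' paternal allele (\code{c}/\code{d}) per locus; crossovers follow the
#' Haldane model (no interference), so the recombination fraction between
#' positions \eqn{d} cM apart is \eqn{r = (1 - e^{-2d/100})/2}. Genotype
#' classes are coded 1 = ac, 2 = ad, 3 = bc, 4 = bd (0 = missing).
#'
#' @param map a linkage map data frame (\code{marker}, \code{lg}, \code{pos}).
#' @param n number of offspring.
#' @param seed integer seed.
#' @param extra_positions optional data frame (\code{lg}, \code{pos}) of
#'   additional loci (e.g. QTL) to simulate; their classes are returned in
#'   the \code{extra_geno} element but not in the marker matrix.
#' @param missing_rate fraction of marker genotypes set to 0 (default 0).
#' @return Object of class \code{"fourway_cross"}: \code{map}, \code{geno}
#'   (n x m integer matrix, columns = markers), \code{ids},
#'   \code{extra_geno} (n x nrow(extra_positions) or NULL).
#' @export
simulate_cross <- function(map, n, seed = NULL, extra_positions = NULL,
                           missing_rate = 0) {
  stopifnot(nrow(map) >= 1L, n >= 1L)
  with_seed(seed, {
    lgs <- unique(map$lg)
    geno <- matrix(0L, n, nrow(map))
    colnames(geno) <- map$marker
    extra <- if (!is.null(extra_positions))
      matrix(0L, n, nrow(extra_positions)) else NULL
    sim_parent <- function(pos) {
      # n x length(pos) matrix of inherited-allele indicators (0 = first allele)
      m <- matrix(0L, n, length(pos))
      m[, 1] <- stats::rbinom(n, 1, 0.5)
      if (length(pos) > 1L) for (j in 2:length(pos)) {
        r <- haldane_r(pos[j] - pos[j - 1])
        sw <- stats::rbinom(n, 1, r)
        m[, j] <- bitwXor(m[, j - 1], sw)
      }
      m
    }
    for (g in lgs) {
      sel <- which(map$lg == g)
      pos <- map$pos[sel]
      stopifnot(!is.unsorted(pos))
      xsel <- if (!is.null(extra_positions)) which(extra_positions$lg == g) else integer(0)
      xpos <- if (length(xsel)) extra_positions$pos[xsel] else numeric(0)
      allpos <- c(pos, xpos)
      ord <- order(allpos)
      mat <- sim_parent(allpos[ord])[, order(ord), drop = FALSE]
      pat <- sim_parent(allpos[ord])[, order(ord), drop = FALSE]
      code <- 2L * mat + pat + 1L
      geno[, sel] <- code[, seq_along(pos), drop = FALSE]
      if (length(xsel))
        extra[, xsel] <- code[, length(pos) + seq_along(xpos), drop = FALSE]
    }
    if (missing_rate > 0) {
      drop <- matrix(stats::runif(length(geno)) < missing_rate, n)
      geno[drop] <- 0L
    }
    structure(list(map = map, geno = geno,
                   ids = sprintf("ind%03d", seq_len(n)), extra_geno = extra),
              class = "fourway_cross")
  })
}

#' @export
print.fourway_cross <- function(x, ...) {
  cat(sprintf("<fourway_cross: %d individuals, %d markers on %d linkage groups>\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$lg))))
  invisible(x)
}

#' Write a four-way cross in fourway-csv format
#'
#' Row 1: marker names; row 2: linkage-group labels; row 3: cM positions;
#' then one row per individual (first column = ID, genotype codes 1 = ac,
#' 2 = ad, 3 = bc, 4 = bd, 0 = missing).
#'
#' @param cross a \code{fourway_cross}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_fourway_csv <- function(cross, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", cross$map$marker), collapse = ","), con)
  writeLines(paste(c("", cross$map$lg), collapse = ","), con)
  writeLines(paste(c("", cross$map$pos), collapse = ","), con)
  for (i in seq_len(nrow(cross$geno)))
    writeLines(paste(c(cross$ids[i], cross$geno[i, ]), collapse = ","), con)
  invisible(path)
}

#' Read a four-way cross from fourway-csv format
#' @param path CSV path in the dialect written by \code{\link{write_fourway_csv}}.
#' @return A \code{fourway_cross}.
#' @export
read_fourway_csv <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) >= 4L)
  split1 <- function(s) strsplit(s, ",", fixed = TRUE)[[1]]
  markers <- split1(lines[1])[-1]
  lg <- as.integer(split1(lines[2])[-1])
  pos <- as.numeric(split1(lines[3])[-1])
  body <- strsplit(lines[-(1:3)], ",", fixed = TRUE)
  ids <- vapply(body, `[`, character(1), 1L)
  geno <- t(vapply(body, function(r) as.integer(r[-1]), integer(length(markers))))
  if (!all(geno %in% 0:4)) stop("invalid genotype codes (expected 0..4)")
  colnames(geno) <- markers
  map <- structure(data.frame(marker = markers, lg = lg, pos = pos),
                   class = c("linkage_map", "data.frame"))
  for (g in unique(lg)) if (is.unsorted(pos[lg == g]))
    stop("map positions not nondecreasing within linkage group ", g)
  structure(list(map = map, geno = geno, ids = ids, extra_geno = NULL),
            class = "fourway_cross")
}
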