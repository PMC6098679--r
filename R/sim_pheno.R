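#' Specify a planted QTL
#'
#' @param lg linkage group; the QTL is planted at the map marker nearest to
#'   \code{pos}.
#' @param pos position, cM.
#' @param frac fraction of the total genotype-mean phenotypic variance the
#'   QTL explains (class frequencies taken as equal).
#' @param pattern genotype-class effect pattern (length 4, classes ac, ad,
#'   bc, bd); default a maternal-allele contrast. The pattern is centered and
#'   rescaled so its equal-frequency variance equals \code{frac}.
#' @return List of class \code{"qtl_spec"}.
#' @export
qtl_spec <- function(lg, pos, frac, pattern = c(-1, -1, 1, 1)) {
  stopifnot(frac >= 0, frac < 1, length(pattern) == 4, stats::var(pattern) > 0)
  structure(list(lg = lg, pos = pos, frac = frac, pattern = pattern),
            class = "qtl_spec")
}

# class-effect vector scaled to variance v (equal class frequencies)
scaled_effects <- function(pattern, v) {
  p <- pattern - mean(pattern)
  p * sqrt(v / mean(p^2))
}

# nearest map marker to (lg, pos); returns column index into cross$geno
nearest_marker <- function(map, lg, pos) {
  sel <- which(map$lg == lg)
  if (!length(sel)) stop("QTL linkage group ", lg, " not on the map")
  if (pos < min(map$pos[sel]) - 1e-9 || pos > max(map$pos[sel]) + 1e-9)
    stop("QTL position ", pos, " outside linkage group ", lg, " map range")
  sel[which.min(abs(map$pos[sel] - pos))]
}

#' Simulate repeated-year phenotypes on a four-way cross
#'
#' The genotypic value of individual \eqn{i} is the sum of its planted QTL
#' class effects and a polygenic term drawn from \eqn{N(0, \sigma_p^2 A)}
#' with \eqn{A} the marker-based relationship matrix. Phenotypes are
#' generated at the fruit level: each fruit's value is the genotypic value
#' plus an additive year effect plus \eqn{N(0, \sigma_e^2)} fruit noise, so
#' the genotype-year mean of \code{n_fruit} fruit carries residual variance
#' \eqn{\sigma_e^2 / n_{fruit}}.
#'
#' Variance bookkeeping is on the genotype-mean scale with total variance 1:
#' QTL fractions and \code{polygenic_h2} are fractions of that total, and the
#' default \eqn{\sigma_e = \sqrt{(1 - \sum frac - h^2_{poly})\, n_{fruit}}}
#' makes the realized fractions match. A configuration error is raised when
#' the requested fractions reach or exceed the total.
#'
#' @param cross a \code{\link{simulate_cross}} object.
#' @param qtl list of \code{\link{qtl_spec}} (possibly empty).
#' @param polygenic_h2 fraction of variance from the polygenic background.
#' @param n_years number of years (default 3).
#' @param n_fruit fruit per genotype per year (default 25).
#' @param sigma_e per-fruit residual SD; \code{NULL} (default) derives it
#'   from the variance fractions as above.
#' @param year_effects numeric vector of additive year shifts (length
#'   \code{n_years}), or \code{NULL} to draw them from \eqn{N(0, 0.25^2)}.
#' @param trait trait name stamped into the tables.
#' @param seed integer seed.
#' @return List of class \code{"sim_pheno"}: \code{per_fruit} (id, year,
#'   fruit, trait, value), \code{per_genotype} (id, year, trait, value, n),
#'   \code{g} (true genotypic values), \code{qtl_classes} (n x #QTL matrix of
#'   planted-QTL genotype classes), \code{qtl} (specs with realized marker
#'   positions), \code{sigma_e}, \code{year_effects}.
#' @export
simulate_phenotypes <- function(cross, qtl = list(), polygenic_h2 = 0,
                                n_years = 3, n_fruit = 25, sigma_e = NULL,
                                year_effects = NULL, trait = "trait",
                                seed = NULL) {
  stopifnot(inherits(cross, "fourway_cross"))
  if (inherits(qtl, "qtl_spec")) qtl <- list(qtl)
  qfrac <- sum(vapply(qtl, `[[`, numeric(1), "frac"))
  if (qfrac + polygenic_h2 >= 1)
    stop("configuration error: requested QTL + polygenic variance (",
         qfrac + polygenic_h2, ") >= total variance")
  n <- nrow(cross$geno)
  with_seed(seed, {
    g <- numeric(n)
    qcl <- NULL
    if (length(qtl)) {
      qcl <- matrix(0L, n, length(qtl))
      for (j in seq_along(qtl)) {
        q <- qtl[[j]]
        mk <- nearest_marker(cross$map, q$lg, q$pos)
        qtl[[j]]$marker <- cross$map$marker[mk]
        qtl[[j]]$pos_realized <- cross$map$pos[mk]
        cl <- cross$geno[, mk]
        if (any(cl == 0L)) cl[cl == 0L] <- sample(1:4, sum(cl == 0L), TRUE)
        qcl[, j] <- cl
        g <- g + scaled_effects(q$pattern, q$frac)[cl]
      }
    }
    if (polygenic_h2 > 0) {
      A <- kinship(cross$geno)$A
      eg <- eigen(A, symmetric = TRUE)
      d <- pmax(eg$values, 0)
      g <- g + as.vector(eg$vectors %*% (sqrt(polygenic_h2 * d) * stats::rnorm(n)))
    }
    if (is.null(sigma_e)) sigma_e <- sqrt((1 - qfrac - polygenic_h2) * n_fruit)
    if (is.null(year_effects)) year_effects <- stats::rnorm(n_years, 0, 0.25)
    stopifnot(length(year_effects) == n_years)
    per_fruit <- vector("list", n_years)
    for (y in seq_len(n_years)) {
      vals <- rep(g, each = n_fruit) + year_effects[y] +
        stats::rnorm(n * n_fruit, 0, sigma_e)
      per_fruit[[y]] <- data.frame(
        id = rep(cross$ids, each = n_fruit), year = y,
        fruit = rep(seq_len(n_fruit), n), trait = trait, value = vals)
    }
    per_fruit <- do.call(rbind, per_fruit)
    per_genotype <- genotype_means(per_fruit)
    structure(list(per_fruit = per_fruit, per_genotype = per_genotype, g = g,
                   qtl_classes = qcl, qtl = qtl, sigma_e = sigma_e,
                   year_effects = year_effects),
              class = "sim_pheno")
  })
}

#' Simulate per-fruit silhouette parameters with genetic shape and size signal
#'
#' Two independent latent traits are simulated on the cross — an elongation
#' (shape) latent and a length (size) latent — each with its own planted QTL
#' and polygenic fraction. Per-fruit latents map to silhouette parameters:
#' length-to-width ratio \code{lw = lw_mean + lw_scale * shape latent} and
#' fruit length \code{L = L_mean + L_scale * size latent} (both clamped to
#' sensible ranges), from which \code{a = L/2}, \code{b = a/lw}. Because size
#' and shape latents are independent, image-derived size traits carry no
#' shape-QTL signal and vice versa.
#'
#' @param cross a \code{fourway_cross}.
#' @param shape_qtl,size_qtl lists of \code{\link{qtl_spec}} for the two
#'   latents.
#' @param shape_h2,size_h2 polygenic fractions of the latents.
#' @param n_years,n_fruit design size (defaults 3 and 25).
#' @param lw_mean,lw_scale,L_mean,L_scale genotype-latent-to-parameter
#'   mapping (defaults: LW ratio 1.45 +- 0.18 SD, length 16 +- 1.8 mm SD
#'   across genotypes).
#' @param lw_fruit_sd,L_fruit_sd fruit-to-fruit SD around the genotype-year
#'   value (defaults 0.08 and 0.9 mm; within-genotype variance is an
#'   assumption of the generator, not an estimate).
#' @param seed integer seed.
#' @return Data frame with one row per fruit: \code{id}, \code{year},
#'   \code{fruit}, \code{a}, \code{b}, \code{lw_true}, \code{length_true};
#'   attributes \code{shape_sim} and \code{size_sim} hold the latent
#'   \code{sim_pheno} objects.
#' @export
sim_fruit_shapes <- function(cross, shape_qtl = list(), size_qtl = list(),
                             shape_h2 = 0.2, size_h2 = 0.2, n_years = 3,
                             n_fruit = 25, lw_mean = 1.45, lw_scale = 0.18,
                             L_mean = 16, L_scale = 1.8, lw_fruit_sd = 0.08,
                             L_fruit_sd = 0.9, seed = NULL) {
  with_seed(seed, {
    s1 <- simulate_phenotypes(cross, shape_qtl, shape_h2, n_years, n_fruit,
                              trait = "shape_latent",
                              seed = sample.int(2^30, 1))
    s2 <- simulate_phenotypes(cross, size_qtl, size_h2, n_years, n_fruit,
                              trait = "size_latent",
                              seed = sample.int(2^30, 1))
    # genotype-year latent means carry the genetic + year signal; fruit-level
    # variation enters through the shape parameters directly
    key_f <- paste(s1$per_fruit$id, s1$per_fruit$year)
    key_g <- paste(s1$per_genotype$id, s1$per_genotype$year)
    z_shape <- s1$per_genotype$value[match(key_f, key_g)]
    z_size <- s2$per_genotype$value[match(key_f, key_g)]
    nf <- length(key_f)
    lw <- pmax(lw_mean + lw_scale * z_shape +
                 stats::rnorm(nf, 0, lw_fruit_sd), 1.02)
    L <- pmax(L_mean + L_scale * z_size + stats::rnorm(nf, 0, L_fruit_sd), 6)
    out <- data.frame(id = s1$per_fruit$id, year = s1$per_fruit$year,
                      fruit = s1$per_fruit$fruit, a = L / 2, b = L / 2 / lw,
                      lw_true = lw, length_true = L)
    attr(out, "shape_sim") <- s1
    attr(out, "size_sim") <- s2
    out
  })
}

#' A matched bell-versus-elongated shape panel
#'
#' Generates fruit masks from two shape classes whose length and width
#' distributions are shared, so the length-to-width ratio is uninformative
#' about class while the silhouette (bell asymmetry and shoulder) differs.
#' For bell fruit the width parameter is rescaled so the transverse chord at
#' the silhouette's centroid matches the nominal width.
#'
#' @param n_per_class masks per class.
#' @param px_per_mm rasterization scale (default 4).
#' @param length_mm,lw,n_exp,bell_k sampling ranges as in
#'   \code{\link{random_fruits}}.
#' @param seed integer seed.
#' @return List with \code{masks} (list of \code{fruit_mask}) and
#'   \code{class} (factor \code{"elongated"}/\code{"bell"}).
#' @export
shape_panel <- function(n_per_class, px_per_mm = 4, length_mm = c(13, 19),
                        lw = c(1.35, 1.75), n_exp = c(2, 2.4),
                        bell_k = c(0.35, 0.55), seed = NULL) {
  with_seed(seed, {
    masks <- list(); cls <- character(0)
    for (class in c("elongated", "bell")) {
      for (i in seq_len(n_per_class)) {
        L <- stats::runif(1, length_mm[1], length_mm[2])
        r <- stats::runif(1, lw[1], lw[2])
        nn <- stats::runif(1, n_exp[1], n_exp[2])
        a <- L / 2; b <- a / r
        if (class == "bell") {
          k <- stats::runif(1, bell_k[1], bell_k[2])
          # rescale b so the half-width at the profile centroid equals b
          t <- seq(-1, 1, length.out = 401)
          w <- (1 - k * t) * (1 - t^2)^(1 / nn)
          tbar <- sum(t * w) / sum(w)
          b <- b / ((1 - k * tbar) * (1 - tbar^2)^(1 / nn))
          p <- shape_params("bell", a = a, b = min(b, a), n_exp = nn,
                            bell_k = k, rotation = stats::runif(1, 0, pi))
        } else {
          p <- shape_params("elongated", a = a, b = b, n_exp = nn,
                            rotation = stats::runif(1, 0, pi))
        }
        masks[[length(masks) + 1L]] <- make_fruit_mask(p, px_per_mm)
        cls <- c(cls, class)
      }
    }
    list(masks = masks, class = factor(cls))
  })
}
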