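#' Default pipeline configuration
#'
#' Demo-scale run: 48 genotypes on a 2-linkage-group map, 2 years, 25 fruit
#' per genotype-year, 200 permutations, with one planted shape QTL.
#'
#' @param out_dir output directory.
#' @param seed master seed; stage seeds are derived from it by fixed offsets.
#' @return Nested configuration list (YAML-serializable).
#' @export
default_config <- function(out_dir = tempfile("berrymorph_run"), seed = 1) {
  list(seed = seed, out_dir = out_dir,
       stages = list(simulate = TRUE, phenotype = TRUE, ph = TRUE,
                     blup = TRUE, scan = TRUE, collocate = TRUE,
                     report = TRUE),
       scene = list(n_fruit = 25, px_per_mm = 4, ref_diameter_mm = 30,
                    n_ref_circles_per_side = 6),
       cross = list(n = 48, n_lg = 2, length_cm = 80, spacing_cm = 5),
       phenotype = list(n_years = 2, shape_h2 = 0.2, size_h2 = 0.2,
                        shape_qtl = list(list(lg = 2, pos = 40, frac = 0.2)),
                        size_qtl = list()),
       ph = list(n_annuli = 4, n_levels = 30, bandwidth_frac = 0.2),
       scan = list(step = 2, n_perm = 200, alpha = 0.05, window_cm = 8,
                   min_years = 2))
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return The configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  utils::modifyList(base, cfg)
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

md5_of <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full simulation-to-QTL pipeline
#'
#' Executes the enabled stages in order — simulate, phenotype, ph, blup,
#' scan, collocate, report — each reading only the declared artifacts of the
#' stages before it, and writes a JSON manifest recording the configuration,
#' derived stage seeds, per-stage timings and output-file checksums. A rerun
#' with an identical configuration reproduces identical checksums for the
#' deterministic stages.
#'
#' @param config configuration list (see \code{\link{default_config}}) or a
#'   YAML path.
#' @return The manifest list, invisibly; artifacts under
#'   \code{config$out_dir}.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- function(...) file.path(config$out_dir, ...)
  manifest <- list(config = config,
                   seeds = list(), stages = list(), files = list(),
                   r_version = as.character(getRversion()))
  tic <- function() proc.time()[["elapsed"]]
  stage_on <- function(s) isTRUE(config$stages[[s]])
  need <- function(path, stage) {
    if (!file.exists(path))
      stop("stage-dependency error: stage '", stage, "' needs missing artifact ",
           path)
    path
  }

  ## simulate -----------------------------------------------------------
  if (stage_on("simulate")) {
    t0 <- tic()
    s_seed <- child_seed(config$seed, 1)
    manifest$seeds$simulate <- s_seed
    map <- sim_linkage_map(config$cross$n_lg, config$cross$length_cm,
                           config$cross$spacing_cm)
    cross <- simulate_cross(map, config$cross$n, seed = s_seed)
    write_fourway_csv(cross, od("cross.csv"))
    qspec <- lapply(config$phenotype$shape_qtl, function(q)
      qtl_spec(q$lg, q$pos, q$frac))
    qsize <- lapply(config$phenotype$size_qtl, function(q)
      qtl_spec(q$lg, q$pos, q$frac))
    shapes <- sim_fruit_shapes(cross, qspec, qsize,
                               shape_h2 = config$phenotype$shape_h2,
                               size_h2 = config$phenotype$size_h2,
                               n_years = config$phenotype$n_years,
                               n_fruit = config$scene$n_fruit,
                               seed = child_seed(config$seed, 2))
    utils::write.csv(shapes, od("fruit_truth.csv"), row.names = FALSE)
    dir.create(od("scenes"), showWarnings = FALSE)
    for (y in seq_len(config$phenotype$n_years)) {
      for (id in cross$ids) {
        sub <- shapes[shapes$id == id & shapes$year == y, , drop = FALSE]
        fruits <- lapply(seq_len(nrow(sub)), function(i)
          shape_params("elongated", a = sub$a[i], b = min(sub$b[i], sub$a[i]),
                       n_exp = 2.2,
                       rotation = (i * 37) %% 180 / 180 * pi))
        sc <- compose_scene(scene_spec(fruits,
                                       config$scene$n_ref_circles_per_side,
                                       config$scene$ref_diameter_mm,
                                       config$scene$px_per_mm),
                            seed = child_seed(s_seed, match(id, cross$ids) * 100 + y))
        write_scene_png(sc, od("scenes", sprintf("%s_y%d.png", id, y)))
      }
    }
    manifest$stages$simulate <- list(status = "done", seconds = tic() - t0)
  } else manifest$stages$simulate <- list(status = "skipped")

  ## phenotype ----------------------------------------------------------
  if (stage_on("phenotype")) {
    t0 <- tic()
    need(od("cross.csv"), "phenotype")
    scenes <- list.files(od("scenes"), pattern = "\\.png$", full.names = TRUE)
    if (!length(scenes)) stop("stage-dependency error: no scenes for 'phenotype'")
    ppm <- config$scene$px_per_mm
    ref_area <- pi * (config$scene$ref_diameter_mm / 2 * ppm)^2
    dir.create(od("masks"), showWarnings = FALSE)
    traits <- list()
    for (sc in scenes) {
      sid <- sub("\\.png$", "", basename(sc))
      img <- read_scene_png(sc)
      seg <- segment_scene(img, ref_expected_area_px = ref_area,
                           scene_id = sid)
      cal <- calibrate_scale(seg$refs, config$scene$ref_diameter_mm)
      fruit <- apply_scale(seg$fruit, cal)
      tab <- measure_scene(fruit, scene_id = sid)
      tab$mm_per_px <- cal$mm_per_px
      traits[[length(traits) + 1L]] <- tab
      for (i in seq_along(fruit))
        png::writePNG(matrix(as.numeric(fruit[[i]]$grid),
                             nrow(fruit[[i]]$grid)),
                      od("masks", sprintf("%s_f%02d.png", sid, i)))
    }
    utils::write.csv(do.call(rbind, traits), od("traits.csv"),
                     row.names = FALSE)
    manifest$stages$phenotype <- list(status = "done", seconds = tic() - t0)
  } else manifest$stages$phenotype <- list(status = "skipped")

  ## ph ------------------------------------------------------------------
  if (stage_on("ph")) {
    t0 <- tic()
    tr <- utils::read.csv(need(od("traits.csv"), "ph"))
    masks <- list.files(od("masks"), pattern = "\\.png$", full.names = TRUE)
    if (!length(masks)) stop("stage-dependency error: no masks for 'ph'")
    ids <- sub("\\.png$", "", basename(masks))
    desc <- t(vapply(masks, function(p) {
      g <- png::readPNG(p) > 0.5
      as.numeric(ph_descriptor(fruit_mask(g, 1),
                               n_annuli = config$ph$n_annuli,
                               n_levels = config$ph$n_levels,
                               bandwidth_frac = config$ph$bandwidth_frac))
    }, numeric(config$ph$n_annuli * config$ph$n_levels)))
    rownames(desc) <- ids
    utils::write.csv(data.frame(fruit = ids, desc, check.names = FALSE),
                     od("descriptors.csv"), row.names = FALSE)
    # per-year PCA; mask ids look like <id>_y<year>_f<k>
    year <- as.integer(sub(".*_y(\\d+)_f\\d+$", "\\1", ids))
    scores <- matrix(NA_real_, length(ids), 2,
                     dimnames = list(ids, c("PC1", "PC2")))
    for (y in unique(year)) {
      sel <- year == y
      pc <- fit_pca(desc[sel, , drop = FALSE], k = 2)
      scores[sel, ] <- pc$scores[, 1:2]
    }
    sc_df <- data.frame(fruit = ids, PC1 = scores[, 1], PC2 = scores[, 2])
    utils::write.csv(sc_df, od("scores.csv"), row.names = FALSE)
    # merge into the per-fruit seven-trait table
    key <- sprintf("%s_f%02d", tr$scene_id, tr$fruit_id)
    m <- match(key, ids)
    tr$PC1 <- scores[m, 1]; tr$PC2 <- scores[m, 2]
    tr$id <- sub("_y\\d+$", "", tr$scene_id)
    tr$year <- as.integer(sub(".*_y(\\d+)$", "\\1", tr$scene_id))
    utils::write.csv(tr, od("fruit_traits.csv"), row.names = FALSE)
    manifest$stages$ph <- list(status = "done", seconds = tic() - t0)
  } else manifest$stages$ph <- list(status = "skipped")

  ## blup ----------------------------------------------------------------
  trait_cols <- c(length = "length_mm", width = "width_mm", area = "area_mm2",
                  lw_ratio = "lw_ratio", eccentricity = "eccentricity",
                  PC1 = "PC1", PC2 = "PC2")
  if (stage_on("blup")) {
    t0 <- tic()
    tr <- utils::read.csv(need(od("fruit_traits.csv"), "blup"))
    cross <- read_fourway_csv(need(od("cross.csv"), "blup"))
    long <- do.call(rbind, lapply(names(trait_cols), function(nm)
      data.frame(id = tr$id, year = tr$year, trait = nm,
                 value = tr[[trait_cols[[nm]]]])))
    means <- genotype_means(long)
    K <- kinship(cross)
    utils::write.csv(data.frame(id = K$ids, K$A, check.names = FALSE),
                     od("kinship.csv"), row.names = FALSE)
    fits <- fit_all_traits(means, K)
    utils::write.csv(fits$blups, od("blups.csv"), row.names = FALSE)
    utils::write.csv(fits$h2, od("h2.csv"), row.names = FALSE)
    manifest$stages$blup <- list(status = "done", seconds = tic() - t0)
  } else manifest$stages$blup <- list(status = "skipped")

  ## scan ----------------------------------------------------------------
  if (stage_on("scan")) {
    t0 <- tic()
    blups <- utils::read.csv(need(od("blups.csv"), "scan"))
    cross <- read_fourway_csv(need(od("cross.csv"), "scan"))
    gp <- calc_genoprob(cross, step = config$scan$step)
    scans <- list(); qtls <- list()
    for (tt in unique(blups$trait)) for (y in sort(unique(blups$year))) {
      sub <- blups[blups$trait == tt & blups$year == y, ]
      yv <- sub$blup[match(cross$ids, sub$id)]
      if (stats::sd(yv, na.rm = TRUE) < 1e-12) next  # shrunk-to-zero trait
      sc <- hk_scan(gp, yv)
      scans[[length(scans) + 1L]] <- cbind(trait = tt, year = y, sc)
      pen <- perm_threshold(gp, yv, n_perm = config$scan$n_perm,
                            alpha = config$scan$alpha,
                            seed = child_seed(config$seed,
                                              3000 + y * 29 + nchar(tt)))
      if (pen$T_m <= 0) next
      m <- stepwise_additive(gp, yv, penalty = pen)
      if (nrow(m$qtls))
        qtls[[length(qtls) + 1L]] <- cbind(trait = tt, year = y,
                                           covariate = "", m$qtls,
                                           T_m = pen$T_m)
    }
    utils::write.csv(do.call(rbind, scans), od("scans.csv"),
                     row.names = FALSE)
    qdf <- if (length(qtls)) do.call(rbind, qtls) else
      data.frame(trait = character(0), year = integer(0),
                 covariate = character(0), lg = integer(0), pos = numeric(0),
                 lod_drop1 = numeric(0), pct_var_drop1 = numeric(0),
                 ci_lo = numeric(0), ci_hi = numeric(0), eff_ac = numeric(0),
                 eff_ad = numeric(0), eff_bc = numeric(0),
                 eff_bd = numeric(0), T_m = numeric(0))
    utils::write.csv(qdf, od("qtl.csv"), row.names = FALSE)
    manifest$stages$scan <- list(status = "done", seconds = tic() - t0)
  } else manifest$stages$scan <- list(status = "skipped")

  ## collocate -----------------------------------------------------------
  if (stage_on("collocate")) {
    t0 <- tic()
    qdf <- utils::read.csv(need(od("qtl.csv"), "collocate"))
    rep <- collocate(qdf, config$scan$window_cm, config$scan$min_years)
    utils::write.csv(rep, od("collocation.csv"), row.names = FALSE)
    manifest$stages$collocate <- list(status = "done", seconds = tic() - t0)
  } else manifest$stages$collocate <- list(status = "skipped")

  ## report --------------------------------------------------------------
  if (stage_on("report")) {
    t0 <- tic()
    manifest$report <- report_run(config$out_dir)
    manifest$stages$report <- list(status = "done", seconds = tic() - t0)
  } else manifest$stages$report <- list(status = "skipped")

  outs <- list.files(config$out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest$files <- md5_of(outs)
  jsonlite::write_json(manifest, od("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

#' Summary tables and plots for a completed run
#'
#' Writes the per-trait-year heritability table, the trait correlation
#' matrix (on BLUPs; symmetric with unit diagonal), and per-linkage-group
#' scan plots with the selected QTL and their 1.5-LOD support intervals as
#' linear tracks.
#'
#' @param out_dir directory of a completed \code{\link{run_pipeline}} run.
#' @return List with \code{h2} and \code{correlations}, invisibly.
#' @export
report_run <- function(out_dir) {
  od <- function(...) file.path(out_dir, ...)
  h2 <- if (file.exists(od("h2.csv"))) utils::read.csv(od("h2.csv")) else NULL
  blups <- if (file.exists(od("blups.csv"))) utils::read.csv(od("blups.csv")) else NULL
  corr <- NULL
  if (!is.null(blups)) {
    wide <- stats::reshape(blups[, c("id", "year", "trait", "blup")],
                           idvar = c("id", "year"), timevar = "trait",
                           direction = "wide")
    names(wide) <- sub("^blup\\.", "", names(wide))
    corr <- suppressWarnings(
      stats::cor(as.matrix(wide[, -(1:2), drop = FALSE]),
                 use = "pairwise.complete.obs"))
    diag(corr) <- 1      # zero-variance BLUP vectors otherwise yield NA
    utils::write.csv(data.frame(trait = rownames(corr), corr,
                                check.names = FALSE),
                     od("trait_correlations.csv"), row.names = FALSE)
  }
  if (file.exists(od("scans.csv"))) {
    scans <- utils::read.csv(od("scans.csv"))
    qdf <- if (file.exists(od("qtl.csv"))) utils::read.csv(od("qtl.csv")) else NULL
    for (g in unique(scans$lg)) {
      grDevices::png(od(sprintf("scan_lg%s.png", g)), 900, 500)
      sub <- scans[scans$lg == g, ]
      graphics::plot(NA, xlim = range(sub$pos), ylim = c(0, max(sub$lod, 1)),
                     xlab = sprintf("LG %s (cM)", g), ylab = "LOD",
                     main = sprintf("Scans on LG %s", g))
      combos <- unique(sub[, c("trait", "year")])
      for (i in seq_len(nrow(combos))) {
        s <- sub[sub$trait == combos$trait[i] & sub$year == combos$year[i], ]
        graphics::lines(s$pos, s$lod, col = i)
      }
      if (!is.null(qdf) && nrow(qdf)) {
        qs <- qdf[qdf$lg == g, , drop = FALSE]
        if (nrow(qs)) {
          graphics::points(qs$pos, qs$lod_drop1, pch = 19)
          graphics::segments(qs$ci_lo, qs$lod_drop1, qs$ci_hi, qs$lod_drop1)
        }
      }
      grDevices::dev.off()
    }
  }
  invisible(list(h2 = h2, correlations = corr))
}
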