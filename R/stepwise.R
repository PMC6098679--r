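# internal: lookup table of genoprob design blocks keyed by lg/pos
block_table <- function(gp, ok) {
  blocks <- genoprob_positions(gp)
  list(lg = vapply(blocks, `[[`, integer(1), "lg"),
       pos = vapply(blocks, `[[`, numeric(1), "pos"),
       P = lapply(blocks, function(b) b$P[ok, , drop = FALSE]))
}

# design matrix for a multi-QTL model given block indices
model_design <- function(bt, X0, idx) {
  if (length(idx) == 0L) return(X0)
  cbind(X0, do.call(cbind, bt$P[idx]))
}

#' Additive stepwise multi-QTL model selection
#'
#' Forward search adds, at each step, the position that maximizes the model
#' LOD, accepting it while the penalized LOD \eqn{pLOD = LOD - T_m \cdot
#' \#QTL} increases; backward deletion then removes any QTL whose deletion
#' does not decrease pLOD, and one round of local position refinement
#' rescans each retained QTL within \code{refine_window} cM holding the
#' others fixed. Reported per QTL: the drop-one LOD and drop-one explained
#' variance, the estimated genotype-class effects, and the 1.5-LOD support
#' interval from the conditional scan.
#'
#' @param gp a \code{\link{calc_genoprob}} object.
#' @param y phenotype vector.
#' @param covar optional covariates (travel with \code{y}).
#' @param penalty a \code{\link{perm_threshold}} (or bare number \eqn{T_m}).
#' @param max_qtl maximum model size (default 6).
#' @param refine_window local rescan half-width, cM (default 10).
#' @param lod_drop support-interval drop (default 1.5).
#' @return Object of class \code{"qtl_model"}: \code{qtls} (data frame with
#'   \code{lg}, \code{pos}, \code{lod_drop1}, \code{pct_var_drop1},
#'   \code{ci_lo}, \code{ci_hi} and effect columns \code{eff_ac..eff_bd}),
#'   \code{full_model_pct_var}, \code{lod}, \code{plod}, \code{T_m},
#'   \code{n}. An empty model is a valid result.
#' @export
stepwise_additive <- function(gp, y, covar = NULL, penalty, max_qtl = 6,
                              refine_window = 10, lod_drop = 1.5) {
  T_m <- if (inherits(penalty, "perm_threshold")) penalty$T_m else penalty
  stopifnot(is.numeric(T_m), T_m > 0)
  ok <- stats::complete.cases(y, covar)
  yv <- y[ok]
  n <- length(yv)
  C <- if (is.null(covar)) NULL else as.matrix(covar)[ok, , drop = FALSE]
  X0 <- if (is.null(C)) matrix(1, n, 1) else cbind(1, C)
  bt <- block_table(gp, ok)
  nb <- length(bt$P)
  rss0 <- rss_fit(X0, yv)
  tss <- sum((yv - mean(yv))^2)
  model_lod <- function(idx)
    lod_from_rss(rss0, rss_fit(model_design(bt, X0, idx), yv), n)
  # forward
  sel <- integer(0)
  plod <- 0
  repeat {
    if (length(sel) >= max_qtl) break
    if (ncol(X0) + 3L * (length(sel) + 1L) >= n - 3L) break  # keep residual df
    cand <- setdiff(seq_len(nb), sel)
    if (length(cand) == 0L) break
    lods <- vapply(cand, function(k) model_lod(c(sel, k)), numeric(1))
    best <- which.max(lods)
    new_plod <- lods[best] - T_m * (length(sel) + 1L)
    if (new_plod > plod + 1e-9) {
      sel <- c(sel, cand[best]); plod <- new_plod
    } else break
  }
  # backward deletion
  repeat {
    if (length(sel) <= 1L) break
    drops <- vapply(seq_along(sel), function(j)
      model_lod(sel[-j]) - T_m * (length(sel) - 1L), numeric(1))
    if (max(drops) >= plod - 1e-9) {
      sel <- sel[-which.max(drops)]; plod <- max(drops)
    } else break
  }
  if (length(sel) == 1L && model_lod(sel) - T_m < 1e-9) sel <- integer(0)
  # one round of local position refinement
  if (length(sel) > 0L) for (j in seq_along(sel)) {
    here <- sel[j]
    local <- which(bt$lg == bt$lg[here] &
                   abs(bt$pos - bt$pos[here]) <= refine_window)
    lods <- vapply(local, function(k) model_lod(c(sel[-j], k)), numeric(1))
    sel[j] <- local[which.max(lods)]
  }
  sel <- sel[order(bt$lg[sel], bt$pos[sel])]
  full_lod <- if (length(sel)) model_lod(sel) else 0
  plod <- full_lod - T_m * length(sel)
  rss_full <- rss_fit(model_design(bt, X0, sel), yv)
  rows <- list()
  if (length(sel)) for (j in seq_along(sel)) {
    rss_wo <- rss_fit(model_design(bt, X0, sel[-j]), yv)
    lod1 <- lod_from_rss(rss_wo, rss_full, n)
    pct1 <- 100 * (rss_wo - rss_full) / tss
    # conditional scan along this QTL's linkage group for the support interval
    lg_idx <- which(bt$lg == bt$lg[sel[j]])
    cond <- vapply(lg_idx, function(k)
      lod_from_rss(rss_wo, rss_fit(model_design(bt, X0, c(sel[-j], k)), yv), n),
      numeric(1))
    curve <- data.frame(lg = bt$lg[lg_idx], pos = bt$pos[lg_idx], lod = cond)
    ci <- support_interval(curve, peak_pos = bt$pos[sel[j]], drop = lod_drop)
    # genotype-class effects from the full-model coefficients
    Xf <- model_design(bt, X0, c(sel[-j], sel[j]))  # this QTL's columns last
    cf <- stats::lm.fit(Xf, yv)$coefficients        # original column order
    eff <- c(0, utils::tail(cf, 3))
    eff[is.na(eff)] <- 0
    eff <- eff - mean(eff)
    rows[[j]] <- data.frame(lg = bt$lg[sel[j]], pos = bt$pos[sel[j]],
                            lod_drop1 = lod1, pct_var_drop1 = pct1,
                            ci_lo = ci[1], ci_hi = ci[2],
                            eff_ac = eff[1], eff_ad = eff[2],
                            eff_bc = eff[3], eff_bd = eff[4])
  }
  qtls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lg = integer(0), pos = numeric(0), lod_drop1 = numeric(0),
               pct_var_drop1 = numeric(0), ci_lo = numeric(0),
               ci_hi = numeric(0), eff_ac = numeric(0), eff_ad = numeric(0),
               eff_bc = numeric(0), eff_bd = numeric(0))
  structure(list(qtls = qtls,
                 full_model_pct_var = 100 * (1 - rss_full / tss) *
                   (length(sel) > 0),
                 lod = full_lod, plod = plod, T_m = T_m, n = n),
            class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf("<qtl_model: %d QTL, LOD %.2f, pLOD %.2f (T_m %.2f), %.1f%% variance>\n",
              nrow(x$qtls), x$lod, x$plod, x$T_m, x$full_model_pct_var))
  if (nrow(x$qtls)) print(x$qtls, digits = 4)
  invisible(x)
}

#' 1.5-LOD support interval around a scan peak
#'
#' The widest contiguous run of grid positions around the peak with LOD at
#' least \code{peak - drop}, expanded to the nearest grid point outside each
#' end (one-sided at linkage-group boundaries). With \code{drop = 0} the
#' interval degenerates to the peak grid point(s).
#'
#' @param scan data frame with \code{pos} and \code{lod} for one linkage
#'   group (e.g. an \code{\link{hk_scan}} subset).
#' @param peak_pos peak position on the scan grid (default the argmax).
#' @param drop LOD drop (default 1.5).
#' @return \code{c(lo, hi)} in cM.
#' @export
support_interval <- function(scan, peak_pos = NULL, drop = 1.5) {
  stopifnot(all(c("pos", "lod") %in% names(scan)), drop >= 0)
  ord <- order(scan$pos)
  pos <- scan$pos[ord]; lod <- scan$lod[ord]
  pk <- if (is.null(peak_pos)) which.max(lod) else which.min(abs(pos - peak_pos))
  thr <- lod[pk] - drop
  above <- lod >= thr - 1e-9
  lo <- pk; hi <- pk
  while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  while (hi < length(pos) && above[hi + 1L]) hi <- hi + 1L
  if (drop > 0) {           # expand to the nearest grid point outside
    if (lo > 1L) lo <- lo - 1L
    if (hi < length(pos)) hi <- hi + 1L
  }
  c(pos[lo], pos[hi])
}

#' Explained variance of a fitted QTL model
#'
#' Recomputes \code{full_model_pct_var} \eqn{= 100 (1 - RSS_{full}/TSS)} and
#' the per-QTL drop-one percentages \eqn{100 (RSS_{-q} - RSS_{full})/TSS}
#' for a model's QTL positions against a phenotype.
#'
#' @param model a \code{\link{stepwise_additive}} result.
#' @param gp the \code{genoprobs} the model was fitted on.
#' @param y phenotype vector.
#' @param covar optional covariates.
#' @return The model with updated variance fields.
#' @export
explained_variance <- function(model, gp, y, covar = NULL) {
  stopifnot(inherits(model, "qtl_model"))
  ok <- stats::complete.cases(y, covar)
  yv <- y[ok]
  C <- if (is.null(covar)) NULL else as.matrix(covar)[ok, , drop = FALSE]
  X0 <- if (is.null(C)) matrix(1, n, 1) else cbind(1, C)
  bt <- block_table(gp, ok)
  tss <- sum((yv - mean(yv))^2)
  if (nrow(model$qtls) == 0L) { model$full_model_pct_var <- 0; return(model) }
  idx <- vapply(seq_len(nrow(model$qtls)), function(j)
    which(bt$lg == model$qtls$lg[j] &
          abs(bt$pos - model$qtls$pos[j]) < 1e-6)[1], integer(1))
  rss_full <- rss_fit(model_design(bt, X0, idx), yv)
  model$full_model_pct_var <- 100 * (1 - rss_full / tss)
  model$qtls$pct_var_drop1 <- vapply(seq_along(idx), function(j)
    100 * (rss_fit(model_design(bt, X0, idx[-j]), yv) - rss_full) / tss,
    numeric(1))
  model
}
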