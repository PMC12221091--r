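# Variance stabilization, empirical-Bayes batch correction, and moderated
# t-statistics for each post-settlement timepoint against the zoospore
# reference.

#' Generalized-log variance-stabilizing normalization
#'
#' Each sample is first calibrated by its median ratio to the
#' geometric-mean reference profile over complete rows, then transformed by
#' the generalized logarithm
#' \deqn{y = \log_2\{(x + \sqrt{x^2 + c^2})/2\},}
#' which is \eqn{\log_2 x} for large intensities and stays finite through
#' zero. The glog offset `c` is set per run from a low-intensity quantile of
#' the calibrated values (default the 5th percentile), so the transform
#' flattens replicate variance at the low-intensity end where additive
#' noise dominates.
#'
#' @param m A raw-scale [intensity_matrix()].
#' @param offset_quantile Quantile of calibrated intensities defining `c`.
#' @param offset Explicit glog offset `c`, overriding the quantile
#'   heuristic. When the additive and multiplicative noise components of
#'   the platform are known, the variance-minimizing choice is their ratio
#'   `sd_additive / sd_multiplicative`.
#' @return An [intensity_matrix()] with `scale = "glog"`; calibration
#'   factors and the offset are stored in attributes `size_factors` and
#'   `glog_offset`.
#' @export
glog_normalize <- function(m, offset_quantile = 0.05, offset = NULL) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$scale != "raw")
    abort_sp("glog_normalize expects a raw-scale matrix", "settleprot_de_error")
  x <- m$values
  n_finite <- colSums(is.finite(x))
  if (any(n_finite < 3)) {
    bad <- colnames(x)[n_finite < 3]
    abort_sp(paste0("sample(s) with < 3 finite values: ",
                    paste(bad, collapse = ", ")), "settleprot_de_error")
  }
  complete <- rowSums(!is.finite(x)) == 0
  if (!any(complete))
    abort_sp("no complete rows available for calibration", "settleprot_de_error")
  ref <- exp(rowMeans(log(x[complete, , drop = FALSE])))
  sf <- apply(x[complete, , drop = FALSE], 2, function(col)
    stats::median(col / ref))
  xc <- sweep(x, 2, sf, "/")
  c0 <- offset %||%
    stats::quantile(xc[is.finite(xc)], offset_quantile, names = FALSE)
  y <- glog2(xc, c0)
  out <- intensity_matrix(y, m$design, scale = "glog")
  attr(out, "size_factors") <- sf
  attr(out, "glog_offset") <- c0
  out
}

# the generalized logarithm: log2 x for x >> c, finite at and below zero
glog2 <- function(x, c) {
  log2((x + sqrt(x^2 + c^2)) / 2)
}

#' Empirical-Bayes batch correction protecting timepoint means
#'
#' Two-way decomposition in the ComBat style: per-protein timepoint means
#' are fit and set aside, per-batch location and scale parameters are
#' estimated on the standardized residuals and shrunk by parametric
#' empirical Bayes (normal prior on locations, inverse-gamma prior on
#' scales, iterative posterior solution), the batch effects are removed,
#' and the timepoint means restored. Missing cells are tolerated and stay
#' missing.
#'
#' @param m A glog-scale [intensity_matrix()].
#' @param mean_only Adjust batch locations only (default). With a handful
#'   of samples per batch the per-batch scale estimates are noisy and their
#'   removal distorts downstream variance estimates, so the location-scale
#'   adjustment is opt-in.
#' @param conv Convergence tolerance of the iterative posterior solution.
#' @return An [intensity_matrix()] with `scale = "batch_corrected"`.
#' @export
batch_correct <- function(m, mean_only = TRUE, conv = 1e-4) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$scale != "glog")
    abort_sp("batch_correct expects a glog-scale matrix", "settleprot_de_error")
  design <- m$design
  batches <- unique(design$batch)
  if (length(batches) < 2) {
    out <- intensity_matrix(m$values, design, scale = "batch_corrected")
    attr(out, "batch_params") <- NULL
    return(out)
  }
  for (b in batches) {
    tps <- unique(design$timepoint[design$batch == b])
    if (length(tps) < 2)
      abort_sp(paste0("batch '", b, "' is nested within a single timepoint ",
                      "(confounded with the time course)"),
               "settleprot_de_error")
  }
  y <- m$values
  tpf <- factor(design$timepoint)
  bf <- factor(design$batch)
  Xb <- stats::model.matrix(~ 0 + bf)
  Xt <- stats::model.matrix(~tpf)[, -1, drop = FALSE]
  X <- cbind(Xb, Xt)
  nb_cols <- ncol(Xb)
  batch_w <- as.numeric(table(bf)[levels(bf)]) / ncol(y)

  # per-protein two-way OLS (timepoint + batch); the timepoint part plus the
  # sample-weighted mean batch intercept is the protected signal
  complete <- rowSums(!is.finite(y)) == 0
  beta <- matrix(NA_real_, nrow(y), ncol(X))
  if (any(complete)) {
    XtXi <- solve(crossprod(X))
    beta[complete, ] <- t(XtXi %*% crossprod(X, t(y[complete, , drop = FALSE])))
  }
  estimable <- complete
  for (g in which(!complete)) {
    f <- which(is.finite(y[g, ]))
    Xf <- X[f, , drop = FALSE]
    if (length(f) <= ncol(X) || qr(Xf)$rank < ncol(X)) next # left unadjusted
    beta[g, ] <- solve(crossprod(Xf), crossprod(Xf, y[g, f]))
    estimable[g] <- TRUE
  }
  grand <- as.vector(beta[, seq_len(nb_cols), drop = FALSE] %*% batch_w)
  stand_mean <- grand + beta[, -seq_len(nb_cols), drop = FALSE] %*% t(Xt)
  resid <- y - (beta %*% t(X))
  n_fin <- rowSums(is.finite(y))
  sigma <- sqrt(rowSums(resid^2, na.rm = TRUE) / pmax(n_fin, 1))
  active <- estimable & is.finite(sigma) & sigma > 1e-10
  z <- (y - stand_mean) / sigma

  adj <- y
  batch_params <- list()
  for (b in levels(bf)) {
    cols <- which(bf == b)
    zb <- z[, cols, drop = FALSE]
    nb <- rowSums(is.finite(zb))
    g_hat <- rowMeans(zb, na.rm = TRUE)
    d_hat <- row_vars(zb, na.rm = TRUE)
    ok <- active & nb >= 2 & is.finite(g_hat) & is.finite(d_hat) & d_hat > 0
    if (!any(ok)) next
    g_bar <- mean(g_hat[ok])
    t2 <- stats::var(g_hat[ok])
    m_d <- mean(d_hat[ok]); s2_d <- stats::var(d_hat[ok])
    # inverse-gamma prior hyperparameters by moment matching
    a_prior <- (2 * s2_d + m_d^2) / s2_d
    b_prior <- (m_d * s2_d + m_d^3) / s2_d
    g_new <- g_hat[ok]; d_new <- d_hat[ok]
    zb_ok <- zb[ok, , drop = FALSE]
    nb_ok <- nb[ok]
    if (mean_only) {
      # location-only posterior mean with unit prior scale (the ComBat
      # mean-only convention)
      g_new <- (t2 * g_hat[ok] + g_bar) / (t2 + 1)
      d_new <- rep(1, sum(ok))
    } else {
      change <- 1
      while (change > conv) {
        g_old <- g_new; d_old <- d_new
        g_new <- (t2 * nb_ok * g_hat[ok] + d_old * g_bar) / (t2 * nb_ok + d_old)
        sum2 <- rowSums((zb_ok - g_new)^2, na.rm = TRUE)
        d_new <- (0.5 * sum2 + b_prior) / (nb_ok / 2 + a_prior - 1)
        change <- max(abs(g_new - g_old) / abs(g_old),
                      abs(d_new - d_old) / abs(d_old), na.rm = TRUE)
      }
    }
    zadj <- (zb_ok - g_new) / sqrt(d_new)
    adj[ok, cols] <- zadj * sigma[ok] + stand_mean[ok, cols, drop = FALSE]
    batch_params[[b]] <- list(gamma_star = g_new, delta_star_sq = d_new,
                              gamma_bar = g_bar, tau_sq = t2)
  }
  out <- intensity_matrix(adj, design, scale = "batch_corrected")
  attr(out, "batch_params") <- batch_params
  out
}

# Newton inversion of the trigamma function (tolerance 1e-8), used by the
# moment-matching hyperparameter estimator.
trigamma_inverse <- function(y) {
  out <- y
  for (i in seq_along(y)) {
    yi <- y[i]
    if (!is.finite(yi) || yi <= 0) { out[i] <- NA_real_; next }
    if (yi > 1e7) { out[i] <- 1 / sqrt(yi); next }
    if (yi < 1e-6) { out[i] <- 1 / yi; next }
    x <- 0.5 + 1 / yi
    repeat {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (-dif / x < 1e-8) break
    }
    out[i] <- x
  }
  out
}

#' Estimate the variance prior (d0, s0^2) by moment matching
#'
#' Under the hierarchical model \eqn{s_g^2 | \sigma_g^2 \sim \sigma_g^2
#' \chi^2_{d_g}/d_g} and \eqn{\sigma_g^2 \sim s_0^2 d_0/\chi^2_{d_0}}, the
#' log sample variances have closed-form mean and variance in terms of
#' digamma/trigamma functions; the prior degrees of freedom `d0` and prior
#' variance `s0_sq` are recovered by inverting those moments (Newton on the
#' trigamma function, tolerance 1e-8). When the observed spread of log
#' variances is no larger than expected from sampling alone, `d0` is
#' reported as `Inf` and `s0_sq` as the common variance.
#'
#' @param s2 Per-protein residual variances.
#' @param df Residual degrees of freedom (scalar or per-protein).
#' @return List with `d0` and `s0_sq`.
#' @export
estimate_variance_prior <- function(s2, df) {
  if (length(df) == 1) df <- rep(df, length(s2))
  keep <- is.finite(s2) & is.finite(df) & df > 0 & s2 > 0
  s2 <- s2[keep]; df <- df[keep]
  if (length(s2) < 2)
    abort_sp("need >= 2 positive variances to estimate the prior",
             "settleprot_de_error")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  e_var <- stats::var(e) - mean(trigamma(df / 2))
  if (!is.finite(e_var) || e_var <= 0)
    return(list(d0 = Inf, s0_sq = mean(s2)))
  d0 <- 2 * trigamma_inverse(e_var)
  s0_sq <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-statistics for each timepoint versus the reference
#'
#' Per protein, ordinary least squares on timepoint means; the residual
#' variance \eqn{s_g^2} (with \eqn{d_g} df pooled over timepoints) is shrunk
#' toward the empirical-Bayes prior via
#' \eqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}, and the
#' moderated t for contrast k is
#' \eqn{\tilde{t} = \mathrm{log_2FC} / (\tilde{s}_g \sqrt{1/n_k + 1/n_0})}
#' on \eqn{d_0 + d_g} degrees of freedom. A protein quantified in fewer
#' than 2 replicates at the reference or contrast timepoint gets a missing
#' statistic with a reason code.
#'
#' The residual variance comes from a per-protein two-way fit (timepoint
#' plus batch when the design has several batches), so the degrees of
#' freedom spent on batch structure are accounted for and the raw p-values
#' stay calibrated whether or not the matrix was batch-corrected first.
#'
#' @param m A batch-corrected (or glog) [intensity_matrix()].
#' @param reference_timepoint Reference timepoint (default the smallest).
#' @return List with `params` (`d0`, `s0_sq`, per-protein `dg`, `s2`,
#'   `s_tilde_sq`) and `table`, a per-protein-per-contrast data frame with
#'   `log2fc`, `t`, `p_raw`, replicate counts and `reason`.
#' @export
fit_moderated <- function(m, reference_timepoint = NULL) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$scale == "raw")
    abort_sp("fit_moderated expects glog or batch-corrected values",
             "settleprot_de_error")
  y <- m$values
  design <- m$design
  tps <- sort(unique(design$timepoint))
  ref <- reference_timepoint %||% tps[1]
  if (!ref %in% tps)
    abort_sp("reference timepoint absent from the design", "settleprot_de_error")

  n_t <- mu_t <- list()
  for (t in tps) {
    cols <- which(design$timepoint == t)
    yt <- y[, cols, drop = FALSE]
    key <- as.character(t)
    n_t[[key]] <- rowSums(is.finite(yt))
    mu_t[[key]] <- rowMeans(yt, na.rm = TRUE)
  }

  # residual variance from the two-way linear model (timepoint + batch)
  X <- stats::model.matrix(~ 0 + factor(design$timepoint))
  if (length(unique(design$batch)) > 1)
    X <- cbind(X, stats::model.matrix(~ factor(design$batch))[, -1, drop = FALSE])
  n_fin <- rowSums(is.finite(y))
  ss <- rep(NA_real_, nrow(y))
  dg <- rep(0, nrow(y))
  complete <- n_fin == ncol(y)
  if (any(complete)) {
    P <- X %*% solve(crossprod(X), t(X))
    yc <- y[complete, , drop = FALSE]
    res <- yc - yc %*% P
    ss[complete] <- rowSums(res^2)
    dg[complete] <- ncol(y) - ncol(X)
  }
  for (g in which(!complete)) {
    f <- which(is.finite(y[g, ]))
    if (length(f) == 0) next
    Xf <- X[f, , drop = FALSE]
    qrf <- qr(Xf)
    dgf <- length(f) - qrf$rank
    if (dgf < 1) next
    ss[g] <- sum(qr.resid(qrf, y[g, f])^2)
    dg[g] <- dgf
  }
  s2 <- ifelse(dg >= 1, ss / pmax(dg, 1), NA_real_)

  prior <- estimate_variance_prior(s2, dg)
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  s_tilde_sq <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  s_tilde_sq[!(dg >= 1)] <- NA_real_

  contrasts <- setdiff(tps, ref)
  refk <- as.character(ref)
  tabs <- lapply(contrasts, function(tk) {
    k <- as.character(tk)
    lfc <- mu_t[[k]] - mu_t[[refk]]
    vk <- 1 / n_t[[k]] + 1 / n_t[[refk]]
    tt <- lfc / sqrt(s_tilde_sq * vk)
    df <- d0 + dg
    p <- 2 * stats::pt(-abs(tt), df = df)
    reason <- rep(NA_character_, length(lfc))
    bad_rep <- n_t[[k]] < 2 | n_t[[refk]] < 2
    reason[bad_rep] <- "insufficient_replication"
    reason[!bad_rep & !(dg >= 1)] <- "no_residual_df"
    drop <- !is.na(reason)
    lfc[drop] <- NA_real_; tt[drop] <- NA_real_; p[drop] <- NA_real_
    data.frame(protein_id = rownames(y), contrast = paste0("T", tk),
               timepoint = tk, log2fc = lfc, t = tt, p_raw = p,
               n_ref = n_t[[refk]], n_alt = n_t[[k]],
               reason = reason, stringsAsFactors = FALSE, row.names = NULL)
  })
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL
  list(params = list(d0 = d0, s0_sq = s0_sq, dg = dg, s2 = s2,
                     s_tilde_sq = s_tilde_sq,
                     reference_timepoint = ref),
       table = table)
}

#' Significance thresholds
#'
#' Defaults follow the study design: Benjamini-Hochberg adjusted p < 0.1
#' and fold-change > 1.0001 for upregulation or < 1/1.0001 = 0.9999 for
#' downregulation. `use_adjusted = FALSE` applies the cutoff to raw p.
#'
#' @param alpha P-value cutoff.
#' @param fc_up Upregulation fold-change threshold (ratio scale);
#'   `fc_down` is its reciprocal.
#' @param adjust_method Multiple-testing method (see [stats::p.adjust()]).
#' @param use_adjusted Apply `alpha` to the adjusted p (default) or raw p.
#' @param pool_contrasts Adjust across all contrasts jointly instead of
#'   within each contrast family.
#' @return A `significance_thresholds` list.
#' @export
significance_thresholds <- function(alpha = 0.1, fc_up = 1.0001,
                                    adjust_method = "BH",
                                    use_adjusted = TRUE,
                                    pool_contrasts = FALSE) {
  if (alpha <= 0 || alpha >= 1)
    abort_sp("alpha must lie in (0, 1)", "settleprot_de_error")
  if (fc_up <= 1)
    abort_sp("fc_up must exceed 1", "settleprot_de_error")
  structure(list(alpha = alpha, fc_up = fc_up, fc_down = 1 / fc_up,
                 adjust_method = adjust_method, use_adjusted = use_adjusted,
                 pool_contrasts = pool_contrasts),
            class = "significance_thresholds")
}

#' Adjust p-values and call significance
#'
#' BH step-up within each contrast family (default) or pooled; a protein is
#' significant when its (adjusted) p is below `alpha` and its log2
#' fold-change clears the fold-change bound in either direction.
#'
#' @param table Contrast table from [fit_moderated()].
#' @param thresholds A [significance_thresholds()].
#' @return The table with `p_adj`, `significant` and `direction`
#'   (`up`/`down`/`none`) columns.
#' @export
adjust_and_call <- function(table, thresholds = significance_thresholds()) {
  stopifnot(inherits(thresholds, "significance_thresholds"))
  if (thresholds$pool_contrasts) {
    table$p_adj <- stats::p.adjust(table$p_raw, thresholds$adjust_method)
  } else {
    table$p_adj <- stats::ave(table$p_raw, table$contrast,
                              FUN = function(p)
                                stats::p.adjust(p, thresholds$adjust_method))
  }
  p_use <- if (thresholds$use_adjusted) table$p_adj else table$p_raw
  lfc_up <- log2(thresholds$fc_up)
  up <- !is.na(p_use) & p_use < thresholds$alpha & table$log2fc > lfc_up
  down <- !is.na(p_use) & p_use < thresholds$alpha & table$log2fc < -lfc_up
  table$significant <- up | down
  table$direction <- ifelse(up, "up", ifelse(down, "down", "none"))
  attr(table, "thresholds") <- thresholds
  table
}

#' Summarize differential-abundance calls
#'
#' Per protein, the sets of timepoints called up and down; globally, the
#' counts of proteins up at >= 1 timepoint, down at >= 1 timepoint, unique
#' differential proteins, proteins in both directions, per-timepoint
#' counts, and the pattern counts of the study's accounting: exclusively
#' upregulated at the first post-settlement timepoint, and downregulated
#' across all timepoints.
#'
#' @param table A called contrast table from [adjust_and_call()].
#' @return A `de_summary` list.
#' @export
summarize_de <- function(table) {
  if (!"significant" %in% names(table))
    abort_sp("call adjust_and_call() before summarize_de()",
             "settleprot_de_error")
  tps <- sort(unique(table$timepoint))
  ids <- unique(table$protein_id)
  sig <- table[table$significant, , drop = FALSE]
  up_list <- split(sig$timepoint[sig$direction == "up"],
                   sig$protein_id[sig$direction == "up"])
  down_list <- split(sig$timepoint[sig$direction == "down"],
                     sig$protein_id[sig$direction == "down"])
  up_at <- lapply(stats::setNames(ids, ids), function(i)
    sort(up_list[[i]] %||% numeric(0)))
  down_at <- lapply(stats::setNames(ids, ids), function(i)
    sort(down_list[[i]] %||% numeric(0)))
  n_up_tp <- vapply(up_at, length, integer(1))
  n_down_tp <- vapply(down_at, length, integer(1))
  early <- tps[1]
  per_protein <- data.frame(
    protein_id = ids,
    up_at = vapply(up_at, paste, character(1), collapse = ","),
    down_at = vapply(down_at, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  per_tp <- data.frame(
    timepoint = tps,
    n_up = vapply(tps, function(t)
      sum(vapply(up_at, function(v) t %in% v, logical(1))), integer(1)),
    n_down = vapply(tps, function(t)
      sum(vapply(down_at, function(v) t %in% v, logical(1))), integer(1))
  )
  counts <- list(
    n_up = sum(n_up_tp > 0),
    n_down = sum(n_down_tp > 0),
    n_unique_de = sum(n_up_tp > 0 | n_down_tp > 0),
    n_both_directions = sum(n_up_tp > 0 & n_down_tp > 0),
    n_exclusively_up_first = sum(vapply(up_at, function(v)
      length(v) == 1 && v[1] == early, logical(1))),
    n_down_all_timepoints = sum(vapply(down_at, function(v)
      length(v) == length(tps), logical(1)))
  )
  counts$accounting_disjoint <-
    counts$n_up + counts$n_down - counts$n_both_directions == counts$n_unique_de
  structure(list(per_protein = per_protein, per_timepoint = per_tp,
                 counts = counts, up_at = up_at, down_at = down_at,
                 timepoints = tps),
            class = "de_summary")
}

#' @export
print.de_summary <- function(x, ...) {
  cat(sprintf("de_summary: %d up, %d down, %d unique differential (%d both)\n",
              x$counts$n_up, x$counts$n_down, x$counts$n_unique_de,
              x$counts$n_both_directions))
  cat(sprintf("  exclusively up at T%s: %d; down at all timepoints: %d\n",
              x$timepoints[1], x$counts$n_exclusively_up_first,
              x$counts$n_down_all_timepoints))
  invisible(x)
}
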