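test_that("glog approaches log2 at high intensity and stays finite at zero", {
  x <- c(0, 1, 10, 1e3, 1e5, 1e8)
  c0 <- 100
  y <- settleprot:::glog2(x, c0)
  expect_true(all(is.finite(y)))
  expect_equal(y[1], log2(c0 / 2)) # glog(0) = log2(c/2)
  high <- x >= 100 * c0
  expect_true(all(abs(y[high] - log2(x[high])) < 0.01))
  # monotone
  expect_true(all(diff(y) > 0))
})

test_that("glog_normalize calibrates samples and records its parameters", {
  set.seed(3)
  # multiplicative sample shifts on shared row profiles
  vals <- outer(2^runif(40, 12, 20), rep(1, 5)) *
    2^matrix(rnorm(200, 0, 0.1), 40)
  vals[, 2] <- vals[, 2] * 2 # a doubled sample
  m <- mk_im(vals, mk_design(c(0, 2, 4, 6, 8), 1), scale = "raw")
  g <- glog_normalize(m)
  expect_equal(g$scale, "glog")
  sf <- attr(g, "size_factors")
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 0.05)
  # a sample of mostly-missing values is rejected
  vals2 <- vals; vals2[3:40, 1] <- NA
  m2 <- mk_im(vals2, mk_design(c(0, 2, 4, 6, 8), 1), scale = "raw")
  expect_error(glog_normalize(m2), class = "settleprot_de_error")
})

test_that("glog stabilizes replicate variance under additive+multiplicative noise", {
  set.seed(1)
  n <- 4000; reps <- 3
  mu <- 2^runif(n, 10.6, 22); sd_m <- 0.2; sd_a <- 1000
  x <- pmax(matrix(mu, n, reps) * exp(matrix(rnorm(n * reps, 0, sd_m), n)) +
              matrix(rnorm(n * reps, 0, sd_a), n), 1)
  m <- mk_im(x, mk_design(0, reps), scale = "raw")
  dec <- cut(rank(rowMeans(x)), 10)
  ratio <- function(v) {
    sds <- tapply(v[, 1] - v[, 2], dec, stats::sd)
    max(sds) / min(sds)
  }
  raw_ratio <- ratio(log2(x))
  expect_gt(raw_ratio, 3) # raw log variance blows up at low intensity
  # with the noise-informed offset the decile sds agree within 25%
  g <- glog_normalize(m, offset = sd_a / sd_m)
  expect_lt(ratio(g$values), 1.25)
  # the quantile heuristic still removes most of the trend
  gq <- glog_normalize(m)
  expect_lt(ratio(gq$values), raw_ratio / 3)
})

test_that("batch correction is the identity without batch structure", {
  # noise-free data with pure timepoint structure: nothing to remove
  tps <- c(0, 2, 4, 6, 8)
  mu <- outer(1:30, rep(seq_along(tps), each = 3) * 0.5)
  m <- mk_im(mu + 15, scale = "glog")
  out <- batch_correct(m)
  expect_lt(sqrt(mean((out$values - m$values)^2)), 1e-6)
  # single batch: identity transform
  d1 <- mk_design(); d1$batch <- "B1"
  m1 <- mk_im(matrix(rnorm(150, 18), 10), d1, scale = "glog")
  out1 <- batch_correct(m1)
  expect_identical(out1$values, m1$values)
  expect_equal(out1$scale, "batch_corrected")
})

test_that("planted batch offsets are removed within tolerance", {
  set.seed(4)
  n <- 600
  des <- mk_design()
  off <- c(R1 = 0.5, R2 = 0, R3 = -0.5)
  y <- matrix(rnorm(n * 15, 18, 0.25), n) +
    matrix(off[des$replicate], n, 15, byrow = TRUE)
  m <- mk_im(y, des, scale = "glog")
  out <- batch_correct(m)
  tp_mean <- sapply(unique(des$timepoint), function(t)
    rowMeans(out$values[, des$timepoint == t, drop = FALSE]))
  resid <- out$values - tp_mean[, match(des$timepoint, unique(des$timepoint))]
  for (b in unique(des$batch)) {
    bm <- mean(resid[, des$batch == b])
    expect_lt(abs(bm), 0.05)
  }
  # missing cells survive and stay missing
  y2 <- y; y2[cbind(1:50, sample(1:15, 50, TRUE))] <- NA
  out2 <- batch_correct(mk_im(y2, des, scale = "glog"))
  expect_identical(which(is.na(out2$values)), which(is.na(y2)))
})

test_that("a batch nested in one timepoint is rejected as confounded", {
  des <- mk_design(c(0, 2), 3)
  des$batch <- ifelse(des$timepoint == 0, "B1", "B2")
  m <- mk_im(matrix(rnorm(60, 18), 10), des, scale = "glog")
  expect_error(batch_correct(m), "confounded", class = "settleprot_de_error")
})

test_that("batch correction matches the reference EB implementation", {
  skip_if_not_installed("sva")
  set.seed(5)
  n <- 200
  des <- mk_design()
  y <- matrix(rnorm(n * 15, 18, 0.5), n,
              dimnames = list(sprintf("P%03d", 1:n), des$sample_id)) +
    matrix(c(0.4, 0, -0.4)[match(des$replicate, c("R1", "R2", "R3"))],
           n, 15, byrow = TRUE)
  m <- intensity_matrix(y, des, scale = "glog")
  mod <- stats::model.matrix(~ factor(des$timepoint))
  ref_mean <- suppressMessages(sva::ComBat(y, batch = m$design$batch,
                                           mod = mod, mean.only = TRUE))
  expect_lt(max(abs(batch_correct(m)$values - ref_mean)), 1e-10)
  # the location-scale variant agrees to the iterative solver's tolerance
  ref_full <- suppressMessages(sva::ComBat(y, batch = m$design$batch,
                                           mod = mod))
  expect_lt(max(abs(batch_correct(m, mean_only = FALSE)$values - ref_full)),
            1e-4)
})

test_that("trigamma inversion and the variance prior recover hyperparameters", {
  y <- trigamma(c(0.1, 1, 5, 50))
  expect_equal(settleprot:::trigamma_inverse(y), c(0.1, 1, 5, 50),
               tolerance = 1e-7)
  set.seed(7)
  d0 <- 4; s0 <- 2; dg <- 10
  sigma2 <- s0 * d0 / rchisq(2000, d0)
  s2 <- sigma2 * rchisq(2000, dg) / dg
  pr <- estimate_variance_prior(s2, dg)
  expect_gt(pr$d0, 3.2); expect_lt(pr$d0, 4.8)
  expect_gt(pr$s0_sq, 1.8); expect_lt(pr$s0_sq, 2.2)
})

test_that("identical variances collapse the prior to d0 = Inf", {
  # two proteins with numerically identical residual variance
  base <- matrix(rnorm(15, 0, 1), 1)
  y <- rbind(base + 10, base + 12, base + 14)
  m <- mk_im(y, scale = "glog")
  fit <- fit_moderated(m)
  expect_true(is.infinite(fit$params$d0))
  expect_equal(fit$params$s_tilde_sq, rep(fit$params$s0_sq, 3))
  expect_equal(fit$params$s0_sq, unique(round(fit$params$s2, 12)))
})

test_that("moderated statistics match limma on complete data", {
  skip_if_not_installed("limma")
  set.seed(8)
  n <- 250
  tp <- rep(c(0, 2, 4, 6, 8), each = 3)
  y <- matrix(rnorm(n * 15, 18, 1), n,
              dimnames = list(sprintf("P%03d", 1:n), NULL))
  y[1:40, tp == 4] <- y[1:40, tp == 4] + 1
  d1 <- mk_design(); d1$batch <- "B1" # limma model has no batch term
  m <- mk_im(y, d1, scale = "glog")
  fit <- fit_moderated(m)
  X <- stats::model.matrix(~ 0 + factor(tp))
  colnames(X) <- paste0("T", c(0, 2, 4, 6, 8))
  cm <- limma::makeContrasts(T2 - T0, T4 - T0, T6 - T0, T8 - T0, levels = X)
  eb <- limma::eBayes(limma::contrasts.fit(limma::lmFit(y, X), cm))
  expect_equal(fit$params$d0, eb$df.prior, tolerance = 1e-9)
  expect_equal(fit$params$s0_sq, eb$s2.prior, tolerance = 1e-9)
  expect_equal(matrix(fit$table$t, ncol = 4), unname(eb$t), tolerance = 1e-9)
  expect_equal(matrix(fit$table$p_raw, ncol = 4), unname(eb$p.value),
               tolerance = 1e-9)
  expect_equal(matrix(fit$table$log2fc, ncol = 4), unname(eb$coefficients),
               tolerance = 1e-12)
})

test_that("a zero-effect protein gets t = 0 and p = 1", {
  # equal timepoint means, nonzero replicate scatter
  row <- rep(c(-1, 0, 1), 5) + 18
  y <- rbind(row, row + rnorm(15, 0, 0.1))
  m <- mk_im(y, scale = "glog")
  fit <- fit_moderated(m)
  r1 <- fit$table[fit$table$protein_id == rownames(y)[1], ]
  expect_equal(r1$t, rep(0, 4))
  expect_equal(r1$p_raw, rep(1, 4))
})

test_that("insufficient replication yields missing statistics with reasons", {
  set.seed(9)
  y <- matrix(rnorm(2 * 15, 18, 0.3), 2)
  des <- mk_design()
  y[1, des$timepoint == 4] <- c(NA, NA, 17) # < 2 replicates at T4
  y[2, des$timepoint == 0] <- NA            # < 2 at the reference
  m <- mk_im(y, des, scale = "glog")
  tab <- fit_moderated(m)$table
  r1 <- tab[tab$protein_id == "P001" & tab$timepoint == 4, ]
  expect_true(is.na(r1$t))
  expect_equal(r1$reason, "insufficient_replication")
  expect_false(is.na(tab$t[tab$protein_id == "P001" & tab$timepoint == 2]))
  expect_true(all(is.na(tab$t[tab$protein_id == "P002"])))
})

test_that("BH adjustment and the calling rule follow the step-up by hand", {
  tab <- data.frame(protein_id = c("p1", "p2", "p3"), contrast = "T2",
                    timepoint = 2, log2fc = c(1, -1, 0.5),
                    t = c(5, -5, 3), p_raw = c(0.01, 0.02, 0.03),
                    stringsAsFactors = FALSE)
  out <- adjust_and_call(tab, significance_thresholds(alpha = 0.1))
  expect_equal(out$p_adj, c(0.03, 0.03, 0.03)) # step-up by hand
  expect_true(all(out$significant))
  expect_equal(out$direction, c("up", "down", "up"))
  # a single p is unchanged
  out1 <- adjust_and_call(tab[1, ], significance_thresholds())
  expect_equal(out1$p_adj, out1$p_raw)
  # log2fc = 0 exactly never passes the fold-change bound
  tab$log2fc <- 0
  out0 <- adjust_and_call(tab, significance_thresholds())
  expect_false(any(out0$significant))
  # raw-p switch
  tabr <- tab; tabr$log2fc <- 1; tabr$p_raw <- c(0.05, 0.5, 0.5)
  outr <- adjust_and_call(tabr, significance_thresholds(use_adjusted = FALSE))
  expect_equal(outr$significant, c(TRUE, FALSE, FALSE))
})

test_that("BH adjusted p is monotone nondecreasing in raw p", {
  set.seed(10)
  tab <- data.frame(protein_id = sprintf("p%03d", 1:200), contrast = "T2",
                    timepoint = 2, log2fc = rnorm(200), t = rnorm(200),
                    p_raw = runif(200), stringsAsFactors = FALSE)
  out <- adjust_and_call(tab, significance_thresholds())
  ord <- order(out$p_raw)
  expect_true(all(diff(out$p_adj[ord]) >= -1e-15))
  # thresholds invariants
  th <- significance_thresholds(fc_up = 1.0001)
  expect_equal(th$fc_down, 1 / th$fc_up, tolerance = 1e-12)
  expect_error(significance_thresholds(alpha = 1.5),
               class = "settleprot_de_error")
})

test_that("the DE summary equals brute-force enumeration of the calls", {
  set.seed(11)
  ids <- sprintf("p%02d", 1:30)
  tab <- expand.grid(protein_id = ids, timepoint = c(2, 4, 6, 8),
                     stringsAsFactors = FALSE)
  tab$contrast <- paste0("T", tab$timepoint)
  tab$log2fc <- rnorm(nrow(tab))
  tab$p_raw <- runif(nrow(tab))
  tab$p_adj <- tab$p_raw
  tab$significant <- tab$p_raw < 0.3
  tab$direction <- ifelse(!tab$significant, "none",
                          ifelse(tab$log2fc > 0, "up", "down"))
  s <- summarize_de(tab)
  # brute force over proteins
  n_up <- n_down <- n_excl <- n_down_all <- 0
  for (p in ids) {
    tp_up <- tab$timepoint[tab$protein_id == p & tab$direction == "up"]
    tp_dn <- tab$timepoint[tab$protein_id == p & tab$direction == "down"]
    if (length(tp_up) > 0) n_up <- n_up + 1
    if (length(tp_dn) > 0) n_down <- n_down + 1
    if (identical(sort(tp_up), 2)) n_excl <- n_excl + 1
    if (length(tp_dn) == 4) n_down_all <- n_down_all + 1
  }
  expect_equal(s$counts$n_up, n_up)
  expect_equal(s$counts$n_down, n_down)
  expect_equal(s$counts$n_exclusively_up_first, n_excl)
  expect_equal(s$counts$n_down_all_timepoints, n_down_all)
  expect_equal(s$counts$n_unique_de,
               s$counts$n_up + s$counts$n_down - s$counts$n_both_directions)
  # no significant calls at all
  tab$significant <- FALSE; tab$direction <- "none"
  s0 <- summarize_de(tab)
  expect_equal(s0$counts$n_unique_de, 0)
  expect_equal(s0$counts$n_exclusively_up_first, 0)
})

test_that("a protein up at T2 only is counted as exclusively upregulated there", {
  tab <- data.frame(protein_id = "p1", timepoint = c(2, 4, 6, 8),
                    contrast = paste0("T", c(2, 4, 6, 8)),
                    log2fc = c(1, 0, 0, 0), p_raw = c(0.001, 1, 1, 1),
                    p_adj = c(0.004, 1, 1, 1),
                    significant = c(TRUE, FALSE, FALSE, FALSE),
                    direction = c("up", "none", "none", "none"),
                    stringsAsFactors = FALSE)
  s <- summarize_de(tab)
  expect_equal(s$counts$n_exclusively_up_first, 1)
  expect_equal(s$per_protein$up_at, "2")
})
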