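# Over-/under-representation of annotation terms in protein sets against
# the detected background, by exact hypergeometric tails with BH correction.

#' Exact hypergeometric tail probabilities
#'
#' With `X ~ Hypergeometric(N, K, n)` (a foreground of size `n` drawn from a
#' background of `N` proteins of which `K` carry the term),
#' `p_over = P(X >= k)` and `p_under = P(X <= k)`.
#'
#' @param k Term members observed in the foreground.
#' @param K Term members in the background.
#' @param n Foreground size.
#' @param N Background size.
#' @return List with vectors `p_over` and `p_under`.
#' @export
hypergeom_test <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | k > pmin(K, n) | K > N | n > N |
    k < pmax(0, K + n - N)
  if (any(bad))
    abort_sp("hypergeometric bounds violated (need 0 <= k <= min(K, n), K, n <= N, k >= K + n - N)",
             "settleprot_enrich_error")
  list(p_over = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       p_under = stats::phyper(k, K, N - K, n, lower.tail = TRUE))
}

#' Term enrichment of named foreground sets against a background
#'
#' One record per term x foreground with exact hypergeometric tails; each
#' tail (over- and under-representation) is BH-corrected as its own family
#' across all records, and flagged at the requested FDR.
#'
#' @param annotations An [annotation_map()] or a list of them.
#' @param foregrounds Named list of protein-id vectors (clusters, up/down
#'   unions, custom sets); each must be a subset of `background`.
#' @param background Character vector: the detected-protein universe.
#' @param fdr False discovery rate for the flags (default 0.05).
#' @return Data frame of enrichment records: `namespace`, `term`,
#'   `foreground`, `k`, `K`, `n`, `N`, `odds_ratio`, `p_over`, `p_under`,
#'   `p_over_adj`, `p_under_adj`, `over_flag`, `under_flag`.
#' @export
enrich_sets <- function(annotations, foregrounds, background, fdr = 0.05) {
  if (inherits(annotations, "annotation_map")) annotations <- list(annotations)
  background <- unique(as.character(background))
  N <- length(background)
  if (is.null(names(foregrounds)) || any(!nzchar(names(foregrounds))))
    abort_sp("foreground sets must be named", "settleprot_enrich_error")
  for (nm in names(foregrounds)) {
    extra <- setdiff(foregrounds[[nm]], background)
    if (length(extra) > 0)
      abort_sp(paste0("foreground '", nm, "' contains protein(s) absent from ",
                      "the background: ", paste(utils::head(extra, 5),
                                                collapse = ", ")),
               "settleprot_enrich_error")
  }
  rows <- list()
  for (ann in annotations) {
    for (term in names(ann$terms)) {
      members <- intersect(ann$terms[[term]], background)
      K <- length(members)
      if (K == 0) next
      for (nm in names(foregrounds)) {
        fg <- unique(foregrounds[[nm]])
        n <- length(fg)
        k <- length(intersect(members, fg))
        pv <- hypergeom_test(k, K, n, N)
        or <- (k * (N - K - n + k)) / ((n - k) * (K - k))
        rows[[length(rows) + 1]] <- data.frame(
          namespace = ann$namespace, term = term, foreground = nm,
          k = k, K = K, n = n, N = N, odds_ratio = or,
          p_over = pv$p_over, p_under = pv$p_under,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$p_over_adj <- stats::p.adjust(out$p_over, "BH")
  out$p_under_adj <- stats::p.adjust(out$p_under, "BH")
  out$over_flag <- out$p_over_adj < fdr
  out$under_flag <- out$p_under_adj < fdr
  rownames(out) <- NULL
  out
}
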