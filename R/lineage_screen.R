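# Screen for candidate ectoplasmic-network/bothrosome proteins: upregulated
# after settlement and taxonomically restricted to Labyrinthulomycota, via
# (a) classification of stramenopile-database homology hits and (b) an
# orthogroup filter, combined by union; plus the cross-study directional
# concordance cross-tabulation.

.BIN_LEVELS <- c("Q0_85", "Q85_90", "Q90_95", "Q95_975", "Q975_100")

#' Screen configuration
#'
#' @param top_n Hits retained per query (default 5).
#' @param min_laby_genomes Minimum Labyrinthulomycota genomes containing the
#'   protein's orthogroup (condition 1; default 2).
#' @param max_nonlaby_genomes Maximum non-Labyrinthulomycota genomes
#'   (condition 2; default 1).
#' @param required_hondaea_copies Minimum copies in the Hondaea genome
#'   (condition 4; default 1).
#' @param upregulated_timepoints Settlement timepoints whose upregulation
#'   satisfies condition 3 (default 4, 6, 8 h).
#' @param blast_qualifying_bins Quantile bin(s) of the bitscore-delta
#'   distribution that qualify a `both`-group protein for the homology
#'   path (default the top 97.5-100% bin, the most conservative reading).
#' @param include_aurli_only Treat queries with no stramenopile hits as
#'   qualifying (default FALSE: no identifiable labyrinthulomycete homolog).
#' @param hondaea_genome Name of the Hondaea genome column.
#' @param conservation_min_genomes Orthogroup presence in at least this many
#'   of the Labyrinthulomycota genomes sets the (annotation-only)
#'   `conserved` flag (default 3).
#' @return A `screen_config` list.
#' @export
screen_config <- function(top_n = 5,
                          min_laby_genomes = 2,
                          max_nonlaby_genomes = 1,
                          required_hondaea_copies = 1,
                          upregulated_timepoints = c(4, 6, 8),
                          blast_qualifying_bins = "Q975_100",
                          include_aurli_only = FALSE,
                          hondaea_genome = "Honfer1",
                          conservation_min_genomes = 3) {
  if (top_n < 1)
    abort_sp("top_n must be >= 1", "settleprot_screen_error")
  if (!all(blast_qualifying_bins %in% .BIN_LEVELS))
    abort_sp(paste0("unknown quantile bin(s): ",
                    paste(setdiff(blast_qualifying_bins, .BIN_LEVELS),
                          collapse = ", ")), "settleprot_screen_error")
  structure(as.list(environment()), class = "screen_config")
}

#' Retain the top hits per query
#'
#' At most `top_n` rows per query, ordered by ascending e-value, then
#' descending percent identity, then descending bitscore, then subject id.
#'
#' @param hits A [hit_table()].
#' @param top_n Hits retained per query.
#' @return The truncated, sorted [hit_table()].
#' @export
select_top_hits <- function(hits, top_n = 5) {
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$qseqid, hits$evalue, -hits$pident, -hits$bitscore,
               hits$sseqid, method = "radix")
  h <- hits[ord, , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(h)), h$qseqid, FUN = seq_along)
  out <- h[rank <= top_n, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify each query's lineage from its retained hits
#'
#' Four groups: `aurli_only` (no stramenopile hits at all), `laby_only`
#' (hits only to Hondaea), `stramenopile_not_hondaea` (at least `top_n`
#' retained non-Hondaea hits each with bitscore strictly greater than the
#' query's best Hondaea hit, or non-Hondaea hits with no Hondaea hit at
#' all), and `both` (hits to both classes otherwise). For `both`, deltas
#' are best-by-bitscore Hondaea minus best-by-bitscore other for bitscore,
#' percent identity, and e-value on the -log10 scale.
#'
#' @param top_hits Output of [select_top_hits()], with `taxon_class`.
#' @param queries Character universe of query ids (queries without hits are
#'   classified `aurli_only`).
#' @param cfg A [screen_config()].
#' @return Data frame of lineage calls: `query`, `group`, `delta_bitscore`,
#'   `delta_evalue`, `delta_pident` (NA unless `both`).
#' @export
classify_lineage <- function(top_hits, queries, cfg = screen_config()) {
  if (is.null(top_hits$taxon_class))
    abort_sp("top_hits must carry taxon_class (see read_hit_table)",
             "settleprot_screen_error")
  known <- c("laby_hondaea", "other_stramenopile")
  bad <- setdiff(unique(top_hits$taxon_class), c(known, NA))
  if (length(bad) > 0)
    abort_sp(paste0("unknown taxon_class: ", paste(bad, collapse = ", ")),
             "settleprot_screen_error")
  queries <- unique(as.character(queries))
  out <- data.frame(query = queries, group = "aurli_only",
                    delta_bitscore = NA_real_, delta_evalue = NA_real_,
                    delta_pident = NA_real_, stringsAsFactors = FALSE)

  # best hit per query within each taxon class (max bitscore, tie -> lower
  # e-value), plus the count of non-Hondaea hits beating the best Hondaea one
  best_by_class <- function(h) {
    if (nrow(h) == 0)
      return(h[0, c("qseqid", "bitscore", "evalue", "pident"), drop = FALSE])
    ord <- order(h$qseqid, -h$bitscore, h$evalue, method = "radix")
    hh <- h[ord, , drop = FALSE]
    hh[!duplicated(hh$qseqid), c("qseqid", "bitscore", "evalue", "pident"),
       drop = FALSE]
  }
  laby <- top_hits[top_hits$taxon_class %in% "laby_hondaea", , drop = FALSE]
  other <- top_hits[top_hits$taxon_class %in% "other_stramenopile", ,
                    drop = FALSE]
  bl <- best_by_class(laby)
  bo <- best_by_class(other)
  il <- match(queries, bl$qseqid)
  io <- match(queries, bo$qseqid)
  has_laby <- !is.na(il)
  has_other <- !is.na(io)

  better <- other$bitscore > bl$bitscore[match(other$qseqid, bl$qseqid)]
  n_better_tab <- table(other$qseqid[which(better)])
  n_better <- rep(0L, length(queries))
  hitq <- match(queries, names(n_better_tab))
  n_better[!is.na(hitq)] <- as.integer(n_better_tab[hitq[!is.na(hitq)]])

  out$group[has_laby & !has_other] <- "laby_only"
  out$group[!has_laby & has_other] <- "stramenopile_not_hondaea"
  both_ish <- has_laby & has_other
  out$group[both_ish & n_better >= cfg$top_n] <- "stramenopile_not_hondaea"
  is_both <- both_ish & n_better < cfg$top_n
  out$group[is_both] <- "both"
  out$delta_bitscore[is_both] <- bl$bitscore[il[is_both]] -
    bo$bitscore[io[is_both]]
  out$delta_evalue[is_both] <-
    (-log10(pmax(bl$evalue[il[is_both]], 1e-300))) -
    (-log10(pmax(bo$evalue[io[is_both]], 1e-300)))
  out$delta_pident[is_both] <- bl$pident[il[is_both]] - bo$pident[io[is_both]]
  out
}

#' Bin `both`-group bitscore deltas by empirical quantiles
#'
#' Deltas are binned at the 85th, 90th, 95th and 97.5th empirical
#' percentiles (linear-interpolation quantiles) of the bitscore-delta
#' distribution over all `both`-group calls; a larger delta (more
#' Hondaea-like) never maps to a lower bin. With a single delta it is its
#' own maximum and falls in the top bin; with several identical deltas the
#' distribution is degenerate and all fall in the lowest bin.
#'
#' @param calls Lineage calls from [classify_lineage()].
#' @return `calls` with a `quantile_bin` factor (NA unless group `both`).
#' @export
bin_deltas <- function(calls) {
  calls$quantile_bin <- factor(NA, levels = .BIN_LEVELS)
  both <- which(calls$group == "both")
  if (length(both) == 0) {
    warn_sp("no 'both'-group calls; no deltas to bin")
    return(calls)
  }
  d <- calls$delta_bitscore[both]
  if (length(d) > 1 && diff(range(d)) == 0) {
    calls$quantile_bin[both] <- .BIN_LEVELS[1]
    return(calls)
  }
  qs <- stats::quantile(d, c(0.85, 0.90, 0.95, 0.975), names = FALSE, type = 7)
  idx <- vapply(d, function(v) sum(v >= qs), integer(1)) + 1L
  calls$quantile_bin[both] <- .BIN_LEVELS[idx]
  calls
}

#' Orthogroup-based lineage filter
#'
#' A protein passes when all four conditions hold: (1) its orthogroup is
#' present in at least `min_laby_genomes` Labyrinthulomycota genomes,
#' (2) in no more than `max_nonlaby_genomes` other genomes, (3) the protein
#' is upregulated at one of the settlement timepoints, and (4) the
#' orthogroup has at least `required_hondaea_copies` copies in the Hondaea
#' genome. A protein with no orthogroup fails condition 1 (not an error).
#' The `conserved` column flags presence in at least
#' `conservation_min_genomes` Labyrinthulomycota genomes (annotation only;
#' it does not gate candidacy).
#'
#' @param og An `orthogroup_table` from [read_orthogroups()].
#' @param de_summary A [summarize_de()] result (or a named list of
#'   upregulated-timepoint vectors).
#' @param cfg A [screen_config()].
#' @param proteins Protein universe to evaluate (default: the DE summary's).
#' @return Data frame: `protein_id`, `orthogroup`, `cond1`..`cond4`,
#'   `passed`, `conserved`.
#' @export
orthogroup_filter <- function(og, de_summary, cfg = screen_config(),
                              proteins = NULL) {
  stopifnot(inherits(og, "orthogroup_table"))
  up_at <- if (inherits(de_summary, "de_summary")) de_summary$up_at
           else de_summary
  proteins <- proteins %||% names(up_at)
  laby_g <- og$genomes[og$lineages == "labyrinthulomycota"]
  nonlaby_g <- og$genomes[og$lineages != "labyrinthulomycota"]
  if (!cfg$hondaea_genome %in% og$genomes)
    abort_sp(paste0("Hondaea genome '", cfg$hondaea_genome,
                    "' absent from the orthogroup table"),
             "settleprot_screen_error")
  # member -> orthogroup lookup
  member_og <- character(0)
  for (i in seq_along(og$og_ids)) {
    mem <- unlist(og$members[[i]], use.names = FALSE)
    member_og[mem] <- og$og_ids[i]
  }
  laby_present <- rowSums(og$counts[, laby_g, drop = FALSE] > 0)
  nonlaby_present <- rowSums(og$counts[, nonlaby_g, drop = FALSE] > 0)
  hondaea_copies <- og$counts[, cfg$hondaea_genome]

  ogid <- unname(member_og[proteins])
  has_og <- !is.na(ogid)
  cond1 <- cond2 <- cond4 <- conserved <- rep(FALSE, length(proteins))
  cond2[!has_og] <- TRUE # absent from every non-laby genome
  i <- match(ogid[has_og], og$og_ids)
  cond1[has_og] <- laby_present[i] >= cfg$min_laby_genomes
  cond2[has_og] <- nonlaby_present[i] <= cfg$max_nonlaby_genomes
  cond4[has_og] <- hondaea_copies[i] >= cfg$required_hondaea_copies
  conserved[has_og] <- laby_present[i] >= cfg$conservation_min_genomes
  cond3 <- vapply(proteins, function(p)
    any((up_at[[p]] %||% numeric(0)) %in% cfg$upregulated_timepoints),
    logical(1))
  data.frame(protein_id = proteins, orthogroup = ogid,
             cond1 = cond1, cond2 = cond2, cond3 = unname(cond3),
             cond4 = cond4,
             passed = cond1 & cond2 & unname(cond3) & cond4,
             conserved = conserved,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Combine the homology and orthogroup screens into candidate records
#'
#' A candidate passes the homology path (`laby_only`, or `both` within a
#' qualifying quantile bin, optionally `aurli_only`) or the orthogroup
#' filter, and is upregulated at one of the configured settlement
#' timepoints.
#'
#' @param calls Binned lineage calls from [bin_deltas()].
#' @param og_flags Orthogroup filter output from [orthogroup_filter()].
#' @param de_summary A [summarize_de()] result (or named up-timepoint list).
#' @param cfg A [screen_config()].
#' @return Data frame of candidate records: per protein, `group`,
#'   `quantile_bin`, `passed_blast`, `passed_orthogroup`, `upregulated_at`,
#'   `candidate`.
#' @export
combine_candidates <- function(calls, og_flags, de_summary,
                               cfg = screen_config()) {
  up_at <- if (inherits(de_summary, "de_summary")) de_summary$up_at
           else de_summary
  ids <- unique(c(calls$query, og_flags$protein_id))
  i_call <- match(ids, calls$query)
  i_og <- match(ids, og_flags$protein_id)
  group <- calls$group[i_call]
  bin <- as.character(calls$quantile_bin[i_call])
  passed_blast <- !is.na(group) & (
    group == "laby_only" |
      (group == "both" & !is.na(bin) & bin %in% cfg$blast_qualifying_bins) |
      (cfg$include_aurli_only & group == "aurli_only"))
  passed_og <- !is.na(i_og) & og_flags$passed[i_og]
  up_late <- vapply(ids, function(p)
    any((up_at[[p]] %||% numeric(0)) %in% cfg$upregulated_timepoints),
    logical(1))
  up_str <- vapply(ids, function(p)
    paste(intersect(up_at[[p]] %||% numeric(0), cfg$upregulated_timepoints),
          collapse = ","), character(1))
  out <- data.frame(
    protein_id = ids, group = group, quantile_bin = bin,
    passed_blast = passed_blast, passed_orthogroup = passed_og,
    upregulated_at = unname(up_str),
    candidate = (passed_blast | passed_og) & unname(up_late),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$protein_id), , drop = FALSE]
}

#' Cross-study directional concordance cross-tabulation
#'
#' For genes called significant in both a protein-level and a
#' transcript-level study, cross-tabulates the direction of change
#' (up/down) in each, reporting the concordant diagonal and each discordant
#' cell.
#'
#' @param protein_calls,transcript_calls Data frames with columns `id` and
#'   `direction` (`"up"`/`"down"`), one row per significant gene.
#' @return List: `table` (2x2 protein x transcript counts), `n_shared`,
#'   `n_concordant`, `n_protein_up_transcript_down`,
#'   `n_protein_down_transcript_up`.
#' @export
concordance_crosstab <- function(protein_calls, transcript_calls) {
  for (d in list(protein_calls, transcript_calls)) {
    if (!all(c("id", "direction") %in% names(d)))
      abort_sp("call tables need columns id, direction",
               "settleprot_screen_error")
    if (!all(d$direction %in% c("up", "down")))
      abort_sp("direction must be 'up' or 'down'", "settleprot_screen_error")
  }
  shared <- intersect(protein_calls$id, transcript_calls$id)
  dp <- factor(protein_calls$direction[match(shared, protein_calls$id)],
               levels = c("up", "down"))
  dt <- factor(transcript_calls$direction[match(shared, transcript_calls$id)],
               levels = c("up", "down"))
  tab <- table(protein = dp, transcript = dt)
  list(table = tab,
       n_shared = length(shared),
       n_concordant = tab["up", "up"] + tab["down", "down"],
       n_protein_up_transcript_down = tab["up", "down"],
       n_protein_down_transcript_up = tab["down", "up"])
}
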