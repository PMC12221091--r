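test_that("top-hit selection keeps the best e-values with the tie cascade", {
  h <- mk_hits(rep("q", 7), paste0("s", 1:7), bit = 100 + 1:7,
               evalue = 10^-(1:7))
  top <- select_top_hits(h, 5)
  expect_equal(nrow(top), 5L)
  expect_setequal(top$sseqid, paste0("s", 3:7)) # five smallest e-values
  # e-value tie: higher pident first
  h2 <- mk_hits(c("q", "q"), c("s1", "s2"), c(50, 50),
                evalue = c(1e-10, 1e-10), pident = c(40, 80))
  expect_equal(select_top_hits(h2, 1)$sseqid, "s2")
})

test_that("top-hit selection equals the full-sort oracle on random tables", {
  set.seed(21)
  for (rep in 1:10) {
    h <- rand_hits(200, 25, 30)
    got <- select_top_hits(h, 5)
    for (q in unique(h$qseqid)) {
      sub <- h[h$qseqid == q, ]
      ord <- order(sub$evalue, -sub$pident, -sub$bitscore, sub$sseqid)
      want <- sub$sseqid[ord][seq_len(min(5, nrow(sub)))]
      expect_equal(got$sseqid[got$qseqid == q], want)
    }
  }
})

test_that("lineage classification follows the four-group definitions", {
  cfg <- screen_config()
  hits <- rbind(
    mk_hits("q_laby", "HON1", 150, taxon_class = "laby_hondaea"),
    mk_hits(rep("q_stram", 5), paste0("S", 1:5), c(200, 190, 180, 170, 160),
            taxon_class = rep("other_stramenopile", 5)),
    mk_hits("q_stram", "HON2", 100, taxon_class = "laby_hondaea"),
    mk_hits("q_both", "HON3", 120, taxon_class = "laby_hondaea"),
    mk_hits("q_both", "S9", 90, taxon_class = "other_stramenopile")
  )
  calls <- classify_lineage(hits, c("q_laby", "q_stram", "q_both", "q_none"),
                            cfg)
  g <- stats::setNames(calls$group, calls$query)
  expect_equal(unname(g["q_none"]), "aurli_only")   # absent from the table
  expect_equal(unname(g["q_laby"]), "laby_only")
  expect_equal(unname(g["q_stram"]), "stramenopile_not_hondaea") # 5 better
  expect_equal(unname(g["q_both"]), "both")
  expect_equal(calls$delta_bitscore[calls$query == "q_both"], 30)
  expect_equal(calls$delta_evalue[calls$query == "q_both"],
               (120 - 90) / 4, tolerance = 1e-9) # -log10 scale
  expect_true(all(is.na(calls$delta_bitscore[calls$group != "both"])))
  # unknown taxon class is an error
  bad <- mk_hits("q", "s", 100, taxon_class = "fungus")
  expect_error(classify_lineage(bad, "q", cfg),
               class = "settleprot_screen_error")
})

test_that("classification is a partition of the query universe", {
  set.seed(22)
  for (rep in 1:5) {
    h <- rand_hits(300, 40, 50)
    h$taxon_class <- sample(c("laby_hondaea", "other_stramenopile"),
                            nrow(h), TRUE)
    queries <- paste0("q", 1:60) # 20 with no hits at all
    calls <- classify_lineage(select_top_hits(h, 5), queries)
    expect_equal(nrow(calls), 60L)
    expect_equal(anyDuplicated(calls$query), 0L)
    expect_true(all(calls$group %in% c("aurli_only", "laby_only",
                                       "stramenopile_not_hondaea", "both")))
    expect_equal(sum(table(calls$group)), 60L)
    # deltas present iff group is both
    expect_true(all(is.na(calls$delta_bitscore) == (calls$group != "both")))
  }
})

test_that("delta binning respects empirical quantiles and degenerate cases", {
  calls <- data.frame(query = paste0("q", 1:100), group = "both",
                      delta_bitscore = 1:100, delta_evalue = 0,
                      delta_pident = 0, stringsAsFactors = FALSE)
  out <- bin_deltas(calls)
  expect_equal(as.character(out$quantile_bin[out$delta_bitscore %in% 99:100]),
               rep("Q975_100", 2))
  expect_equal(as.character(out$quantile_bin[out$delta_bitscore == 1]),
               "Q0_85")
  # monotone: a larger delta never gets a lower bin
  idx <- order(out$delta_bitscore)
  expect_true(all(diff(as.integer(out$quantile_bin[idx])) >= 0))
  # all equal -> lowest bin
  calls$delta_bitscore <- 7
  expect_true(all(bin_deltas(calls)$quantile_bin == "Q0_85"))
  # a single delta is its own maximum -> top bin
  one <- calls[1, ]
  expect_equal(as.character(bin_deltas(one)$quantile_bin), "Q975_100")
  # no both-group calls: warning, all bins NA
  none <- data.frame(query = "q", group = "laby_only",
                     delta_bitscore = NA_real_, delta_evalue = NA_real_,
                     delta_pident = NA_real_, stringsAsFactors = FALSE)
  expect_warning(out0 <- bin_deltas(none), "no 'both'")
  expect_true(is.na(out0$quantile_bin))
})

mk_og <- function(spec_rows) {
  # spec_rows: list of list(id, protein, laby (genome names), nonlaby, honfer)
  laby <- c("Aurli1", "Honfer1", "Schag1", "Aplke1", "Labyh1")
  nonlaby <- c("Phytri1", "Ectsil1", "Sacce1")
  genomes <- c(laby, nonlaby)
  lineages <- stats::setNames(c(rep("labyrinthulomycota", 5), rep("other", 3)),
                              genomes)
  members <- lapply(spec_rows, function(r) {
    row <- stats::setNames(rep(list(character(0)), 8), genomes)
    row[["Aurli1"]] <- r$protein
    for (g in r$extra) row[[g]] <- paste0(g, "|", r$protein)
    if (!is.null(r$honfer) && r$honfer > 0)
      row[["Honfer1"]] <- paste0("Honfer1|", r$protein, "_", seq_len(r$honfer))
    row
  })
  names(members) <- vapply(spec_rows, `[[`, character(1), "id")
  orthogroup_table(names(members), genomes, lineages, members)
}

test_that("the orthogroup filter applies its four conditions independently", {
  og <- mk_og(list(
    list(id = "OG1", protein = "pass", extra = character(0), honfer = 1),
    list(id = "OG2", protein = "fail2", extra = c("Phytri1", "Ectsil1"),
         honfer = 1),
    list(id = "OG3", protein = "failT2", extra = character(0), honfer = 1),
    list(id = "OG4", protein = "fail4", extra = c("Schag1", "Aplke1"),
         honfer = 0)
  ))
  up_at <- list(pass = c(6), fail2 = c(6), failT2 = c(2), fail4 = c(8),
                no_og = c(6))
  flags <- orthogroup_filter(og, up_at, screen_config())
  rownames(flags) <- flags$protein_id
  expect_true(flags["pass", "passed"])
  expect_equal(unname(unlist(flags["fail2", c("cond1", "cond2", "cond3",
                                              "cond4")])),
               c(TRUE, FALSE, TRUE, TRUE))  # 2 non-laby genomes
  expect_equal(unname(unlist(flags["failT2", c("cond1", "cond2", "cond3",
                                               "cond4")])),
               c(TRUE, TRUE, FALSE, TRUE))  # up at T2 only
  expect_equal(unname(unlist(flags["fail4", c("cond1", "cond2", "cond3",
                                              "cond4")])),
               c(TRUE, TRUE, TRUE, FALSE))  # no Hondaea copy
  # no orthogroup: fails condition 1, flagged rather than an error
  expect_false(flags["no_og", "cond1"])
  expect_true(is.na(flags["no_og", "orthogroup"]))
  # conservation flag needs presence in >= 3 laby genomes
  expect_false(flags["pass", "conserved"])
  expect_true(flags["fail4", "conserved"])
})

test_that("candidates combine the two screens by union, gated on upregulation", {
  cfg <- screen_config()
  calls <- data.frame(
    query = c("og_only", "blast_only", "both_top", "both_low", "aurli",
              "not_up"),
    group = c("stramenopile_not_hondaea", "laby_only", "both", "both",
              "aurli_only", "laby_only"),
    delta_bitscore = c(NA, NA, 50, 1, NA, NA),
    delta_evalue = NA_real_, delta_pident = NA_real_,
    quantile_bin = factor(c(NA, NA, "Q975_100", "Q0_85", NA, NA),
                          levels = settleprot:::.BIN_LEVELS),
    stringsAsFactors = FALSE)
  og_flags <- data.frame(
    protein_id = calls$query,
    passed = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  up_at <- list(og_only = 6, blast_only = 6, both_top = 8, both_low = 8,
                aurli = 6, not_up = numeric(0))
  cand <- combine_candidates(calls, og_flags, up_at, cfg)
  rownames(cand) <- cand$protein_id
  expect_true(cand["og_only", "candidate"])
  expect_false(cand["og_only", "passed_blast"])
  expect_true(cand["blast_only", "candidate"])
  expect_true(cand["both_top", "candidate"])   # qualifying top bin
  expect_false(cand["both_low", "candidate"])  # low bin does not qualify
  expect_false(cand["aurli", "candidate"])     # excluded by default
  expect_false(cand["not_up", "candidate"])    # no settlement upregulation
  # aurli_only is switchable
  cfg2 <- screen_config(include_aurli_only = TRUE)
  cand2 <- combine_candidates(calls, og_flags, up_at, cfg2)
  expect_true(cand2$candidate[cand2$protein_id == "aurli"])
})

test_that("the screen recovers exactly the planted candidates", {
  cfg <- simulation_config(n_proteins = 800, n_restricted = 8, seed = 23)
  sim <- simulate_intensities(cfg)
  hits <- simulate_hit_tables(sim$truth, cfg)
  og <- simulate_orthogroups(sim$truth, cfg)
  up_at <- truth_up_at(sim$truth)
  scfg <- screen_config()
  calls <- bin_deltas(classify_lineage(select_top_hits(hits$screen_hits, 5),
                                       sim$truth$protein_id, scfg))
  flags <- orthogroup_filter(og, up_at, scfg)
  cand <- combine_candidates(calls, flags, up_at, scfg)
  found <- cand$protein_id[cand$candidate]
  planted <- sim$truth$protein_id[sim$truth$is_candidate]
  expect_setequal(found, planted) # precision = recall = 1 on the clean fixture
  # no broad-lineage decoy ever passes, across seeds and with score noise
  for (s in 1:3) {
    cfg_s <- simulation_config(n_proteins = 800, n_restricted = 8,
                               seed = 40 + s, bitscore_noise_sd = 5)
    sim_s <- simulate_intensities(cfg_s)
    hits_s <- simulate_hit_tables(sim_s$truth, cfg_s)
    calls_s <- bin_deltas(classify_lineage(
      select_top_hits(hits_s$screen_hits, 5), sim_s$truth$protein_id, scfg))
    flags_s <- orthogroup_filter(simulate_orthogroups(sim_s$truth, cfg_s),
                                 truth_up_at(sim_s$truth), scfg)
    cand_s <- combine_candidates(calls_s, flags_s, truth_up_at(sim_s$truth),
                                 scfg)
    broad <- sim_s$truth$protein_id[sim_s$truth$lineage_class == "broad"]
    expect_equal(sum(cand_s$candidate & cand_s$protein_id %in% broad), 0L)
  }
})

test_that("cross-study concordance cross-tabs match hand counts", {
  p <- data.frame(id = c("g1", "g2", "g3", "g4", "g5", "g6"),
                  direction = c("up", "up", "down", "down", "up", "down"),
                  stringsAsFactors = FALSE)
  t <- data.frame(id = c("g1", "g2", "g3", "g4", "g5", "g9"),
                  direction = c("up", "down", "down", "up", "up", "down"),
                  stringsAsFactors = FALSE)
  cc <- concordance_crosstab(p, t)
  expect_equal(cc$n_shared, 5)
  expect_equal(unname(cc$n_concordant), 3)        # g1, g3, g5
  expect_equal(unname(cc$n_protein_up_transcript_down), 1)  # g2
  expect_equal(unname(cc$n_protein_down_transcript_up), 1)  # g4
  # identical call sets: all mass on the diagonal
  cc2 <- concordance_crosstab(p, p)
  expect_equal(unname(cc2$n_concordant), 6)
  expect_equal(unname(cc2$n_protein_up_transcript_down), 0)
  # empty intersection: all zeros
  t0 <- data.frame(id = "gX", direction = "up", stringsAsFactors = FALSE)
  cc0 <- concordance_crosstab(p, t0)
  expect_equal(cc0$n_shared, 0)
  expect_equal(sum(cc0$table), 0)
  expect_error(concordance_crosstab(p, data.frame(id = "g", direction = "flat")),
               class = "settleprot_screen_error")
})
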