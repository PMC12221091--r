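# Synthetic-data module: generates every pipeline input with known ground
# truth. The generative model is an additive log2-scale model
#   y_itr = baseline_i + effect_i(t) + batch_r + N(0, noise_sd^2)
# exponentiated to integer raw intensities, plus homology hit tables,
# orthogroup tables and annotation maps with planted structure.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a zoospore settlement time
#' course: 3,783 detected proteins over 5 timepoints (0, 2, 4, 6, 8 h) with
#' 3 replicate batches, baselines spanning log2 intensities 11.8-24.4, four
#' planted temporal archetypes sized like the observed clusters
#' (C1 91, C2 177, C3 160, C4 195 of 3,783), a planted log2 effect of 1.0,
#' replicate-level batch offsets, and 18 planted lineage-restricted
#' upregulated proteins.
#'
#' @param n_proteins Number of proteins.
#' @param timepoints Ordered hours post-settlement; the first is the
#'   zoospore reference.
#' @param n_replicates Biological replicates per timepoint (= batches).
#' @param de_fraction Named proportions of proteins planted in archetypes
#'   C1 (early decline), C2 (gradual decline), C3 (late rise), C4 (early
#'   rise); must sum to < 1.
#' @param effect_size_log2 Planted full effect size, log2 units.
#' @param noise_sd_log2 Residual noise sd, log2 units.
#' @param batch_sd_log2 Sd of per-replicate additive batch offsets, log2.
#' @param missing_rate Missing-at-random cell probability.
#' @param baseline_log2_range Range of per-protein baseline log2 intensity.
#' @param n_restricted Planted lineage-restricted upregulated proteins
#'   (drawn from archetype C3).
#' @param seed Integer base seed; every generator stream derives from it.
#' @param orphan_fraction,broad_fraction Lineage-class proportions for the
#'   non-restricted proteins (remainder is stramenopile-shared).
#' @param hondaea_like_fraction Fraction of non-differential broad proteins
#'   given a strongly Hondaea-shifted bitscore delta (fills the top
#'   quantile bin without being upregulated).
#' @param bitscore_noise_sd Sd of Gaussian noise added to all simulated
#'   bitscores (bits).
#' @param rbh_rate Fraction of proteins given a second-annotation alias
#'   forming a reciprocal best hit pair.
#' @param b_only_fraction Extra second-annotation-only ids, as a fraction of
#'   `n_proteins`.
#' @param n_ambiguous Unpaired second-annotation ids planted as many-to-one
#'   best-hit targets (exercise the merge ambiguity rule).
#' @param enriched_archetype Archetype carrying the planted enriched
#'   annotation term.
#' @param enrichment_odds Odds ratio of the planted term in that archetype
#'   (`Inf` nests the term inside the archetype).
#' @param annotation_base_rate Base membership probability of the planted
#'   term outside the target archetype.
#' @param n_background_terms Number of uniform background terms.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 3783,
                              timepoints = c(0, 2, 4, 6, 8),
                              n_replicates = 3,
                              de_fraction = c(C1 = 91, C2 = 177,
                                              C3 = 160, C4 = 195) / 3783,
                              effect_size_log2 = 1.0,
                              noise_sd_log2 = 0.25,
                              batch_sd_log2 = 0.3,
                              missing_rate = 0.05,
                              baseline_log2_range = c(11.8, 24.4),
                              n_restricted = 18,
                              seed = 1,
                              orphan_fraction = 0.03,
                              broad_fraction = 0.35,
                              hondaea_like_fraction = 0.05,
                              bitscore_noise_sd = 0,
                              rbh_rate = 0.65,
                              b_only_fraction = 0.13,
                              n_ambiguous = 5,
                              enriched_archetype = "C4",
                              enrichment_odds = 8,
                              annotation_base_rate = 0.05,
                              n_background_terms = 20) {
  cfg <- as.list(environment())
  if (length(cfg$de_fraction) != 4)
    abort_sp("de_fraction must give 4 proportions (C1..C4)",
             "settleprot_config_error")
  names(cfg$de_fraction) <- c("C1", "C2", "C3", "C4")
  if (any(cfg$de_fraction < 0) || any(cfg$de_fraction > 1) ||
      sum(cfg$de_fraction) >= 1)
    abort_sp("de_fraction proportions must lie in [0,1] and sum to < 1",
             "settleprot_config_error")
  if (length(cfg$timepoints) < 2 || is.unsorted(cfg$timepoints, strictly = TRUE))
    abort_sp("timepoints must be strictly increasing, length >= 2",
             "settleprot_config_error")
  if (diff(cfg$baseline_log2_range) <= 0)
    abort_sp("baseline_log2_range must be an ordered interval",
             "settleprot_config_error")
  if (cfg$effect_size_log2 <= 0 || cfg$noise_sd_log2 < 0 ||
      cfg$batch_sd_log2 < 0 || cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    abort_sp("invalid noise/effect/missing configuration",
             "settleprot_config_error")
  if (round(cfg$de_fraction[["C3"]] * cfg$n_proteins) < cfg$n_restricted)
    abort_sp("n_restricted exceeds the number of late-rise (C3) proteins",
             "settleprot_config_error")
  structure(cfg, class = "simulation_config")
}

# archetype shapes as multiples of the full effect, on m timepoints:
# C1 sustained early decline, C2 gradual decline, C3 late rise, C4 early rise
archetype_shapes <- function(m) {
  stopifnot(m >= 3)
  rbind(
    C1 = c(0, rep(-1, m - 1)),
    C2 = c(0, -seq_len(m - 1) / (m - 1)),
    C3 = c(rep(0, m - 2), 1, 1),
    C4 = c(0, 1, rep(0.25, m - 2))
  )
}

#' Simulate a raw intensity time course with planted ground truth
#'
#' @param config A [simulation_config()].
#' @return A list with `matrix` (a raw-scale [intensity_matrix()]) and
#'   `truth` (per-protein data frame: archetype, true per-timepoint log2
#'   effects, planted up/down timepoints, lineage class, orthogroup
#'   condition flags, candidate flag, and second-annotation alias).
#' @export
simulate_intensities <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_proteins
  tps <- config$timepoints
  m <- length(tps)
  reps <- paste0("R", seq_len(config$n_replicates))
  ids <- sprintf("A%05d", seq_len(n))

  truth <- simulate_truth(config, ids)
  shapes <- archetype_shapes(m) * config$effect_size_log2
  eff <- matrix(0, n, m, dimnames = list(ids, paste0("T", tps)))
  for (arch in rownames(shapes)) {
    sel <- truth$archetype == arch
    if (any(sel)) eff[sel, ] <- matrix(shapes[arch, ], sum(sel), m, byrow = TRUE)
  }

  baseline <- with_stream_seed(config$seed, "baseline",
    stats::runif(n, config$baseline_log2_range[1], config$baseline_log2_range[2]))
  batch_off <- with_stream_seed(config$seed, "batch",
    stats::rnorm(config$n_replicates, 0, config$batch_sd_log2))

  design <- sample_design(data.frame(
    sample_id = paste0("T", rep(tps, each = config$n_replicates), "_",
                       rep(reps, m)),
    timepoint = rep(tps, each = config$n_replicates),
    replicate = rep(reps, m),
    stringsAsFactors = FALSE
  ))

  y <- baseline +
    eff[, rep(seq_len(m), each = config$n_replicates), drop = FALSE] +
    matrix(rep(batch_off, m), n, m * config$n_replicates, byrow = TRUE)
  noise <- with_stream_seed(config$seed, "noise",
    matrix(stats::rnorm(length(y), 0, config$noise_sd_log2), n))
  y <- y + noise
  raw <- pmax(round(2^y), 1)
  if (config$missing_rate > 0) {
    mask <- with_stream_seed(config$seed, "missing",
      matrix(stats::runif(length(raw)) < config$missing_rate, n))
    raw[mask] <- NA_real_
  }
  dimnames(raw) <- list(ids, design$sample_id)

  colnames(eff) <- paste0("eff_T", tps)
  truth <- cbind(truth, as.data.frame(eff))
  attr(truth, "timepoints") <- tps
  attr(truth, "effect_size_log2") <- config$effect_size_log2
  attr(truth, "batch_offsets") <- stats::setNames(batch_off, reps)

  list(matrix = intensity_matrix(raw, design, scale = "raw"), truth = truth)
}

# assign archetypes, lineage classes and orthogroup-condition truth flags
simulate_truth <- function(config, ids) {
  n <- length(ids)
  tps <- config$timepoints
  counts <- round(config$de_fraction * n)
  arch <- rep("null", n)
  perm <- with_stream_seed(config$seed, "archetypes", sample.int(n))
  idx <- perm
  off <- 0
  for (k in names(counts)) {
    take <- seq_len(counts[[k]]) + off
    arch[idx[take]] <- k
    off <- off + counts[[k]]
  }

  shapes <- archetype_shapes(length(tps)) * config$effect_size_log2
  full <- config$effect_size_log2 - 1e-9
  up_tp <- lapply(arch, function(a) {
    if (a == "null") return(numeric(0))
    tps[shapes[a, ] >= full]
  })
  down_tp <- lapply(arch, function(a) {
    if (a == "null") return(numeric(0))
    tps[shapes[a, ] <= -full]
  })
  late <- setdiff(tps, tps[1])
  late <- late[late >= 4] # settlement-phase timepoints for the screen
  up_late <- vapply(up_tp, function(v) any(v %in% late), logical(1))

  c3_idx <- which(arch == "C3")
  if (config$n_restricted > length(c3_idx))
    abort_sp("n_restricted exceeds the number of late-rise (C3) proteins",
             "settleprot_config_error")
  lineage <- rep("stramenopile_shared", n)
  delta_class <- rep("none", n)
  picks <- with_stream_seed(config$seed, "lineage", {
    restricted <- sample(c3_idx, config$n_restricted)
    pool <- setdiff(seq_len(n), restricted)
    # orthogroup-filter negative controls, one violated condition each
    ctl_pool_c3 <- setdiff(intersect(pool, which(arch == "C3")), restricted)
    ctl2 <- sample(ctl_pool_c3, min(4, length(ctl_pool_c3)))
    ctl4 <- sample(setdiff(ctl_pool_c3, ctl2),
                   min(4, length(ctl_pool_c3) - length(ctl2)))
    ctl3 <- sample(intersect(pool, which(arch == "null")), 4)
    pool2 <- setdiff(pool, c(ctl2, ctl3, ctl4))
    orphan <- sample(pool2, round(config$orphan_fraction * n))
    pool3 <- setdiff(pool2, orphan)
    broad <- sample(pool3, round(config$broad_fraction * n))
    hondaea_like <- {
      nde_broad <- intersect(broad, which(arch == "null"))
      sample(nde_broad, round(config$hondaea_like_fraction * length(nde_broad)))
    }
    list(restricted = restricted, ctl2 = ctl2, ctl3 = ctl3, ctl4 = ctl4,
         orphan = orphan, broad = broad, hondaea_like = hondaea_like)
  })
  lineage[picks$restricted] <- "laby_restricted"
  lineage[picks$ctl3] <- "laby_restricted" # restricted but not upregulated
  lineage[picks$orphan] <- "orphan"
  lineage[picks$broad] <- "broad"
  de <- arch != "null"
  delta_class[picks$broad] <- ifelse(de[picks$broad], "negative", "low")
  delta_class[picks$hondaea_like] <- "high"

  # orthogroup-condition truth: cond1 >=2 laby genomes, cond2 <=1 non-laby,
  # cond3 upregulated at a settlement timepoint, cond4 >=1 Hondaea copy
  cond1 <- cond2 <- cond4 <- rep(NA, n)
  cond3 <- up_late
  is_ctl <- seq_len(n) %in% c(picks$ctl2, picks$ctl3, picks$ctl4)
  for (i in seq_len(n)) {
    if (i %in% picks$restricted || i %in% picks$ctl3) {
      cond1[i] <- TRUE; cond2[i] <- TRUE; cond4[i] <- TRUE
    } else if (i %in% picks$ctl2) {
      cond1[i] <- TRUE; cond2[i] <- FALSE; cond4[i] <- TRUE
    } else if (i %in% picks$ctl4) {
      cond1[i] <- TRUE; cond2[i] <- TRUE; cond4[i] <- FALSE
    } else if (lineage[i] == "broad") {
      cond1[i] <- TRUE; cond2[i] <- FALSE; cond4[i] <- TRUE
    } else if (lineage[i] == "orphan") {
      cond1[i] <- FALSE; cond2[i] <- TRUE; cond4[i] <- FALSE
    } else { # stramenopile_shared
      cond1[i] <- FALSE; cond2[i] <- FALSE; cond4[i] <- FALSE
    }
  }
  conserved <- rep(FALSE, n)
  conserved[picks$restricted[seq_along(picks$restricted) %% 2 == 1]] <- TRUE
  is_candidate <- seq_len(n) %in% picks$restricted

  # second-annotation aliases for the proteome merge
  id_b <- rep(NA_character_, n)
  paired <- with_stream_seed(config$seed, "aliases",
    sample.int(n, round(config$rbh_rate * n)))
  id_b[paired] <- sub("^A", "B", ids[paired])

  data.frame(
    protein_id = ids, archetype = arch,
    up_timepoints = vapply(up_tp, paste, character(1), collapse = ","),
    down_timepoints = vapply(down_tp, paste, character(1), collapse = ","),
    lineage_class = lineage, delta_class = delta_class,
    og_cond1 = cond1, og_cond2 = cond2, og_cond3 = cond3, og_cond4 = cond4,
    og_conserved = conserved, og_control = is_ctl,
    is_candidate = is_candidate, id_b = id_b,
    stringsAsFactors = FALSE
  )
}

#' Simulate homology hit tables from planted lineage truth
#'
#' Emits (a) a stramenopile-database search table in which lineage-restricted
#' proteins hit only Hondaea-labeled subjects, shared proteins have at least
#' five stronger non-Hondaea hits, orphans have none, and broad proteins hit
#' both classes with class-specific bitscore deltas; and (b) the pair of
#' bidirectional hit tables between the two annotation id spaces used by the
#' proteome merge, with planted reciprocal-best-hit pairs, asymmetric decoy
#' hits, and many-to-one ambiguity targets.
#'
#' @param truth Truth table from [simulate_intensities()].
#' @param config The same [simulation_config()].
#' @return List with `screen_hits` (a [hit_table()] with `taxon_class`),
#'   `taxon_map` (data frame), `hits_ab`, `hits_ba`, `ids_a`, `ids_b`.
#' @export
simulate_hit_tables <- function(truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- nrow(truth)
  ids <- truth$protein_id

  rows <- with_stream_seed(config$seed, "screen_hits", {
    qs <- character(0); ss <- character(0); bits <- numeric(0); pid <- numeric(0)
    add <- function(q, s, b, p) {
      qs <<- c(qs, q); ss <<- c(ss, s); bits <<- c(bits, b); pid <<- c(pid, p)
    }
    laby_idx <- which(truth$lineage_class == "laby_restricted")
    for (i in laby_idx) {
      b0 <- stats::rnorm(1, 150, 15)
      add(rep(ids[i], 2), paste0("HONFER_", ids[i], "_", 1:2),
          c(b0, b0 - stats::runif(1, 5, 20)), stats::runif(2, 40, 90))
    }
    shared_idx <- which(truth$lineage_class == "stramenopile_shared")
    for (i in shared_idx) {
      b0 <- stats::rnorm(1, 200, 15)
      add(rep(ids[i], 6), paste0("STRAM_", ids[i], "_", 1:6),
          b0 - seq(0, 25, length.out = 6), stats::runif(6, 40, 95))
      if (i %% 2 == 0) # half also carry one clearly weaker Hondaea hit
        add(ids[i], paste0("HONFER_", ids[i], "_w"), b0 - 40,
            stats::runif(1, 30, 60))
    }
    broad_idx <- which(truth$lineage_class == "broad")
    for (i in broad_idx) {
      base <- stats::rnorm(1, 180, 15)
      delta <- switch(truth$delta_class[i],
                      high = stats::rnorm(1, 45, 5),
                      negative = stats::rnorm(1, -12, 4),
                      stats::rnorm(1, 0, 8))
      add(rep(ids[i], 6),
          c(paste0("STRAM_", ids[i], "_", 1:5), paste0("HONFER_", ids[i], "_h")),
          c(base - c(0, 5, 10, 15, 20), base + delta),
          stats::runif(6, 30, 95))
    }
    if (config$bitscore_noise_sd > 0)
      bits <- bits + stats::rnorm(length(bits), 0, config$bitscore_noise_sd)
    data.frame(qseqid = qs, sseqid = ss, pident = round(pid, 1),
               length = 200L, mismatch = 50L, gapopen = 5L,
               qstart = 1L, qend = 200L, sstart = 1L, send = 200L,
               evalue = pmax(10^(-bits / 4), 1e-180),
               bitscore = round(bits, 1), stringsAsFactors = FALSE)
  })
  taxon_map <- data.frame(
    sseqid = unique(rows$sseqid),
    taxon_class = ifelse(grepl("^HONFER_", unique(rows$sseqid)),
                         "laby_hondaea", "other_stramenopile"),
    stringsAsFactors = FALSE
  )
  screen_hits <- resolve_taxon_class(hit_table(rows), taxon_map)

  merge <- with_stream_seed(config$seed, "merge_hits",
                            simulate_merge_hits(truth, config))
  c(list(screen_hits = screen_hits, taxon_map = taxon_map), merge)
}

simulate_merge_hits <- function(truth, config) {
  ids_a <- truth$protein_id
  paired_a <- ids_a[!is.na(truth$id_b)]
  paired_b <- truth$id_b[!is.na(truth$id_b)]
  n_b_only <- round(config$b_only_fraction * length(ids_a))
  b_only <- sprintf("B9%05d", seq_len(n_b_only))
  ids_b <- c(paired_b, b_only)
  unpaired_a <- setdiff(ids_a, paired_a)

  mk <- function(q, s, bits) data.frame(
    qseqid = q, sseqid = s, pident = 90, length = 200L, mismatch = 10L,
    gapopen = 1L, qstart = 1L, qend = 200L, sstart = 1L, send = 200L,
    evalue = pmax(10^(-bits / 4), 1e-180), bitscore = bits,
    stringsAsFactors = FALSE)

  jit_ab <- stats::runif(length(paired_a), 0, 5)
  ab <- mk(paired_a, paired_b, 300 + jit_ab)
  ba <- mk(paired_b, paired_a, 300 + stats::runif(length(paired_b), 0, 5))
  if (length(paired_b) > 1) { # weaker decoy cross-hits
    decoy <- c(paired_b[-1], paired_b[1])
    ab <- rbind(ab, mk(paired_a, decoy, 200 + stats::runif(length(paired_a), 0, 5)))
  }
  # asymmetric: unpaired A ids best-hitting paired B ids (whose best is their
  # own partner), so they never pair
  n_amb <- min(config$n_ambiguous, floor(length(unpaired_a) / 2),
               length(b_only))
  amb_b <- if (n_amb > 0) b_only[seq_len(n_amb)] else character(0)
  amb_a <- if (n_amb > 0) unpaired_a[seq_len(2 * n_amb)] else character(0)
  rest_a <- setdiff(unpaired_a, amb_a)
  if (length(rest_a) > 0 && length(paired_b) > 0) {
    half <- rest_a[seq_len(floor(length(rest_a) / 2))] # rest have no B hit
    if (length(half) > 0)
      ab <- rbind(ab, mk(half, paired_b[(seq_along(half) %% length(paired_b)) + 1],
                         250 + stats::runif(length(half), 0, 5)))
  }
  if (n_amb > 0) {
    # each ambiguity target is the best hit of exactly two unpaired A queries
    ab <- rbind(ab, mk(amb_a, rep(amb_b, each = 2),
                       280 + stats::runif(length(amb_a), 0, 2)))
    if (length(paired_a) > 0)
      ba <- rbind(ba, mk(amb_b, paired_a[seq_len(n_amb)],
                         280 + stats::runif(n_amb, 0, 2)))
  }
  list(hits_ab = hit_table(ab), hits_ba = hit_table(ba),
       ids_a = ids_a, ids_b = ids_b)
}

#' Simulate an orthogroup table realizing the planted condition flags
#'
#' Planted candidates sit in orthogroups satisfying all four screen
#' conditions; designated negative controls violate exactly one each; broad,
#' shared and orphan proteins get orthogroups (or none) consistent with
#' their lineage class.
#'
#' @param truth Truth table from [simulate_intensities()].
#' @param config The same [simulation_config()].
#' @return An `orthogroup_table`; its `genome_lineages` attribute maps each
#'   genome to its lineage.
#' @export
simulate_orthogroups <- function(truth, config) {
  laby <- c("Aurli1", "Honfer1", "Schag1", "Aplke1", "Labyh1")
  nonlaby <- c("Phytri1", "Ectsil1", "Sacce1")
  genomes <- c(laby, nonlaby)
  lineages <- stats::setNames(
    c(rep("labyrinthulomycota", length(laby)), rep("other", length(nonlaby))),
    genomes)

  # rows derive from the planted condition flags alone, so negative
  # controls keep exactly their one violated condition
  keep <- truth$lineage_class != "orphan"
  idx <- which(keep)
  og_ids <- sprintf("OG%05d", seq_along(idx))
  members <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    pid <- truth$protein_id[i]
    row <- stats::setNames(rep(list(character(0)), length(genomes)), genomes)
    row[["Aurli1"]] <- pid
    foreign <- function(g) paste0(g, "|", pid)
    if (isTRUE(truth$og_cond4[i])) row[["Honfer1"]] <- foreign("Honfer1")
    n_laby <- 1 + isTRUE(truth$og_cond4[i])
    if (isTRUE(truth$og_cond1[i]) && n_laby < 2) {
      row[["Schag1"]] <- foreign("Schag1"); n_laby <- n_laby + 1
    }
    if (isTRUE(truth$og_conserved[i]) && n_laby < 3) {
      row[["Schag1"]] <- foreign("Schag1")
      row[["Aplke1"]] <- foreign("Aplke1")
    }
    if (truth$lineage_class[i] == "broad") { # conserved across all laby
      row[["Schag1"]] <- foreign("Schag1")
      row[["Aplke1"]] <- foreign("Aplke1")
      row[["Labyh1"]] <- foreign("Labyh1")
    }
    if (!isTRUE(truth$og_cond2[i])) {
      row[["Phytri1"]] <- foreign("Phytri1")
      row[["Ectsil1"]] <- foreign("Ectsil1")
      if (truth$lineage_class[i] == "broad")
        row[["Sacce1"]] <- foreign("Sacce1")
    } else if (i %% 2 == 0) {
      row[["Phytri1"]] <- foreign("Phytri1") # <= 1 non-laby still passes
    }
    members[[j]] <- row
  }
  names(members) <- og_ids
  og <- orthogroup_table(og_ids, genomes, lineages, members)
  attr(og, "genome_lineages") <- lineages
  og
}

#' Simulate annotation maps with one planted enriched term
#'
#' One term is enriched in the configured archetype at the configured odds
#' ratio; background terms are assigned uniformly (one per protein).
#'
#' @param truth Truth table from [simulate_intensities()].
#' @param config The same [simulation_config()].
#' @return An [annotation_map()]; the `enriched_term` attribute names the
#'   planted term.
#' @export
simulate_annotations <- function(truth, config) {
  n <- nrow(truth)
  res <- with_stream_seed(config$seed, "annotations", {
    bg_term <- sprintf("KOG%02d", sample.int(config$n_background_terms, n,
                                             replace = TRUE))
    target <- truth$archetype == config$enriched_archetype
    p0 <- config$annotation_base_rate
    if (is.infinite(config$enrichment_odds)) {
      p1 <- 1; p0 <- 0
    } else {
      odds1 <- config$enrichment_odds * p0 / (1 - p0)
      p1 <- odds1 / (1 + odds1)
    }
    memb <- stats::runif(n) < ifelse(target, p1, p0)
    list(bg_term = bg_term, memb = memb)
  })
  terms <- split(truth$protein_id, res$bg_term)
  if (any(res$memb)) terms[["KOGenr"]] <- truth$protein_id[res$memb]
  ann <- annotation_map(terms, "KOG_class")
  attr(ann, "enriched_term") <- if (any(res$memb)) "KOGenr" else NA_character_
  ann
}

#' Generate and write every pipeline input with its ground truth
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_all <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_intensities(config)
  hits <- simulate_hit_tables(sim$truth, config)
  og <- simulate_orthogroups(sim$truth, config)
  ann <- simulate_annotations(sim$truth, config)

  p <- function(f) file.path(out_dir, f)
  write_intensity_table(sim$matrix, p("intensities.tsv"), p("design.tsv"))
  write_hit_table(hits$screen_hits, p("screen_hits.tsv"))
  write_tsv_sp(hits$taxon_map, p("taxon_map.tsv"))
  write_hit_table(hits$hits_ab, p("hits_ab.tsv"))
  write_hit_table(hits$hits_ba, p("hits_ba.tsv"))
  writeLines(hits$ids_a, p("ids_a.txt"))
  writeLines(hits$ids_b, p("ids_b.txt"))
  write_orthogroups(og, p("orthogroups.tsv"))
  write_tsv_sp(data.frame(genome = names(attr(og, "genome_lineages")),
                          lineage = unname(attr(og, "genome_lineages"))),
               p("genome_lineages.tsv"))
  write_annotation_map(ann, p("annotations_kog.tsv"))
  write_tsv_sp(sim$truth, p("truth.tsv"))

  invisible(list(matrix = sim$matrix, truth = sim$truth, hits = hits,
                 orthogroups = og, annotations = ann, dir = out_dir))
}
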