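# shared fixture builders: tiny designs, intensity matrices and hit tables
# constructed in code

mk_design <- function(tps = c(0, 2, 4, 6, 8), reps = 3) {
  data.frame(
    sample_id = paste0("T", rep(tps, each = reps), "_R", rep(seq_len(reps), length(tps))),
    timepoint = rep(tps, each = reps),
    replicate = paste0("R", rep(seq_len(reps), length(tps))),
    stringsAsFactors = FALSE
  )
}

mk_im <- function(values, design = NULL, scale = "glog",
                  tps = c(0, 2, 4, 6, 8), reps = 3) {
  if (is.null(design)) design <- mk_design(tps, reps)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  colnames(values) <- design$sample_id
  intensity_matrix(values, design, scale = scale)
}

mk_hits <- function(q, s, bit, evalue = 10^(-bit / 4), pident = 50,
                    taxon_class = NULL) {
  n <- length(q)
  df <- data.frame(qseqid = q, sseqid = s, pident = rep_len(pident, n),
                   length = rep_len(100L, n), mismatch = rep_len(10L, n),
                   gapopen = rep_len(1L, n), qstart = rep_len(1L, n),
                   qend = rep_len(100L, n), sstart = rep_len(1L, n),
                   send = rep_len(100L, n), evalue = rep_len(evalue, n),
                   bitscore = bit, stringsAsFactors = FALSE)
  h <- hit_table(df)
  if (!is.null(taxon_class)) h$taxon_class <- taxon_class
  h
}

rand_hits <- function(n_rows, n_q, n_s, qpre = "q", spre = "s") {
  mk_hits(
    q = paste0(qpre, sample.int(n_q, n_rows, replace = TRUE)),
    s = paste0(spre, sample.int(n_s, n_rows, replace = TRUE)),
    bit = round(stats::runif(n_rows, 40, 300), 1),
    evalue = 10^(-stats::runif(n_rows, 5, 50)),
    pident = round(stats::runif(n_rows, 20, 100), 1)
  )
}

# brute-force best-hit oracle: explicit pairwise comparator over all rows
oracle_best_hits <- function(hits) {
  out <- character(0)
  for (q in unique(hits$qseqid)) {
    h <- hits[hits$qseqid == q, , drop = FALSE]
    best <- 1
    for (i in seq_len(nrow(h))[-1]) {
      better <- FALSE
      if (h$bitscore[i] > h$bitscore[best]) better <- TRUE
      else if (h$bitscore[i] == h$bitscore[best]) {
        if (h$evalue[i] < h$evalue[best]) better <- TRUE
        else if (h$evalue[i] == h$evalue[best]) {
          if (h$pident[i] > h$pident[best]) better <- TRUE
          else if (h$pident[i] == h$pident[best] &&
                   h$sseqid[i] < h$sseqid[best]) better <- TRUE
        }
      }
      if (better) best <- i
    }
    out[q] <- h$sseqid[best]
  }
  out
}

# truth-derived upregulation sets (noise-free calls) for the screen
truth_up_at <- function(truth) {
  up <- lapply(strsplit(truth$up_timepoints, ","), function(v)
    as.numeric(v[nzchar(v)]))
  names(up) <- truth$protein_id
  up
}
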