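# Merge two predicted-proteome id spaces into one non-redundant protein set
# via reciprocal best hits (RBH), and map per-annotation detection lists
# onto the merged set.

#' Best hit per query
#'
#' For each query the hit maximizing bitscore; ties broken by lower e-value,
#' then higher percent identity, then lexicographically smaller subject id.
#'
#' @param hits A [hit_table()].
#' @return Named character vector: query -> best subject (empty if no hits).
#' @export
best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0) return(stats::setNames(character(0), character(0)))
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, -hits$pident,
               hits$sseqid, method = "radix")
  h <- hits[ord, c("qseqid", "sseqid")]
  first <- !duplicated(h$qseqid)
  stats::setNames(h$sseqid[first], h$qseqid[first])
}

#' Reciprocal best hits between two id spaces
#'
#' @param hits_ab Hits with A-space queries against B-space subjects.
#' @param hits_ba Hits with B-space queries against A-space subjects.
#' @return Data frame with columns `id_a`, `id_b`: pairs `(a, b)` such that
#'   `b` is `a`'s best hit and `a` is `b`'s best hit.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  best_ab <- best_hit_per_query(hits_ab)
  best_ba <- best_hit_per_query(hits_ba)
  a <- names(best_ab)
  b <- unname(best_ab)
  mutual <- !is.na(best_ba[b]) & best_ba[b] == a
  out <- data.frame(id_a = a[mutual], id_b = b[mutual],
                    stringsAsFactors = FALSE)
  out[order(out$id_a), , drop = FALSE]
}

#' Build the non-redundant merged protein set
#'
#' The merged set consists of one entry per RBH pair (keyed by the A-space
#' id, carrying the B-space id as alias) plus all unpaired ids of either
#' space. Optionally, an unpaired entry that is the best hit of two or more
#' queries from the other space which themselves formed no pair (a
#' many-to-one conflict) is dropped as ambiguous; each drop is logged with
#' its reason.
#'
#' @param ids_a,ids_b Character id universes of the two spaces.
#' @param pairs RBH pairs from [reciprocal_best_hits()].
#' @param hits_ab,hits_ba Optional hit tables; required for the ambiguity
#'   rule.
#' @param drop_ambiguous Apply the many-to-one ambiguity rule (default TRUE
#'   when hit tables are supplied).
#' @return A `merge_map`: entries data frame (`entry_id`, `id_a`, `id_b`,
#'   `type` in pair/a_only/b_only), `rbh_pairs`, `unpaired_a`, `unpaired_b`,
#'   `dropped` (with reason codes), and a `log` of category counts.
#' @export
build_nonredundant <- function(ids_a, ids_b, pairs,
                               hits_ab = NULL, hits_ba = NULL,
                               drop_ambiguous = !is.null(hits_ab)) {
  ids_a <- as.character(ids_a); ids_b <- as.character(ids_b)
  if (anyDuplicated(ids_a) || anyDuplicated(ids_b))
    abort_sp("id universes must be duplicate-free", "settleprot_merge_error")
  bad_a <- setdiff(pairs$id_a, ids_a)
  bad_b <- setdiff(pairs$id_b, ids_b)
  if (length(bad_a) + length(bad_b) > 0)
    abort_sp(paste0("pair id(s) absent from their id universe: ",
                    paste(c(bad_a, bad_b), collapse = ", ")),
             "settleprot_merge_error")
  if (anyDuplicated(pairs$id_a) || anyDuplicated(pairs$id_b))
    abort_sp("an id occurs in more than one RBH pair", "settleprot_merge_error")

  unpaired_a <- setdiff(ids_a, pairs$id_a)
  unpaired_b <- setdiff(ids_b, pairs$id_b)

  dropped <- data.frame(id = character(0), space = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  if (isTRUE(drop_ambiguous)) {
    if (is.null(hits_ab) || is.null(hits_ba))
      abort_sp("ambiguity rule needs both hit tables", "settleprot_merge_error")
    best_ab <- best_hit_per_query(hits_ab)
    best_ba <- best_hit_per_query(hits_ba)
    amb <- function(best, queries_unpaired, targets_unpaired, space) {
      b <- best[names(best) %in% queries_unpaired]
      tab <- table(unname(b))
      conflicted <- names(tab)[tab >= 2]
      conflicted <- intersect(conflicted, targets_unpaired)
      if (length(conflicted) == 0) return(NULL)
      data.frame(id = sort(conflicted), space = space,
                 reason = "many_to_one_best_hit_conflict",
                 stringsAsFactors = FALSE)
    }
    dropped <- rbind(
      amb(best_ab, unpaired_a, unpaired_b, "B"),
      amb(best_ba, unpaired_b, unpaired_a, "A")
    ) %||% dropped
    if (is.null(dropped))
      dropped <- data.frame(id = character(0), space = character(0),
                            reason = character(0), stringsAsFactors = FALSE)
    unpaired_a <- setdiff(unpaired_a, dropped$id[dropped$space == "A"])
    unpaired_b <- setdiff(unpaired_b, dropped$id[dropped$space == "B"])
  }

  entries <- rbind(
    if (nrow(pairs) > 0)
      data.frame(entry_id = pairs$id_a, id_a = pairs$id_a, id_b = pairs$id_b,
                 type = "pair", stringsAsFactors = FALSE),
    if (length(unpaired_a) > 0)
      data.frame(entry_id = unpaired_a, id_a = unpaired_a,
                 id_b = NA_character_, type = "a_only",
                 stringsAsFactors = FALSE),
    if (length(unpaired_b) > 0)
      data.frame(entry_id = unpaired_b, id_a = NA_character_,
                 id_b = unpaired_b, type = "b_only", stringsAsFactors = FALSE)
  )
  if (is.null(entries))
    entries <- data.frame(entry_id = character(0), id_a = character(0),
                          id_b = character(0), type = character(0),
                          stringsAsFactors = FALSE)
  entries <- entries[order(entries$entry_id), , drop = FALSE]
  rownames(entries) <- NULL
  if (anyDuplicated(entries$entry_id))
    abort_sp("internal error: duplicate merged entry ids",
             "settleprot_merge_error")

  log <- c(n_pairs = nrow(pairs), n_unpaired_a = length(unpaired_a),
           n_unpaired_b = length(unpaired_b), n_dropped = nrow(dropped),
           n_entries = nrow(entries))
  structure(list(entries = entries, rbh_pairs = pairs,
                 unpaired_a = unpaired_a, unpaired_b = unpaired_b,
                 dropped = dropped, log = log),
            class = "merge_map")
}

#' @export
print.merge_map <- function(x, ...) {
  cat(sprintf(paste0("merge_map: %d entries (%d RBH pairs + %d A-only + ",
                     "%d B-only); %d dropped as ambiguous\n"),
              x$log["n_entries"], x$log["n_pairs"], x$log["n_unpaired_a"],
              x$log["n_unpaired_b"], x$log["n_dropped"]))
  invisible(x)
}

#' Map per-space detection lists onto the merged protein set
#'
#' A pair entry is detected if either member is detected; an unpaired entry
#' is detected iff its own id is.
#'
#' @param detected_a,detected_b Character vectors of detected ids per space.
#' @param merge A `merge_map` from [build_nonredundant()].
#' @return Character vector of detected merged entry ids.
#' @export
map_detected <- function(detected_a, detected_b, merge) {
  stopifnot(inherits(merge, "merge_map"))
  e <- merge$entries
  hit <- (!is.na(e$id_a) & e$id_a %in% detected_a) |
         (!is.na(e$id_b) & e$id_b %in% detected_b)
  e$entry_id[hit]
}
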