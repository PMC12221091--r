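# Readers/writers and validated in-memory containers for every external
# table the pipeline touches. All tables are TSV with '#' comment lines
# permitted. Identifiers are opaque strings throughout.

#' Construct a sample design table
#'
#' Describes the samples of an intensity matrix: hours post-settlement
#' (`timepoint`), biological `replicate`, and `batch` (defaults to the
#' replicate, matching replicate-wise labeling of a time course quantified
#' in one labeling run per replicate).
#'
#' @param df Data frame with columns `sample_id`, `timepoint`, `replicate`
#'   and optionally `batch`.
#' @return A validated `sample_design` data frame.
#' @export
sample_design <- function(df) {
  req <- c("sample_id", "timepoint", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    abort_sp(paste0("design is missing column(s): ", paste(miss, collapse = ", ")),
             "settleprot_io_error")
  df$sample_id <- as.character(df$sample_id)
  df$timepoint <- as.numeric(df$timepoint)
  df$replicate <- as.character(df$replicate)
  if (anyNA(df$timepoint))
    abort_sp("non-numeric timepoint in design", "settleprot_io_error")
  if (is.null(df$batch)) df$batch <- df$replicate
  df$batch <- as.character(df$batch)
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    abort_sp(paste0("duplicate sample_id in design: ", paste(dup, collapse = ", ")),
             "settleprot_io_error")
  }
  key <- paste(df$timepoint, df$replicate)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    abort_sp(paste0("duplicated (timepoint, replicate) pair(s): ",
                    paste(dup, collapse = "; ")), "settleprot_io_error")
  }
  df <- df[, c("sample_id", "timepoint", "replicate", "batch")]
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Construct an intensity matrix
#'
#' Protein-by-sample abundance grid with its sample design. `scale` records
#' where in the pipeline the values sit: `raw` reporter intensities (positive
#' where present), `glog` after variance stabilization, `batch_corrected`
#' after batch-effect removal.
#'
#' @param values Numeric matrix, rownames = protein ids, colnames = sample ids.
#' @param design A [sample_design()] covering exactly the columns of `values`.
#' @param scale One of `"raw"`, `"glog"`, `"batch_corrected"`.
#' @return An `intensity_matrix` object.
#' @export
intensity_matrix <- function(values, design,
                             scale = c("raw", "glog", "batch_corrected")) {
  scale <- match.arg(scale)
  design <- sample_design(design)
  if (!is.matrix(values) || !is.numeric(values))
    abort_sp("values must be a numeric matrix", "settleprot_io_error")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort_sp("values must carry protein ids (rownames) and sample ids (colnames)",
             "settleprot_io_error")
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    abort_sp(paste0("duplicate protein id(s): ", paste(dup, collapse = ", ")),
             "settleprot_io_error")
  }
  if (!identical(sort(colnames(values)), sort(design$sample_id)))
    abort_sp("sample columns do not match the design sample_id set",
             "settleprot_io_error")
  values <- values[, design$sample_id, drop = FALSE]
  if (scale == "raw" && any(values <= 0, na.rm = TRUE))
    abort_sp("raw intensities must be > 0 where present", "settleprot_io_error")
  structure(list(values = values, design = design, scale = scale),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d proteins x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  timepoints: %s; replicates: %s; missing cells: %d\n",
              paste(sort(unique(x$design$timepoint)), collapse = ","),
              paste(sort(unique(x$design$replicate)), collapse = ","),
              sum(!is.finite(x$values))))
  invisible(x)
}

#' Read a protein-by-sample intensity table with its design
#'
#' The intensity TSV has a protein-id first column and one column per sample;
#' the design TSV has columns `sample_id`, `timepoint`, `replicate` and
#' optionally `batch`. Cells equal to `missing_sentinel` (default 0, the
#' MaxQuant convention for unquantified reporter intensities) and empty/NA
#' cells are recorded as missing.
#'
#' @param path Intensity TSV path.
#' @param design_path Design TSV path.
#' @param missing_sentinel Numeric sentinel treated as missing, or `NULL` to
#'   disable.
#' @return An [intensity_matrix()] on the raw scale.
#' @export
read_intensity_table <- function(path, design_path, missing_sentinel = 0) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    abort_sp("intensity table needs a protein id column plus >= 1 sample column",
             "settleprot_io_error")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort_sp(paste0("duplicate protein id(s) in ", path, ": ",
                    paste(dup, collapse = ", ")), "settleprot_io_error")
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  design <- read_sample_design(design_path)
  orphan <- setdiff(colnames(vals), design$sample_id)
  if (length(orphan) > 0)
    abort_sp(paste0("sample(s) in data absent from design: ",
                    paste(orphan, collapse = ", ")), "settleprot_io_error")
  design <- design[design$sample_id %in% colnames(vals), , drop = FALSE]
  if (!is.null(missing_sentinel))
    vals[!is.na(vals) & vals == missing_sentinel] <- NA_real_
  intensity_matrix(vals, design, scale = "raw")
}

#' Read a sample design TSV
#' @param path Design TSV path.
#' @return A [sample_design()] data frame.
#' @export
read_sample_design <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  sample_design(df)
}

#' Write an intensity matrix (and optionally its design) to TSV
#' @param m An [intensity_matrix()].
#' @param path Output TSV for the values.
#' @param design_path Optional output TSV for the design.
#' @param missing_sentinel Value written for missing cells (default 0).
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(m, path, design_path = NULL,
                                  missing_sentinel = 0) {
  stopifnot(inherits(m, "intensity_matrix"))
  vals <- m$values
  if (!is.null(missing_sentinel)) vals[!is.finite(vals)] <- missing_sentinel
  df <- data.frame(protein_id = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_sp(df, path)
  if (!is.null(design_path)) write_tsv_sp(as.data.frame(m$design), design_path)
  invisible(path)
}

.HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore")
.HIT_NUM <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
              "sstart", "send", "evalue", "bitscore")

#' Construct a homology hit table
#'
#' Standard 12-column tabular homology-search rows ("outfmt 6" dialect),
#' optionally carrying a resolved `taxon_class` per subject.
#'
#' @param df Data frame with the 12 standard columns (and optionally
#'   `taxon_class`).
#' @return A `hit_table` data frame.
#' @export
hit_table <- function(df) {
  miss <- setdiff(.HIT_COLS, names(df))
  if (length(miss) > 0)
    abort_sp(paste0("hit table missing column(s): ", paste(miss, collapse = ", ")),
             "settleprot_io_error")
  for (cc in .HIT_NUM) df[[cc]] <- as.numeric(df[[cc]])
  df$qseqid <- as.character(df$qseqid)
  df$sseqid <- as.character(df$sseqid)
  bad <- !is.finite(df$bitscore) | !is.finite(df$evalue)
  if (any(bad))
    abort_sp(paste0("non-numeric bitscore/evalue in hit row(s): ",
                    paste(which(bad), collapse = ", ")), "settleprot_io_error")
  if (any(df$evalue < 0))
    abort_sp("negative e-value in hit table", "settleprot_io_error")
  if (any(df$pident < 0 | df$pident > 100, na.rm = TRUE))
    abort_sp("percent identity outside [0, 100]", "settleprot_io_error")
  class(df) <- unique(c("hit_table", class(df)))
  df
}

#' Read a 12-column tabular homology-search file
#'
#' @param path Tabular file, no header, 12 tab-separated columns per row.
#' @param taxon_map Optional subject-to-taxon-class map: a named character
#'   vector or a 2-column data frame (`sseqid`, `taxon_class`).
#' @param unmapped Policy for subjects absent from `taxon_map`: `"drop"`
#'   (default; dropped with a warning), `"keep"` (class `NA`) or `"error"`.
#' @return A [hit_table()]; with `taxon_class` resolved when a map is given.
#' @export
read_hit_table <- function(path, taxon_map = NULL,
                           unmapped = c("drop", "keep", "error")) {
  unmapped <- match.arg(unmapped)
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#", quote = "")
  if (length(nf) > 0 && any(nf != 12)) {
    bad <- which(nf != 12)[1]
    abort_sp(sprintf("malformed hit row at line %d: %d column(s), expected 12",
                     bad, nf[bad]), "settleprot_io_error")
  }
  if (length(nf) == 0) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), 12), .HIT_COLS))
  } else {
    df <- utils::read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                            quote = "", colClasses = "character",
                            col.names = .HIT_COLS, stringsAsFactors = FALSE)
  }
  for (cc in .HIT_NUM) {
    conv <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(conv) & !is.na(df[[cc]]))
    if (length(bad) > 0)
      abort_sp(sprintf("malformed hit row at line %d: non-numeric %s '%s'",
                       bad[1], cc, df[[cc]][bad[1]]), "settleprot_io_error")
    df[[cc]] <- conv
  }
  df <- hit_table(df)
  if (!is.null(taxon_map)) df <- resolve_taxon_class(df, taxon_map, unmapped)
  df
}

resolve_taxon_class <- function(hits, taxon_map, unmapped = "drop") {
  if (is.data.frame(taxon_map)) {
    tm <- stats::setNames(as.character(taxon_map[[2]]),
                          as.character(taxon_map[[1]]))
  } else tm <- taxon_map
  cls <- unname(tm[hits$sseqid])
  n_unmapped <- sum(is.na(cls) & !is.na(hits$sseqid))
  if (n_unmapped > 0) {
    if (unmapped == "error")
      abort_sp(paste0(n_unmapped, " hit subject(s) missing from taxon map"),
               "settleprot_io_error")
    if (unmapped == "drop") {
      warn_sp(paste0("dropped ", n_unmapped, " hit(s) with unmapped subjects"))
      hits <- hits[!is.na(cls), , drop = FALSE]
      cls <- cls[!is.na(cls)]
    }
  }
  hits$taxon_class <- cls
  hits
}

#' Write a hit table in 12-column tabular format
#' @param hits A [hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, .HIT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an orthogroup membership table
#'
#' Wide TSV in the Orthogroups.tsv dialect: one row per orthogroup, first
#' column the orthogroup id, one column per genome, cells holding
#' comma-separated member ids (possibly empty). Every genome column must be
#' labeled by lineage.
#'
#' @param path Orthogroups TSV path.
#' @param genome_lineages Named character vector mapping each genome column to
#'   `"labyrinthulomycota"` or `"other"` (or a 2-column data frame).
#' @return An `orthogroup_table`: orthogroup ids, per-genome copy counts,
#'   member lists, and lineage labels.
#' @export
read_orthogroups <- function(path, genome_lineages) {
  if (is.data.frame(genome_lineages))
    genome_lineages <- stats::setNames(as.character(genome_lineages[[2]]),
                                       as.character(genome_lineages[[1]]))
  if (length(readLines(path, n = 1)) == 0)
    return(orthogroup_table(character(0), names(genome_lineages),
                            genome_lineages, list()))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  genomes <- colnames(tab)[-1]
  unlabeled <- setdiff(genomes, names(genome_lineages))
  if (length(unlabeled) > 0)
    abort_sp(paste0("genome column(s) without lineage label: ",
                    paste(unlabeled, collapse = ", ")), "settleprot_io_error")
  og_ids <- as.character(tab[[1]])
  members <- lapply(seq_len(nrow(tab)), function(i) {
    row <- lapply(genomes, function(g) {
      cell <- tab[[g]][i]
      if (is.na(cell) || !nzchar(trimws(cell))) character(0)
      else trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
    })
    names(row) <- genomes
    row
  })
  names(members) <- og_ids
  orthogroup_table(og_ids, genomes, genome_lineages[genomes], members)
}

#' Construct an orthogroup table from member lists
#' @param og_ids Character orthogroup ids.
#' @param genomes Character genome names.
#' @param lineages Named lineage labels for `genomes`.
#' @param members List (per orthogroup) of named lists (per genome) of member
#'   ids.
#' @return An `orthogroup_table` object.
#' @export
orthogroup_table <- function(og_ids, genomes, lineages, members) {
  if (anyDuplicated(og_ids))
    abort_sp("duplicate orthogroup ids", "settleprot_io_error")
  counts <- matrix(0L, nrow = length(og_ids), ncol = length(genomes),
                   dimnames = list(og_ids, genomes))
  for (i in seq_along(og_ids))
    counts[i, ] <- vapply(members[[i]], length, integer(1))[genomes]
  all_members <- unlist(members, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    dup <- unique(all_members[duplicated(all_members)])
    abort_sp(paste0("member id(s) present in more than one orthogroup: ",
                    paste(utils::head(dup, 5), collapse = ", ")),
             "settleprot_io_error")
  }
  structure(list(og_ids = og_ids, genomes = genomes,
                 lineages = unname(lineages[genomes]),
                 counts = counts, members = members),
            class = "orthogroup_table")
}

#' Write an orthogroup table in the wide TSV dialect
#' @param og An `orthogroup_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(og, path) {
  stopifnot(inherits(og, "orthogroup_table"))
  cells <- vapply(og$members, function(row)
    vapply(row[og$genomes], paste, character(1), collapse = ","),
    character(length(og$genomes)))
  if (length(og$og_ids) == 1L) cells <- matrix(cells, ncol = 1)
  df <- data.frame(Orthogroup = og$og_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (length(og$og_ids) > 0) {
    m <- t(cells)
    colnames(m) <- og$genomes
    df <- cbind(df, as.data.frame(m, stringsAsFactors = FALSE))
  } else {
    for (g in og$genomes) df[[g]] <- character(0)
  }
  write_tsv_sp(df, path)
  invisible(path)
}

#' Construct an annotation map (term -> protein-id sets)
#'
#' @param terms Named list: term id -> character vector of protein ids.
#' @param namespace One of `"KOG_class"`, `"ko_group"`, `"GO_term"`, `"pfam"`,
#'   `"custom"`.
#' @param labels Optional named character vector of human-readable term labels.
#' @return An `annotation_map` object.
#' @export
annotation_map <- function(terms, namespace = c("KOG_class", "ko_group",
                                                "GO_term", "pfam", "custom"),
                           labels = NULL) {
  namespace <- match.arg(namespace)
  if (length(terms) > 0 && (is.null(names(terms)) || any(!nzchar(names(terms)))))
    abort_sp("annotation terms must be named", "settleprot_io_error")
  empty <- vapply(terms, length, integer(1)) == 0
  if (any(empty))
    abort_sp(paste0("empty annotation term(s): ",
                    paste(names(terms)[empty], collapse = ", ")),
             "settleprot_io_error")
  terms <- lapply(terms, function(v) unique(as.character(v)))
  structure(list(namespace = namespace, terms = terms,
                 labels = labels %||% stats::setNames(names(terms), names(terms))),
            class = "annotation_map")
}

#' Read a 2-column protein-to-term annotation TSV
#' @param path TSV with header columns `protein_id`, `term`.
#' @param namespace Annotation namespace tag (see [annotation_map()]).
#' @return An [annotation_map()].
#' @export
read_annotation_map <- function(path, namespace = "custom") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    abort_sp("annotation map needs 2 columns (protein_id, term)",
             "settleprot_io_error")
  terms <- split(as.character(df[[1]]), as.character(df[[2]]))
  annotation_map(terms, namespace)
}

#' Write an annotation map as a 2-column TSV
#' @param ann An [annotation_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_map <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_map"))
  df <- data.frame(
    protein_id = unlist(ann$terms, use.names = FALSE),
    term = rep(names(ann$terms), vapply(ann$terms, length, integer(1))),
    stringsAsFactors = FALSE
  )
  write_tsv_sp(df, path)
  invisible(path)
}
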