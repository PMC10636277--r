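# Reading and filtering VDJdb-dialect TCR-epitope tables.
#
# Records are held as a plain data.frame with canonical column names
# (cdr3, chain, v_gene, j_gene, mhc_a, mhc_b, mhc_class, host_species,
# epitope_seq, epitope_gene, epitope_species, confidence_score) plus a
# stable integer record_id. All downstream modules consume this layout.

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

CANONICAL_FIELDS <- c(
  "cdr3", "chain", "v_gene", "j_gene", "mhc_a", "mhc_b", "mhc_class",
  "host_species", "epitope_seq", "epitope_gene", "epitope_species",
  "confidence_score"
)

MANDATORY_FIELDS <- c(
  "cdr3", "v_gene", "j_gene", "epitope_seq", "epitope_gene",
  "epitope_species", "confidence_score"
)

#' Default VDJdb web-export column mapping
#'
#' Maps the canonical record fields onto the headers of a VDJdb web export.
#' Override individual entries to ingest other dialects.
#'
#' @return Named character vector: canonical field -> source column header.
#' @export
vdjdb_column_map <- function() {
  c(
    cdr3 = "cdr3",
    chain = "gene",
    v_gene = "v.segm",
    j_gene = "j.segm",
    mhc_a = "mhc.a",
    mhc_b = "mhc.b",
    mhc_class = "mhc.class",
    host_species = "species",
    epitope_seq = "antigen.epitope",
    epitope_gene = "antigen.gene",
    epitope_species = "antigen.species",
    confidence_score = "vdjdb.score"
  )
}

is_valid_cdr3 <- function(x) {
  nzchar(x) & !is.na(x) & grepl(paste0("^[", paste(AMINO_ACIDS, collapse = ""), "]+$"), x)
}

#' Read a VDJdb-dialect tab-separated table
#'
#' Parses a tab-separated export with a header row into the canonical record
#' layout. Rows whose confidence score cannot be parsed as an integer in
#' 0..3, or whose CDR3 contains characters outside the 20-letter amino-acid
#' alphabet, are diverted to a record-level error table instead of aborting
#' the read.
#'
#' @param source Path to a tab-separated file (or a connection).
#' @param column_map Named character vector mapping canonical fields to
#'   source headers; see [vdjdb_column_map()]. Fields absent from the map or
#'   the file are filled with `NA` unless mandatory.
#' @return List with elements `records` (data.frame, one row per clean data
#'   row, with `record_id`) and `errors` (data.frame with `row`, `reason`).
#' @export
read_vdjdb_table <- function(source, column_map = vdjdb_column_map()) {
  raw <- read.delim(source, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE)
  mandatory_src <- column_map[intersect(MANDATORY_FIELDS, names(column_map))]
  missing_mandatory <- MANDATORY_FIELDS[
    !(MANDATORY_FIELDS %in% names(column_map)) |
      !(column_map[MANDATORY_FIELDS] %in% names(raw))
  ]
  if (length(missing_mandatory) > 0) {
    stop("missing mandatory column(s): ",
         paste(sprintf("%s (expected header '%s')", missing_mandatory,
                       ifelse(missing_mandatory %in% names(column_map),
                              column_map[missing_mandatory], "<unmapped>")),
               collapse = ", "), call. = FALSE)
  }

  n <- nrow(raw)
  rec <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    matrix(NA_character_, nrow = n, ncol = 0))
  for (f in CANONICAL_FIELDS) {
    src <- if (f %in% names(column_map)) column_map[[f]] else NA_character_
    rec[[f]] <- if (!is.na(src) && src %in% names(raw)) raw[[src]] else rep(NA_character_, n)
  }
  if (n == 0) {
    rec$confidence_score <- integer(0)
    rec$record_id <- integer(0)
    return(list(records = rec,
                errors = data.frame(row = integer(0), reason = character(0),
                                    stringsAsFactors = FALSE)))
  }

  score_chr <- trimws(rec$confidence_score)
  score <- suppressWarnings(as.integer(score_chr))
  bad_score <- !is.na(score_chr) & nzchar(score_chr) &
    (is.na(score) | score < 0L | score > 3L | as.character(score) != score_chr)
  bad_cdr3 <- !is.na(rec$cdr3) & nzchar(rec$cdr3) & !is_valid_cdr3(rec$cdr3)

  reasons <- character(n)
  reasons[bad_cdr3] <- "cdr3 outside the 20-letter amino-acid alphabet"
  reasons[bad_score] <- paste0("unparseable confidence score '",
                               score_chr[bad_score], "'")
  bad <- bad_score | bad_cdr3
  errors <- data.frame(row = which(bad), reason = reasons[bad],
                       stringsAsFactors = FALSE)

  rec$confidence_score <- score
  rec <- rec[!bad, , drop = FALSE]
  rec$record_id <- which(!bad)
  rownames(rec) <- NULL
  list(records = rec, errors = errors)
}

#' Filter-cascade configuration
#'
#' @param host_allowlist Host species retained (human and murine by default).
#' @param epitope_species_denylist Epitope (antigen) species removed as
#'   non-infectious origins: self antigens (autoimmune disorders, cancer),
#'   synthetic constructs, bacterial antigens and allergens. VDJdb does not
#'   fix this set, so the default is a documented starting point and should
#'   be adapted to the database snapshot in use.
#' @param min_score Exclusive lower bound on the confidence score; the
#'   default keeps only wet-lab-validated pairs (score > 0).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(host_allowlist = c("HomoSapiens", "MusMusculus"),
                          epitope_species_denylist = c(
                            "HomoSapiens", "MusMusculus",
                            "synthetic", "Synthetic",
                            "MycobacteriumTuberculosis",
                            "TriticumAestivum", "PhlPratense"
                          ),
                          min_score = 0L) {
  structure(list(host_allowlist = host_allowlist,
                 epitope_species_denylist = epitope_species_denylist,
                 min_score = min_score),
            class = "filter_config")
}

missing_mandatory_mask <- function(records) {
  bad <- rep(FALSE, nrow(records))
  for (f in MANDATORY_FIELDS) {
    v <- records[[f]]
    bad <- bad | is.na(v) | (is.character(v) & !nzchar(v))
  }
  bad
}

#' Apply the VDJdb filter cascade
#'
#' Applies, in order: removal of rows with missing mandatory values,
#' host-species allowlist, confidence score above the bound, epitope-species
#' denylist, deduplication on (CDR3, V, J, MHC A, MHC B), and the TRB chain
#' restriction. A per-step accounting report is returned alongside the
#' retained records.
#'
#' @param records Canonical records data.frame (see [read_vdjdb_table()]).
#' @param config A [filter_config()].
#' @return List with `records` (retained rows) and `report` (a
#'   `filter_report`: data.frame of `step`, `remaining`).
#' @export
apply_filters <- function(records, config = filter_config()) {
  steps <- character(0)
  remaining <- integer(0)
  note <- function(name, df) {
    steps <<- c(steps, name)
    remaining <<- c(remaining, nrow(df))
    df
  }
  r <- note("raw", records)
  r <- note("remove_missing", r[!missing_mandatory_mask(r), , drop = FALSE])
  r <- note("host_species",
            r[r$host_species %in% config$host_allowlist, , drop = FALSE])
  r <- note("confidence_score",
            r[r$confidence_score > config$min_score, , drop = FALSE])
  r <- note("epitope_species_denylist",
            r[!(r$epitope_species %in% config$epitope_species_denylist), ,
              drop = FALSE])
  r <- note("deduplicate", deduplicate(r))
  r <- note("trb_chain", r[r$chain %in% "TRB", , drop = FALSE])
  rownames(r) <- NULL
  report <- structure(
    data.frame(step = steps, remaining = remaining, stringsAsFactors = FALSE),
    class = c("filter_report", "data.frame")
  )
  list(records = r, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter cascade accounting:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Deduplicate records on the (CDR3, V, J, MHC A, MHC B) key
#'
#' Keeps the first occurrence, in input order, of each duplicated key;
#' idempotent by construction.
#'
#' @param records Canonical records data.frame.
#' @return The deduplicated data.frame, input order preserved.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0) return(records)
  key <- paste(records$cdr3, records$v_gene, records$j_gene,
               records$mhc_a, records$mhc_b, sep = "\r")
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign composite epitope class labels
#'
#' The class label of a record is the space-joined triple
#' (epitope species, epitope parent gene, epitope sequence), e.g.
#' `"MCMV m139 TVYGFCLL"`. Records with an empty epitope field are diverted
#' to the error table.
#'
#' @param records Canonical records data.frame.
#' @return List with `records` (with a `class_label` column added) and
#'   `errors` (data.frame of `record_id`, `reason`).
#' @export
assign_class_labels <- function(records) {
  fields <- c("epitope_species", "epitope_gene", "epitope_seq")
  bad <- rep(FALSE, nrow(records))
  for (f in fields) bad <- bad | is.na(records[[f]]) | !nzchar(records[[f]])
  errors <- data.frame(
    record_id = if (nrow(records)) records$record_id[bad] else integer(0),
    reason = rep("empty epitope field", sum(bad)),
    stringsAsFactors = FALSE
  )
  out <- records[!bad, , drop = FALSE]
  out$class_label <- paste(out$epitope_species, out$epitope_gene,
                           out$epitope_seq)
  rownames(out) <- NULL
  list(records = out, errors = errors)
}

#' Drop classes below a minimum size
#'
#' Classes with fewer than `min_n` members (counted after all earlier
#' filters) are removed; the bound is inclusive, so a class of exactly
#' `min_n` survives.
#'
#' @param records Labelled records (with `class_label`).
#' @param min_n Minimum class size (default 50).
#' @return Filtered records data.frame.
#' @export
min_class_size_filter <- function(records, min_n = 50L) {
  counts <- table(records$class_label)
  keep <- names(counts)[counts >= min_n]
  out <- records[records$class_label %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Categorize classes by training difficulty
#'
#' Classes with more than 100 instances are "easy-to-classify"; all others
#' (including exactly 100) are "hard-to-classify".
#'
#' @param class_counts Named integer vector of per-class counts.
#' @return Named character vector with values `"easy"` / `"hard"`.
#' @export
categorize_difficulty <- function(class_counts) {
  stopifnot(all(class_counts > 0))
  setNames(ifelse(class_counts > 100, "easy", "hard"), names(class_counts))
}

#' Deterministic partition sizes under the floor rule
#'
#' For `n` items and fractions (train, validation, test), train receives
#' `floor(f_train * n)`, validation `floor(f_val * n)`, and test the
#' remainder.
#'
#' @param n Number of items.
#' @param fractions Numeric length-3 vector summing to 1.
#' @return Named integer vector (train, validation, test).
#' @export
partition_sizes <- function(n, fractions = c(train = 0.70, validation = 0.15,
                                             test = 0.15)) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  n_train <- floor(fractions[[1]] * n)
  n_val <- floor(fractions[[2]] * n)
  c(train = n_train, validation = n_val, test = n - n_train - n_val)
}

#' Stratified train/validation/test split
#'
#' Within every class, membership is shuffled with a seeded RNG and assigned
#' to partitions by the floor rule of [partition_sizes()] (remainders go to
#' test). Classes are visited in sorted label order so a fixed seed yields an
#' identical assignment regardless of input row order within the class
#' grouping.
#'
#' @param records Labelled records (with `class_label` and `record_id`).
#' @param fractions Length-3 fractions (train, validation, test).
#' @param seed Integer seed.
#' @return Object of class `split_assignment`: list with `partition`
#'   (data.frame `record_id`, `class_label`, `partition`), `fractions`,
#'   `seed`.
#' @export
stratified_split <- function(records,
                             fractions = c(train = 0.70, validation = 0.15,
                                           test = 0.15),
                             seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  counts <- table(records$class_label)
  too_small <- names(counts)[counts < 3]
  if (length(too_small) > 0) {
    stop("class(es) with fewer than 3 members cannot be split: ",
         paste(too_small, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  part <- character(nrow(records))
  for (cl in sort(names(counts))) {
    idx <- which(records$class_label == cl)
    idx <- idx[sample.int(length(idx))]
    sizes <- partition_sizes(length(idx), fractions)
    lab <- rep(c("train", "validation", "test"), times = sizes)
    part[idx] <- lab
  }
  structure(
    list(
      partition = data.frame(record_id = records$record_id,
                             class_label = records$class_label,
                             partition = part, stringsAsFactors = FALSE),
      fractions = fractions,
      seed = seed
    ),
    class = "split_assignment"
  )
}

#' Build an ordinal gene vocabulary
#'
#' Unique gene names are sorted lexicographically and assigned ordinals
#' 1..n; index 0 is reserved for padding ("no gene") and the last slot
#' (n + 1) for a special/unknown token, giving an embedding table size of
#' n + 2.
#'
#' @param records Canonical records data.frame (or a character vector of
#'   gene names).
#' @param field `"v_gene"` or `"j_gene"` (ignored when `records` is already
#'   a character vector).
#' @return Object of class `gene_vocabulary`.
#' @export
build_gene_vocabulary <- function(records, field = c("v_gene", "j_gene")) {
  if (is.character(records)) {
    values <- records
  } else {
    field <- match.arg(field)
    values <- records[[field]]
  }
  stopifnot(all(!is.na(values) & nzchar(values)))
  names_sorted <- sort(unique(values))
  n <- length(names_sorted)
  structure(
    list(
      names = names_sorted,
      index_of = setNames(seq_len(n), names_sorted),
      padding_index = 0L,
      special_index = n + 1L,
      table_size = n + 2L
    ),
    class = "gene_vocabulary"
  )
}

#' Encode gene names to ordinals
#'
#' Unknown names map to the vocabulary's special index so the padding index
#' keeps its "no gene" meaning.
#'
#' @param vocab A [build_gene_vocabulary()] result.
#' @param names Character vector of gene names.
#' @return Integer ordinals.
#' @export
encode_genes <- function(vocab, names) {
  idx <- vocab$index_of[names]
  idx[is.na(idx)] <- vocab$special_index
  as.integer(unname(idx))
}

#' Decode gene ordinals back to names
#'
#' @param vocab A [build_gene_vocabulary()] result.
#' @param ordinals Integer ordinals in 1..n (padding and special indices
#'   decode to `"<pad>"` / `"<unk>"`).
#' @return Character vector of names.
#' @export
decode_genes <- function(vocab, ordinals) {
  out <- rep("<unk>", length(ordinals))
  out[ordinals == vocab$padding_index] <- "<pad>"
  in_range <- ordinals >= 1 & ordinals <= length(vocab$names)
  out[in_range] <- vocab$names[ordinals[in_range]]
  out
}

#' Write records back out in the VDJdb dialect
#'
#' @param records Canonical records data.frame.
#' @param path Output path.
#' @param column_map Canonical field -> output header mapping.
#' @export
write_vdjdb_table <- function(records, path, column_map = vdjdb_column_map()) {
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    matrix(nrow = nrow(records), ncol = 0))
  for (f in names(column_map)) out[[column_map[[f]]]] <- records[[f]]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize preprocessing artifacts as JSON
#'
#' @param x A `filter_report`, `split_assignment` or `gene_vocabulary`.
#' @param path Output path.
#' @export
write_json_artifact <- function(x, path) {
  if (inherits(x, "split_assignment")) {
    x <- list(partition = setNames(as.list(x$partition$partition),
                                   x$partition$record_id),
              fractions = x$fractions, seed = x$seed)
  } else if (inherits(x, "gene_vocabulary")) {
    x <- unclass(x)
    x$index_of <- as.list(x$index_of)
  } else if (inherits(x, "filter_report")) {
    x <- list(steps = as.list(setNames(x$remaining, x$step)))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
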