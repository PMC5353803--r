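# FASTA / taxonomy / results I/O and the model archive.

#' Read a multi-record FASTA file into a tibble
#'
#' Record IDs are the first whitespace-delimited token of the header line;
#' wrapped and unwrapped sequence lines are both accepted.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  x <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("failed to parse FASTA file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(x) == 0L) {
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(x))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA IDs: ", paste(utils::head(dup, 10L), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(id = ids, sequence = unname(as.character(x)))
}

#' Write sequences to an unwrapped FASTA file
#'
#' @param data A data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path) {
  stopifnot(all(c("id", "sequence") %in% names(data)))
  x <- Biostrings::BStringSet(stats::setNames(data$sequence, data$id))
  Biostrings::writeXStringSet(x, path, width = max(nchar(data$sequence), 1L))
  invisible(path)
}

#' Read a taxonomy table
#'
#' A TSV with a header whose first two columns are `sequence_id` and
#' `genus`; extra lineage columns are carried along untouched.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with at least `sequence_id` and `genus` columns.
#' @export
read_taxonomy <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("sequence_id", "genus") %in% names(tab))) {
    stop("taxonomy table must have columns 'sequence_id' and 'genus'",
         call. = FALSE)
  }
  .check_taxonomy(tab)
  tab
}

.check_taxonomy <- function(tab) {
  dup <- unique(tab$sequence_id[duplicated(tab$sequence_id)])
  if (length(dup) > 0L) {
    stop("duplicate sequence_ids in taxonomy: ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(tab$genus) | !nzchar(tab$genus))) {
    stop("taxonomy contains empty genus names", call. = FALSE)
  }
  if (any(grepl("\t", tab$genus, fixed = TRUE))) {
    stop("genus names must not contain tab characters", call. = FALSE)
  }
  invisible(tab)
}

# join a (id, sequence) table with a (sequence_id, genus) table, erroring
# on IDs without a label
.join_taxonomy <- function(data, taxonomy) {
  .check_taxonomy(taxonomy)
  miss <- setdiff(data$id, taxonomy$sequence_id)
  if (length(miss) > 0L) {
    stop("sequences without a taxonomy label: ",
         paste(utils::head(miss, 10L), collapse = ", "),
         if (length(miss) > 10L) sprintf(" (and %d more)", length(miss) - 10L),
         call. = FALSE)
  }
  keep <- c("sequence_id", "genus", intersect("group", names(taxonomy)))
  dplyr::inner_join(data, taxonomy[keep],
                    by = c(id = "sequence_id"))
}

#' Write classification records to a TSV file
#'
#' Column order is fixed: `query_id`, `taxon`, `d_score`, `r_score`,
#' `r_probability`, `flags`; missing values are written as `NA`. Provenance
#' (seeds, parameters) can be echoed as leading `#` comment lines.
#'
#' @param records A tibble from [classify_with_uncertainty()].
#' @param path Output path.
#' @param comments Optional character vector written as `#`-prefixed
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, comments = NULL) {
  cols <- c("query_id", "taxon", "d_score", "r_score", "r_probability", "flags")
  stopifnot(all(cols %in% names(records)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments) > 0L) {
    writeLines(paste0("# ", comments), con)
  }
  out <- records[cols]
  writeLines(paste(cols, collapse = "\t"), con)
  lines <- apply(out, 1L, function(row) {
    row[is.na(row)] <- "NA"
    paste(row, collapse = "\t")
  })
  if (length(lines) > 0L) writeLines(lines, con)
  invisible(path)
}

#' Save a fitted model to a versioned archive
#'
#' Round-trips bit-exactly: the same object always serializes to the same
#' bytes. Works for [train_multinomial()], [build_taxmachine()] and
#' [train_rdp()] objects.
#'
#' @param model A fitted model object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  archive <- list(format_version = "microtax/1", model = model)
  saveRDS(archive, path, version = 3L)
  invisible(path)
}

#' Load a model archive written by [save_model()]
#'
#' @param path Path to the archive.
#' @return The model object.
#' @export
load_model <- function(path) {
  archive <- readRDS(path)
  if (!is.list(archive) || !identical(archive$format_version, "microtax/1")) {
    stop("'", path, "' is not a microtax model archive", call. = FALSE)
  }
  archive$model
}
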