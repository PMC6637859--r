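#' Gene-set collection
#'
#' A list of term records, each with `term_id`, `term_name`, `namespace`
#' (one of BP, MF, CC, HP, other) and a non-empty, deduplicated character
#' vector `genes`.
#'
#' @param terms list of term records as described above.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(terms) {
  ids <- vapply(terms, `[[`, character(1), "term_id")
  if (anyDuplicated(ids)) stop("duplicate term_id in collection")
  terms <- lapply(terms, function(tm) {
    tm$genes <- unique(as.character(tm$genes))
    if (length(tm$genes) == 0) stop("term ", tm$term_id, " has no genes")
    if (is.null(tm$namespace) ||
        !tm$namespace %in% c("BP", "MF", "CC", "HP", "other"))
      tm$namespace <- "other"
    tm
  })
  names(terms) <- ids
  structure(terms, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  ns <- table(vapply(x, `[[`, character(1), "namespace"))
  cat(sprintf("gene_set_collection: %d terms (%s)\n", length(x),
              paste(names(ns), ns, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Read a gene-set collection from GMT
#'
#' One term per tab-separated line: id, description, member genes.
#' GMT has no namespace slot; an optional leading `ns=XX` token in the
#' description field (e.g. `"ns=BP protein transport"`) is parsed as the
#' namespace, defaulting to `"other"`. Duplicate genes within a line are
#' stored once.
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(list()))
  }
  terms <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    desc <- f[2]
    ns <- "other"
    if (grepl("^ns=", desc)) {
      ns <- sub("^ns=(\\S+).*$", "\\1", desc)
      desc <- sub("^ns=\\S+\\s*", "", desc)
      if (!ns %in% c("BP", "MF", "CC", "HP")) ns <- "other"
    }
    list(term_id = f[1], term_name = desc, namespace = ns,
         genes = unique(f[-(1:2)]))
  })
  gene_set_collection(terms)
}

#' Write a gene-set collection to GMT
#'
#' The namespace is encoded as a leading `ns=XX` token in the description
#' field so that [read_gmt()] round-trips it.
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection, function(tm) {
    paste(c(tm$term_id, paste0("ns=", tm$namespace, " ", tm$term_name),
            tm$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an intensity table to TSV
#'
#' Layout: a metadata comment line (`# state=<state> log2=<0|1>`), then a
#' header and one row per probe with columns `probe_id`, `gene_symbol`,
#' `is_control`, followed by one column per sample. Values are written at
#' full double precision.
#'
#' @param table an [intensity_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(table, path) {
  stopifnot(inherits(table, "intensity_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# state=%s log2=%d", table$state,
                     as.integer(table$log2)), con)
  df <- data.frame(probe_id = table$probe_id,
                   gene_symbol = table$gene_symbol,
                   is_control = as.integer(table$is_control),
                   stringsAsFactors = FALSE)
  vals <- format(table$values, digits = 17, trim = TRUE, scientific = FALSE)
  df <- cbind(df, as.data.frame(vals, stringsAsFactors = FALSE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an intensity table from TSV
#'
#' Expects the layout written by [write_expression_tsv()]; the state is
#' taken from the metadata comment line when present, else from `state`.
#'
#' @param path input path.
#' @param state fallback processing state when no metadata line is present.
#' @return an [intensity_table()].
#' @export
read_expression_tsv <- function(path, state = "raw") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  log2 <- FALSE
  skip <- 0L
  if (grepl("^#", first)) {
    skip <- 1L
    m <- regmatches(first, regexec("state=(\\S+)", first))[[1]]
    if (length(m) == 2) state <- m[2]
    m <- regmatches(first, regexec("log2=(\\d)", first))[[1]]
    if (length(m) == 2) log2 <- m[2] == "1"
  }
  df <- utils::read.delim(path, skip = skip, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probe_id", "gene_symbol", "is_control")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parse error: missing column(s) ", paste(miss, collapse = ", "))
  sample_cols <- setdiff(names(df), need)
  if (length(sample_cols) == 0) stop("parse error: no sample columns")
  vals <- as.matrix(df[sample_cols])
  if (!is.numeric(vals)) {
    bad <- sample_cols[!vapply(df[sample_cols], is.numeric, logical(1))][1L]
    stop("parse error: non-numeric cell in sample column '", bad, "'")
  }
  colnames(vals) <- sample_cols
  intensity_table(vals, df$probe_id, df$gene_symbol,
                  as.logical(df$is_control), state = state, log2 = log2)
}

#' Read a sample-to-group design table
#'
#' TSV with columns `sample_id` and `group`. Group levels keep their order
#' of first appearance.
#'
#' @param path input path.
#' @return data.frame with columns `sample_id`, `group` and attribute
#'   `group_levels`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("parse error: design needs columns sample_id and group")
  validate_design(df)
}

#' Validate a design table, optionally against an expression table
#'
#' Checks that every expression sample has exactly one group, that there
#' are at least two groups, and warns on single-sample groups and on design
#' rows naming unknown samples (which are dropped).
#'
#' @param design data.frame with `sample_id`, `group`.
#' @param table optional [intensity_table()] to cross-check samples against.
#' @return the validated (possibly subset) design data.frame.
#' @export
validate_design <- function(design, table = NULL) {
  if (anyDuplicated(design$sample_id))
    stop("validation error: duplicated sample_id in design")
  if (!is.null(table)) {
    missing <- setdiff(sample_ids(table), design$sample_id)
    if (length(missing))
      stop("validation error: sample(s) in expression but absent from design: ",
           paste(missing, collapse = ", "))
    extra <- setdiff(design$sample_id, sample_ids(table))
    if (length(extra)) {
      warning("design sample(s) not in expression ignored: ",
              paste(extra, collapse = ", "))
      design <- design[design$sample_id %in% sample_ids(table), ,
                       drop = FALSE]
    }
  }
  levels <- unique(design$group)
  if (length(levels) < 2) stop("validation error: need >= 2 groups")
  sizes <- table(design$group)
  if (any(sizes < 2))
    warning("group(s) with a single sample: ",
            paste(names(sizes)[sizes < 2], collapse = ", "),
            " (variance pooling across genes still possible)")
  attr(design, "group_levels") <- levels
  design
}

#' Write a design table to TSV
#' @param design data.frame with `sample_id`, `group`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(design[c("sample_id", "group")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results data.frame to TSV at full precision
#'
#' Columns are written in their given order; doubles keep full floating
#' precision so that written results are reproducible bit-for-bit.
#'
#' @param table a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- format(out[[j]], digits = 17, trim = TRUE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimal adapter for Agilent-style single-channel text exports
#'
#' Extracts probe id, gene symbol, control flag and one signal column from
#' a feature-extraction-style text export (tab-separated with a header
#' containing `ProbeName`, `GeneName`, `ControlType` and a signal column,
#' by default `gMeanSignal`). Convenience only; the pipeline's canonical
#' format is the TSV of [write_expression_tsv()].
#'
#' @param paths one file per sample.
#' @param sample_ids sample ids, one per file.
#' @param signal_column name of the signal column to extract.
#' @return an [intensity_table()] in raw state.
#' @export
read_agilent_txt <- function(paths, sample_ids = basename(paths),
                             signal_column = "gMeanSignal") {
  stopifnot(length(paths) == length(sample_ids))
  cols <- NULL
  meta <- NULL
  for (i in seq_along(paths)) {
    df <- utils::read.delim(paths[i], stringsAsFactors = FALSE)
    need <- c("ProbeName", "GeneName", "ControlType", signal_column)
    if (!all(need %in% names(df)))
      stop("parse error in ", paths[i], ": need columns ",
           paste(need, collapse = ", "))
    df <- df[!duplicated(df$ProbeName), ]
    df <- df[order(df$ProbeName), ]
    if (is.null(meta)) {
      meta <- df[c("ProbeName", "GeneName", "ControlType")]
      cols <- matrix(NA_real_, nrow(df), length(paths),
                     dimnames = list(NULL, sample_ids))
    } else if (!identical(df$ProbeName, meta$ProbeName)) {
      stop("parse error: probe sets differ across files")
    }
    cols[, i] <- df[[signal_column]]
  }
  intensity_table(cols, meta$ProbeName, meta$GeneName,
                  meta$ControlType != 0, state = "raw")
}
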