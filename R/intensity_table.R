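#' Probe-by-sample intensity container
#'
#' The central data structure of the pipeline: a numeric probe x sample
#' matrix plus per-probe metadata (gene symbol, control flag) and a
#' processing-state marker that operations check and advance
#' (`raw` -> `background_corrected` -> `normalized` -> `collapsed`).
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#'   Column names are the sample ids.
#' @param probe_id character vector of unique probe identifiers.
#' @param gene_symbol character vector mapping each probe to a gene symbol
#'   (replicate probes of one gene share the symbol; controls may carry
#'   their own ids).
#' @param is_control logical vector flagging control probes.
#' @param state processing state, one of `"raw"`, `"background_corrected"`,
#'   `"normalized"`, `"collapsed"`.
#' @param log2 logical; whether `values` are on the log2 scale.
#'
#' @return An object of class `intensity_table`.
#' @export
intensity_table <- function(values, probe_id, gene_symbol, is_control,
                            state = c("raw", "background_corrected",
                                      "normalized", "collapsed"),
                            log2 = FALSE) {
  state <- match.arg(state)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("intensity values must be numeric")
  n <- nrow(values)
  probe_id <- as.character(probe_id)
  gene_symbol <- as.character(gene_symbol)
  is_control <- as.logical(is_control)
  if (length(probe_id) != n || length(gene_symbol) != n ||
      length(is_control) != n) {
    stop("probe metadata length does not match the number of rows")
  }
  if (anyDuplicated(probe_id)) {
    dup <- probe_id[duplicated(probe_id)][1L]
    stop("duplicate probe_id: ", dup)
  }
  if (is.null(colnames(values))) stop("sample (column) names are required")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(!is.finite(values))) stop("intensity values must be finite")
  if (state == "raw" && any(values <= 0)) {
    stop("raw intensities must be strictly positive")
  }
  rownames(values) <- probe_id
  structure(
    list(values = values, probe_id = probe_id, gene_symbol = gene_symbol,
         is_control = is_control, state = state, log2 = log2),
    class = "intensity_table"
  )
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf(
    "intensity_table: %d probes x %d samples [state: %s%s, %d controls]\n",
    nrow(x$values), ncol(x$values), x$state,
    if (x$log2) ", log2" else "", sum(x$is_control)))
  invisible(x)
}

#' @export
dim.intensity_table <- function(x) dim(x$values)

#' Sample ids of an intensity table
#' @param x an `intensity_table`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$values)

# internal: subset probes, keeping metadata aligned
subset_probes <- function(x, keep) {
  intensity_table(x$values[keep, , drop = FALSE],
                  x$probe_id[keep], x$gene_symbol[keep],
                  x$is_control[keep], state = x$state, log2 = x$log2)
}
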