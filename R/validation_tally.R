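#' Read a Sanger validation result table
#'
#' Reads a tab-separated table of per-variant validation assays and maps it
#' onto the internal record layout (variant identity, class label, assay
#' outcome). The column mapping is configurable so that differently laid-out
#' external spreadsheets can be adapted; rows whose outcome cannot be
#' interpreted are dropped with a message and reported in the
#' `n_unmapped` attribute.
#'
#' @param path Path to the TSV (header required).
#' @param col_map Named character vector mapping internal names
#'   (`chrom`, `pos`, `ref`, `alt`, `class`, `outcome`) to the file's column
#'   names.
#' @param outcome_map Named character vector translating the file's outcome
#'   vocabulary to `validated`, `invalidated`, `failed_assay`.
#' @return data.frame of class `validation_records` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `class`, `outcome`.
#' @export
read_validation_table <- function(path,
                                  col_map = c(chrom = "chrom", pos = "pos",
                                              ref = "ref", alt = "alt",
                                              class = "variant_class",
                                              outcome = "outcome"),
                                  outcome_map = c(validated = "validated",
                                                  invalidated = "invalidated",
                                                  failed_assay = "failed_assay",
                                                  confirmed = "validated",
                                                  rejected = "invalidated",
                                                  failed = "failed_assay")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(col_map), names(tab))
  if (length(missing_cols))
    stop("validation table lacks mapped columns: ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(chrom = as.character(tab[[col_map["chrom"]]]),
                    pos = as.integer(tab[[col_map["pos"]]]),
                    ref = tab[[col_map["ref"]]], alt = tab[[col_map["alt"]]],
                    class = tab[[col_map["class"]]],
                    outcome = unname(outcome_map[tolower(tab[[col_map["outcome"]]])]),
                    stringsAsFactors = FALSE)
  bad <- is.na(out$outcome)
  if (any(bad)) {
    message(sum(bad), " validation row(s) with unrecognised outcome dropped")
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, n_unmapped = sum(bad),
            class = c("validation_records", "data.frame"))
}

#' False discovery rate from validation tallies
#'
#' FDR per variant class = invalidated / conclusively assayed, where assays
#' that failed (no conclusive Sanger result) are excluded from the
#' denominator.
#'
#' @param records `validation_records` (or any data.frame with `class` and
#'   `outcome` columns).
#' @param class Optional character vector restricting to particular classes;
#'   default tallies every class present plus classes listed here.
#' @return data.frame with one row per class: `class`, `selected` (records of
#'   the class), `assayed` (conclusive), `invalidated`, `fdr`.
#' @export
tally_fdr <- function(records, class = NULL) {
  classes <- if (is.null(class)) sort(unique(records$class)) else class
  rows <- lapply(classes, function(cl) {
    r <- records[records$class == cl, , drop = FALSE]
    conclusive <- r$outcome %in% c("validated", "invalidated")
    assayed <- sum(conclusive)
    if (assayed == 0)
      stop("no conclusively assayed records in class '", cl, "'")
    inv <- sum(r$outcome == "invalidated")
    data.frame(class = cl, selected = nrow(r), assayed = assayed,
               invalidated = inv, fdr = inv / assayed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
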