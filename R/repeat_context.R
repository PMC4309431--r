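#' Extract the sequence window around an indel
#'
#' Returns the reference sequence `flank` bp upstream and downstream of the
#' indel's reference coordinates (clipped at contig ends) together with the
#' 1-based offset of the indel's anchor base within the window.
#'
#' @param reference A `Biostrings::DNAStringSet`, or a named character vector
#'   of contig sequences.
#' @param chrom Contig name.
#' @param pos 1-based position of the indel's anchor (padding) base, VCF
#'   convention.
#' @param ref_len Length of the REF allele (1 for insertions).
#' @param flank Flank length in bp (default 100).
#' @return A list: `window` (character), `offset` (position of `pos` within
#'   the window), `start` (1-based genomic start of the window).
#' @export
extract_context <- function(reference, chrom, pos, ref_len = 1, flank = 100) {
  if (inherits(reference, "DNAStringSet")) {
    if (!chrom %in% names(reference)) stop("contig not in reference: ", chrom)
    contig_len <- Biostrings::width(reference)[match(chrom, names(reference))]
  } else {
    if (!chrom %in% names(reference)) stop("contig not in reference: ", chrom)
    contig_len <- nchar(reference[[chrom]])
  }
  if (pos < 1 || pos + ref_len - 1 > contig_len)
    stop("position outside contig ", chrom, ": ", pos)
  a <- max(1, pos - flank)
  b <- min(contig_len, pos + ref_len - 1 + flank)
  window <- if (inherits(reference, "DNAStringSet")) {
    as.character(Biostrings::subseq(reference[[chrom]], a, b))
  } else {
    substr(reference[[chrom]], a, b)
  }
  list(window = toupper(window), offset = pos - a + 1L, start = a)
}

.min_rotation <- function(unit) {
  k <- nchar(unit)
  if (k == 1) return(unit)
  rot <- vapply(seq_len(k), function(i)
    paste0(substr(unit, i, k), substr(unit, 1, i - 1)), "")
  min(rot)
}

.min_period <- function(s) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  for (p in seq_len(n)) {
    if (n %% p == 0 && all(ch == ch[((seq_len(n) - 1) %% p) + 1])) return(p)
  }
  n
}

#' Find exact tandem repeat arrays in a sequence window
#'
#' Detects every maximal exact tandem array with unit length 1..`max_unit`:
#' mononucleotide runs of at least 6 bases, and arrays of a multi-base unit
#' repeated at least twice. Units are canonicalised to their lexicographically
#' minimal rotation; arrays whose unit is itself periodic are dropped in
#' favour of the shorter-unit array, and arrays fully contained in a longer
#' array with a shorter unit are suppressed. `N` bases never match.
#'
#' @param window Uppercase A/C/G/T/N sequence.
#' @param max_unit Largest unit length considered (default 50).
#' @return data.frame: `unit` (canonical rotation), `unit_len`, `copies`
#'   (full copies, floor of span/unit), `start`, `end` (1-based, inclusive,
#'   the maximal periodic span including any partial copy).
#' @export
find_tandem_repeats <- function(window, max_unit = 50) {
  s <- strsplit(toupper(window), "")[[1]]
  n <- length(s)
  res <- list()
  for (k in seq_len(min(max_unit, n %/% 2))) {
    m <- s[seq_len(n - k)] == s[seq_len(n - k) + k] & s[seq_len(n - k)] != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= k)) {
      a <- starts[j]; b <- ends[j] + k          # span of the periodic stretch
      L <- b - a + 1L
      copies <- L %/% k
      if (k == 1 && copies < 6) next
      if (k > 1 && copies < 2) next
      unit_raw <- paste(s[a:(a + k - 1)], collapse = "")
      if (.min_period(unit_raw) < k) next       # unit itself periodic
      res[[length(res) + 1]] <- data.frame(
        unit = .min_rotation(unit_raw), unit_len = k,
        copies = copies, start = a, end = b, stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(unit = character(0), unit_len = integer(0),
                      copies = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  # suppress arrays fully contained in a longer array with a shorter unit
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    cont <- out$start <= out$start[i] & out$end >= out$end[i] &
      out$unit_len < out$unit_len[i] &
      (out$end - out$start) >= (out$end[i] - out$start[i])
    if (any(cont)) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Canonical tandem-repeat copy-number threshold
#'
#' A tandem repeat with unit length u (u >= 2) is canonical when the unit
#' recurs at least `u * 2 + 5` times: 9 copies for a 2 bp unit, 11 for a
#' 3 bp unit, and so on. Mononucleotide runs are the homopolymer (HR) domain
#' and are not accepted here.
#'
#' @param unit_length Repeat unit length in bp, at least 2.
#' @return The minimum canonical copy number (integer).
#' @export
#' @examples
#' canonical_tr_threshold(2)  # 9
#' canonical_tr_threshold(3)  # 11
canonical_tr_threshold <- function(unit_length) {
  if (any(unit_length < 2))
    stop("unit_length < 2 is the homopolymer domain, not a tandem repeat")
  as.integer(unit_length) * 2L + 5L
}

#' Classify the repeat context of an indel
#'
#' Assigns one of the classes `HR`, `TR`, `HR_NC`, `TR_NC`, `NONE` (in that
#' precedence order) from the tandem arrays overlapping the indel:
#' \itemize{
#'   \item `HR`: the indel lies within a run of six or more identical bases
#'     and the inserted/deleted sequence consists solely of the run base;
#'   \item `HR_NC`: such a run overlaps but the indel sequence contains other
#'     bases;
#'   \item `TR`: a multi-base tandem array overlaps with at least
#'     [canonical_tr_threshold()] copies;
#'   \item `TR_NC`: a multi-base array overlaps with fewer copies;
#'   \item `NONE`: no overlapping array.
#' }
#' "Overlap" means the indel's reference interval (the insertion point for
#' insertions) intersects the array span. Ties between arrays of a class are
#' broken by longer span, then shorter unit.
#'
#' @param window Sequence window from [extract_context()].
#' @param offset 1-based position of the indel anchor base in the window.
#' @param ref,alt REF and ALT alleles (VCF convention, shared anchor base).
#' @param repeats Optional precomputed repeat table (e.g. from
#'   [find_tandem_repeats()] or [read_trf_dat()], coordinates relative to the
#'   window); computed from the window when NULL.
#' @return A list of class `repeat_annotation`: `klass`, `unit`, `copies`,
#'   `span` (c(start, end) in window coordinates; NA for `NONE`).
#' @export
classify_indel_context <- function(window, offset, ref, alt, repeats = NULL) {
  if (nchar(ref) == nchar(alt))
    stop("not an indel: REF and ALT have equal length")
  if (is.null(repeats)) repeats <- find_tandem_repeats(window)
  deletion <- nchar(ref) > nchar(alt)
  indel_seq <- if (deletion) substr(ref, 2, nchar(ref)) else substr(alt, 2, nchar(alt))
  iv <- if (deletion) c(offset + 1L, offset + nchar(ref) - 1L)
        else c(offset, min(offset + 1L, nchar(window)))
  ov <- repeats[repeats$start <= iv[2] & repeats$end >= iv[1], , drop = FALSE]
  none <- structure(list(klass = "NONE", unit = NA_character_,
                         copies = NA_integer_, span = c(NA_integer_, NA_integer_)),
                    class = "repeat_annotation")
  if (!nrow(ov)) return(none)
  pick <- function(d) {
    d <- d[order(-(d$end - d$start), d$unit_len), , drop = FALSE]
    structure(list(klass = NA_character_, unit = d$unit[1],
                   copies = d$copies[1], span = c(d$start[1], d$end[1])),
              class = "repeat_annotation")
  }
  bases <- unique(strsplit(indel_seq, "")[[1]])
  hr <- ov[ov$unit_len == 1 & ov$copies >= 6, , drop = FALSE]
  hr_match <- hr[length(bases) == 1 & hr$unit %in% bases, , drop = FALSE]
  tr <- ov[ov$unit_len > 1, , drop = FALSE]
  tr_can <- tr[tr$copies >= canonical_tr_threshold(pmax(tr$unit_len, 2)), , drop = FALSE]
  ann <- if (nrow(hr_match)) { a <- pick(hr_match); a$klass <- "HR"; a
  } else if (nrow(tr_can)) { a <- pick(tr_can); a$klass <- "TR"; a
  } else if (nrow(hr)) { a <- pick(hr); a$klass <- "HR_NC"; a
  } else if (nrow(tr)) { a <- pick(tr); a$klass <- "TR_NC"; a
  } else none
  ann
}

#' @export
print.repeat_annotation <- function(x, ...) {
  if (x$klass == "NONE") cat("repeat context: NONE\n")
  else cat(sprintf("repeat context: %s (unit %s x %d, window span %d-%d)\n",
                   x$klass, x$unit, x$copies, x$span[1], x$span[2]))
  invisible(x)
}

#' Annotate the repeat context of indel sites
#'
#' Classifies every indel in a site table against a reference sequence; SNVs
#' receive `NONE`.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param reference `DNAStringSet` or named character vector of contigs.
#' @param flank Flank length for [extract_context()].
#' @return The site table with added columns `repeat_class`, `repeat_unit`,
#'   `repeat_copies`.
#' @export
annotate_repeat_context <- function(sites, reference, flank = 100) {
  n <- nrow(sites)
  klass <- rep("NONE", n); unit <- rep(NA_character_, n)
  copies <- rep(NA_integer_, n)
  is_indel <- nchar(sites$ref) != nchar(sites$alt)
  for (i in which(is_indel)) {
    ctx <- extract_context(reference, sites$chrom[i], sites$pos[i],
                           ref_len = nchar(sites$ref[i]), flank = flank)
    ann <- classify_indel_context(ctx$window, ctx$offset,
                                  sites$ref[i], sites$alt[i])
    klass[i] <- ann$klass; unit[i] <- ann$unit; copies[i] <- ann$copies
  }
  sites$repeat_class <- klass
  sites$repeat_unit <- unit
  sites$repeat_copies <- copies
  sites
}

#' Read Tandem Repeats Finder `.dat` output
#'
#' Adapter for externally produced TRF annotations so they can replace the
#' internal exact-match detector (TRF tolerates mismatches/indels inside
#' arrays, which the internal detector does not).
#'
#' @param path Path to a TRF `.dat` file (one or more `Sequence:` blocks
#'   followed by data rows).
#' @return data.frame: `seqname`, `unit` (canonical rotation), `unit_len`,
#'   `copies` (floor of TRF's fractional copy number), `start`, `end`.
#' @export
read_trf_dat <- function(path) {
  ln <- readLines(path)
  seqname <- NA_character_
  rows <- list()
  for (x in ln) {
    if (startsWith(x, "Sequence:")) {
      seqname <- trimws(sub("^Sequence:", "", x))
      seqname <- strsplit(seqname, "\\s+")[[1]][1]
      next
    }
    f <- strsplit(trimws(x), "\\s+")[[1]]
    if (length(f) >= 14 && !is.na(suppressWarnings(as.integer(f[1])))) {
      rows[[length(rows) + 1]] <- data.frame(
        seqname = seqname,
        unit = .min_rotation(toupper(f[14])),
        unit_len = as.integer(f[3]),
        copies = as.integer(floor(as.numeric(f[4]))),
        start = as.integer(f[1]), end = as.integer(f[2]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(seqname = character(0), unit = character(0),
                      unit_len = integer(0), copies = integer(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
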