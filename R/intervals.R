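#' Genomic interval sets
#'
#' An `interval_set` holds 0-based, half-open genomic intervals (BED
#' convention), optionally stranded and named, sorted by
#' (chromosome, start, end, name). All interval arithmetic in the package
#' (merging of overlapping peak calls, peak-by-CRM intersections, flank
#' extension, promoter-overlap flags) operates on this class. Strand is
#' carried but ignored by interval arithmetic; it only matters for signal
#' queries on stranded tracks.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end numeric vectors; `0 <= start < end`, end exclusive.
#' @param strand optional character vector in `c("+", "-", "*")`;
#'   default unstranded (`"*"`).
#' @param name optional character vector of interval labels.
#' @param chrom_sizes optional named numeric vector of chromosome lengths;
#'   when present every `end` must be within the named chromosome.
#' @return An object of class `interval_set`: a data frame with columns
#'   `chrom`, `start`, `end`, `strand`, `name` and a `chrom_sizes`
#'   attribute.
#' @examples
#' interval_set(c("chr1", "chr1"), c(10, 0), c(20, 5))
#' @export
interval_set <- function(chrom, start, end, strand = NULL, name = NULL,
                         chrom_sizes = NULL) {
  n <- length(start)
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  if (is.null(strand)) strand <- rep("*", n)
  strand <- as.character(strand)
  if (length(strand) == 1L) strand <- rep(strand, n)
  strand[strand %in% c(".", "")] <- "*"
  if (is.null(name)) name <- rep(NA_character_, n)
  name <- as.character(name)
  x <- data.frame(chrom = chrom, start = start, end = end,
                  strand = strand, name = name, stringsAsFactors = FALSE)
  validate_interval_set(x, chrom_sizes)
  x <- sort_intervals(x)
  structure(x, chrom_sizes = chrom_sizes,
            class = c("interval_set", "data.frame"))
}

validate_interval_set <- function(x, chrom_sizes = NULL) {
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop("chromosome names must be non-empty")
  if (any(!x$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop(sprintf("invalid interval at row %d: need 0 <= start < end (got [%s, %s))",
                 bad[1], format(x$start[bad[1]]), format(x$end[bad[1]])))
  if (!is.null(chrom_sizes)) {
    if (is.null(names(chrom_sizes)))
      stop("chrom_sizes must be a named vector")
    unknown <- setdiff(unique(x$chrom), names(chrom_sizes))
    if (length(unknown))
      stop("interval on chromosome absent from chrom_sizes: ", unknown[1])
    over <- which(x$end > chrom_sizes[x$chrom])
    if (length(over))
      stop(sprintf("interval end %s exceeds length of %s",
                   format(x$end[over[1]]), x$chrom[over[1]]))
  }
  invisible(x)
}

sort_intervals <- function(x) {
  o <- order(x$chrom, x$start, x$end, x$name, method = "radix")
  x <- x[o, , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' @export
print.interval_set <- function(x, ...) {
  cs <- attr(x, "chrom_sizes")
  cat(sprintf("interval_set: %d intervals on %d chromosome(s)%s\n",
              nrow(x), length(unique(x$chrom)),
              if (is.null(cs)) "" else sprintf(" (genome %s bp)",
                                               format(sum(cs), big.mark = ","))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat(sprintf("... and %d more\n", nrow(x) - 8))
  invisible(x)
}

## IRanges is 1-based closed; BED half-open [start, end) maps to
## [start + 1, end]. Adjacent BED intervals (end == start) become adjacent
## closed ranges, which IRanges::reduce() merges by default -- exactly the
## bedtools-merge semantics the package needs.
as_iranges_by_chrom <- function(x) {
  sp <- split(seq_len(nrow(x)), x$chrom)
  lapply(sp, function(i) IRanges::IRanges(start = x$start[i] + 1L,
                                          end = x$end[i]))
}

iranges_to_df <- function(ir, chrom) {
  if (length(ir) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  data.frame(chrom = chrom, start = IRanges::start(ir) - 1,
             end = IRanges::end(ir), stringsAsFactors = FALSE)
}

#' Merge overlapping or touching intervals
#'
#' Collapses an interval set to its disjoint union, as done for overlapping
#' peak calls prior to signal quantification. Touching intervals
#' (`end == start`) are merged; covered bases are conserved. Strand and
#' names are dropped.
#'
#' @param x an [interval_set].
#' @return A disjoint, sorted [interval_set].
#' @examples
#' merge_intervals(interval_set("chr1", c(10, 15), c(20, 30)))
#' @export
merge_intervals <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  irl <- as_iranges_by_chrom(x)
  parts <- lapply(names(irl), function(ch)
    iranges_to_df(IRanges::reduce(irl[[ch]]), ch))
  df <- if (length(parts)) do.call(rbind, c(parts,
                                            list(make.row.names = FALSE)))
        else NULL
  if (is.null(df)) df <- data.frame(chrom = character(), start = numeric(),
                                    end = numeric())
  interval_set(df$chrom, df$start, df$end,
               chrom_sizes = attr(x, "chrom_sizes"))
}

#' Intersect two interval sets
#'
#' Returns every maximal interval covered by both sets (per-base AND of the
#' two coverage indicators, merged), as used to restrict peak calls to CRM
#' spans.
#'
#' @param a,b [interval_set] objects.
#' @return A disjoint [interval_set] of the shared bases.
#' @examples
#' intersect_intervals(interval_set("chr1", 0, 100),
#'                     interval_set("chr1", 50, 150))
#' @export
intersect_intervals <- function(a, b) {
  stopifnot(inherits(a, "interval_set"), inherits(b, "interval_set"))
  ira <- as_iranges_by_chrom(a)
  irb <- as_iranges_by_chrom(b)
  shared <- intersect(names(ira), names(irb))
  parts <- lapply(shared, function(ch)
    iranges_to_df(IRanges::intersect(ira[[ch]], irb[[ch]]), ch))
  df <- if (length(parts)) do.call(rbind, c(parts,
                                            list(make.row.names = FALSE)))
        else NULL
  if (is.null(df)) df <- data.frame(chrom = character(), start = numeric(),
                                    end = numeric())
  interval_set(df$chrom, df$start, df$end,
               chrom_sizes = attr(a, "chrom_sizes"))
}

#' Extend intervals by a symmetric flank
#'
#' Pads each interval by `flank` bp on both sides (as done to capture
#' pause-associated PRO-seq reads extending beyond raw TRE predictions),
#' clamps to `[0, chromosome length)` when chromosome sizes are known, and
#' re-merges any overlaps the extension creates. `flank = 0` is the
#' identity.
#'
#' @param x an [interval_set].
#' @param flank non-negative flank size in bp.
#' @return An [interval_set].
#' @examples
#' extend_intervals(interval_set("chr1", 1000, 1100), 50)
#' @export
extend_intervals <- function(x, flank) {
  stopifnot(inherits(x, "interval_set"), is.numeric(flank), length(flank) == 1,
            flank >= 0)
  if (flank == 0 || nrow(x) == 0) return(x)
  cs <- attr(x, "chrom_sizes")
  start <- pmax(x$start - flank, 0)
  end <- x$end + flank
  if (!is.null(cs)) end <- pmin(end, cs[x$chrom])
  merge_intervals(interval_set(x$chrom, start, end, chrom_sizes = cs))
}

#' Flag query intervals overlapping a reference set
#'
#' A query interval is flagged when it shares at least one base with any
#' reference interval; half-open adjacency (`end == start`) is not overlap.
#' Used for the CRM promoter-overlap flag.
#'
#' @param query,reference [interval_set] objects.
#' @return Logical vector, one flag per `query` row (in `query`'s sorted
#'   order).
#' @examples
#' overlap_flags(interval_set("chr1", 100, 200),
#'               interval_set("chr1", 199, 300))
#' @export
overlap_flags <- function(query, reference) {
  stopifnot(inherits(query, "interval_set"), inherits(reference, "interval_set"))
  out <- logical(nrow(query))
  if (nrow(query) == 0 || nrow(reference) == 0) return(out)
  sp <- split(seq_len(nrow(query)), query$chrom)
  irr <- as_iranges_by_chrom(reference)
  for (ch in names(sp)) {
    if (is.null(irr[[ch]])) next
    i <- sp[[ch]]
    q <- IRanges::IRanges(start = query$start[i] + 1L, end = query$end[i])
    out[i] <- IRanges::countOverlaps(q, irr[[ch]], minoverlap = 1L) > 0
  }
  out
}

#' Cross-tabulate overlaps among named interval sets
#'
#' For each of 2-3 named sets, counts how many members overlap each
#' combination of the other sets (Venn-style counts by the >= 1 bp rule;
#' each member is counted once, in its combination class).
#'
#' @param sets a named list of 2 or 3 [interval_set] objects.
#' @return A named list (one element per input set) of named integer
#'   vectors; names are `"none"` or `&`-joined names of the other sets a
#'   member overlaps.
#' @export
overlap_summary <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% c(2L, 3L),
            !is.null(names(sets)), all(nzchar(names(sets))))
  out <- vector("list", length(sets))
  names(out) <- names(sets)
  for (nm in names(sets)) {
    others <- setdiff(names(sets), nm)
    flags <- vapply(others, function(o) overlap_flags(sets[[nm]], sets[[o]]),
                    logical(nrow(sets[[nm]])))
    flags <- matrix(flags, nrow = nrow(sets[[nm]]),
                    dimnames = list(NULL, others))
    cls <- apply(flags, 1, function(f) {
      hit <- others[f]
      if (!length(hit)) "none" else paste(hit, collapse = "&")
    })
    out[[nm]] <- table(factor(cls, levels = unique(c("none", sort(cls)))))
    out[[nm]] <- stats::setNames(as.integer(out[[nm]]), names(out[[nm]]))
  }
  out
}

#' Read a BED file
#'
#' Reads BED3 or BED6 (tab-separated, no header; `track`/`browser`/comment
#' lines are skipped) into a sorted [interval_set]. With `dialect =
#' "BED6"`, names come from field 4 and strand from field 6.
#'
#' @param path path to a BED file.
#' @param dialect `"BED3"` or `"BED6"`.
#' @param chrom_sizes optional named numeric vector of chromosome lengths
#'   for bounds validation.
#' @return An [interval_set].
#' @export
read_bed <- function(path, dialect = c("BED3", "BED6"), chrom_sizes = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx))
    return(interval_set(character(), numeric(), numeric(),
                        chrom_sizes = chrom_sizes))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (dialect == "BED6") 6L else 3L
  bad <- which(nf < need)
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: expected >= %d tab-separated fields, got %d",
                 idx[bad[1]], path, need, nf[bad[1]]))
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: start/end must be non-negative integers",
                 idx[bad[1]], path))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("invalid BED line %d in %s: start >= end", idx[bad[1]], path))
  name <- strand <- NULL
  if (dialect == "BED6") {
    name <- vapply(fields, `[[`, character(1), 4L)
    strand <- vapply(fields, `[[`, character(1), 6L)
  }
  interval_set(chrom, start, end, strand = strand, name = name,
               chrom_sizes = chrom_sizes)
}

#' Write an interval set as BED
#'
#' Writes BED3 when the set is unstranded and unnamed, otherwise BED6
#' (score column 0).
#'
#' @param x an [interval_set].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "interval_set"))
  bed6 <- any(x$strand != "*") || any(!is.na(x$name))
  if (bed6) {
    nm <- ifelse(is.na(x$name), ".", x$name)
    out <- sprintf("%s\t%d\t%d\t%s\t0\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), nm, x$strand)
  } else {
    out <- sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start),
                   as.integer(x$end))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read / write chromosome sizes
#'
#' Two-column tab-separated table: chromosome name, length in bp.
#'
#' @param path file path.
#' @return `read_chrom_sizes`: a named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  if (any(df$size <= 0)) stop("chromosome lengths must be positive")
  stats::setNames(df$size, df$chrom)
}

#' @rdname read_chrom_sizes
#' @param sizes named numeric vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}
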