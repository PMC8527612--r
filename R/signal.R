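#' Per-base signal tracks
#'
#' A `signal_track` stores non-negative per-base signal (e.g. ATAC-seq
#' cut-site density, Pol II ChIP coverage, PRO-seq 3'-end counts) as one
#' run-length encoding per chromosome. The contract is per-base semantics:
#' any base not covered by input data is 0. Tracks can be normalized to
#' reads per million per base (RPM).
#'
#' @param values named list of numeric vectors or [S4Vectors::Rle] objects,
#'   one per chromosome; all values must be `>= 0`.
#' @param chrom_sizes optional named numeric vector; chromosomes are
#'   zero-padded (or validated) to these lengths.
#' @param normalized logical; whether RPM normalization has been applied.
#' @return An object of class `signal_track` with elements `data` (list of
#'   `Rle`), `chrom_sizes`, `total_signal` and `normalized`.
#' @examples
#' signal_track(list(chr1 = c(0, 2, 2, 1)))
#' @export
signal_track <- function(values, chrom_sizes = NULL, normalized = FALSE) {
  stopifnot(is.list(values), !is.null(names(values)))
  data <- lapply(values, function(v) {
    r <- if (methods::is(v, "Rle")) v else S4Vectors::Rle(as.numeric(v))
    if (any(S4Vectors::runValue(r) < 0)) stop("signal values must be >= 0")
    r
  })
  if (!is.null(chrom_sizes)) {
    missing_ch <- setdiff(names(data), names(chrom_sizes))
    if (length(missing_ch))
      stop("track chromosome absent from chrom_sizes: ", missing_ch[1])
    for (ch in names(chrom_sizes)) {
      len <- as.integer(chrom_sizes[[ch]])
      cur <- if (is.null(data[[ch]])) S4Vectors::Rle(numeric(0)) else data[[ch]]
      if (length(cur) > len)
        stop(sprintf("signal on %s extends past chromosome length %d", ch, len))
      if (length(cur) < len)
        cur <- c(cur, S4Vectors::Rle(0, len - length(cur)))
      data[[ch]] <- cur
    }
    data <- data[names(chrom_sizes)]
  } else {
    chrom_sizes <- vapply(data, length, numeric(1))
  }
  total <- sum(vapply(data, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                              S4Vectors::runLength(r)),
                      numeric(1)))
  structure(list(data = data, chrom_sizes = chrom_sizes,
                 total_signal = total, normalized = normalized),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s), %s bp, total signal %.4g%s\n",
              length(x$data), format(sum(x$chrom_sizes), big.mark = ","),
              x$total_signal, if (x$normalized) " (RPM)" else ""))
  invisible(x)
}

#' Stranded signal track
#'
#' Pairs plus- and minus-strand tracks (PRO-seq 3' ends); both must share
#' the same chromosome universe. Minus-strand values are stored as
#' magnitudes.
#'
#' @param plus,minus [signal_track] objects.
#' @return An object of class `stranded_track`.
#' @export
stranded_track <- function(plus, minus) {
  stopifnot(inherits(plus, "signal_track"), inherits(minus, "signal_track"))
  if (!identical(names(plus$data), names(minus$data)) ||
      !isTRUE(all.equal(unname(plus$chrom_sizes), unname(minus$chrom_sizes))))
    stop("plus and minus tracks must share the same chromosome universe")
  structure(list(plus = plus, minus = minus,
                 normalized = plus$normalized && minus$normalized),
            class = "stranded_track")
}

#' @export
print.stranded_track <- function(x, ...) {
  cat("stranded_track\n  plus:  ")
  print(x$plus)
  cat("  minus: ")
  print(x$minus)
  invisible(x)
}

#' Read a bedGraph file
#'
#' Four-column bedGraph (chrom, start, end, value; 0-based half-open).
#' Intervals within a chromosome must not overlap; uncovered bases are 0.
#' Files holding minus-strand data as non-positive values are accepted and
#' negated to magnitudes; mixed-sign files are rejected.
#'
#' @param path path to a bedGraph file.
#' @param chrom_sizes optional named numeric vector of chromosome lengths.
#' @return A [signal_track].
#' @export
read_bedgraph <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    if (is.null(chrom_sizes)) chrom_sizes <- numeric(0)
    return(signal_track(stats::setNames(
      lapply(chrom_sizes, function(l) S4Vectors::Rle(0, as.integer(l))),
      names(chrom_sizes)), chrom_sizes = chrom_sizes))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4L)
  if (length(bad))
    stop(sprintf("malformed bedGraph line %d in %s: expected 4 tab-separated fields",
                 idx[bad[1]], path))
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(value) | start < 0 |
                 start >= end)
  if (length(bad))
    stop(sprintf("malformed bedGraph line %d in %s", idx[bad[1]], path))
  if (any(value < 0)) {
    if (all(value <= 0)) value <- -value  # minus-strand dialect
    else stop("bedGraph mixes positive and negative values: ", path)
  }
  data <- list()
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    o <- order(start[i])
    s <- start[i][o]; e <- end[i][o]; v <- value[i][o]
    if (any(s[-1] < e[-length(e)]))
      stop("overlapping bedGraph intervals on ", ch, " in ", path)
    # interleave zero gaps with covered runs
    gap <- c(s, 0) - c(0, e)
    lens <- as.vector(rbind(gap[seq_along(s)], e - s))
    vals <- as.vector(rbind(0, v))
    keep_run <- lens > 0
    data[[ch]] <- S4Vectors::Rle(vals[keep_run], lens[keep_run])
  }
  signal_track(data, chrom_sizes = chrom_sizes)
}

#' Write a signal track as bedGraph
#'
#' Zero runs are omitted; values are written at run-length boundaries.
#'
#' @param track a [signal_track].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(track$data)) {
    r <- track$data[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0, ends[-length(ends)])
    v <- S4Vectors::runValue(r)
    nz <- v != 0
    if (any(nz))
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, as.integer(starts[nz]),
                         as.integer(ends[nz]),
                         formatC(v[nz], format = "g", digits = 10)), con)
  }
  invisible(path)
}

#' Normalize a track to reads per million per base
#'
#' Scales every per-base value by `1e6 / library_total`. For a stranded
#' track the default library total is the combined plus + minus signal
#' (one sequencing library), and both strands are scaled by the same
#' factor.
#'
#' @param track a [signal_track] or [stranded_track].
#' @param library_total raw summed signal of the library; defaults to the
#'   track's own total (combined across strands when stranded). Must be
#'   positive.
#' @return The normalized track (same class as the input).
#' @export
rpm_normalize <- function(track, library_total = NULL) {
  UseMethod("rpm_normalize")
}

#' @export
rpm_normalize.signal_track <- function(track, library_total = NULL) {
  if (is.null(library_total)) library_total <- track$total_signal
  if (!is.numeric(library_total) || library_total <= 0)
    stop("library_total must be > 0")
  f <- 1e6 / library_total
  out <- lapply(track$data, function(r) r * f)
  signal_track(out, chrom_sizes = track$chrom_sizes, normalized = TRUE)
}

#' @export
rpm_normalize.stranded_track <- function(track, library_total = NULL) {
  if (is.null(library_total))
    library_total <- track$plus$total_signal + track$minus$total_signal
  stranded_track(rpm_normalize(track$plus, library_total),
                 rpm_normalize(track$minus, library_total))
}

clamp_views <- function(r, start0, end0) {
  ## start0/end0 are BED half-open; returns per-interval (sum, max) with
  ## bases past the stored length treated as 0.
  len <- length(r)
  s <- pmax(as.integer(start0) + 1L, 1L)
  e <- pmin(as.integer(end0), len)
  ok <- s <= e
  sums <- numeric(length(s))
  maxs <- numeric(length(s))
  if (any(ok)) {
    v <- IRanges::Views(r, start = s[ok], end = e[ok])
    sums[ok] <- IRanges::viewSums(v)
    maxs[ok] <- IRanges::viewMaxs(v)
  }
  list(sum = sums, max = pmax(maxs, 0))
}

#' Query signal over an interval set
#'
#' Per-interval sum (total per-base signal) or max (peak summit value),
#' plus the set-level aggregate: the sum over intervals of the per-interval
#' statistic (for `max` this is the "sum of the maximum values" used for
#' summit-based features).
#'
#' @param track a [signal_track].
#' @param set an [interval_set]; every chromosome must exist in the track.
#' @param stat `"sum"` or `"max"`.
#' @return A list with `per_interval` (numeric, in `set` order) and
#'   `aggregate` (their sum; 0 for an empty set).
#' @export
track_query <- function(track, set, stat = c("sum", "max")) {
  stat <- match.arg(stat)
  stopifnot(inherits(track, "signal_track"), inherits(set, "interval_set"))
  out <- numeric(nrow(set))
  if (nrow(set)) {
    unknown <- setdiff(unique(set$chrom), names(track$data))
    if (length(unknown))
      stop("interval on chromosome unknown to the track: ", unknown[1])
    sp <- split(seq_len(nrow(set)), set$chrom)
    for (ch in names(sp)) {
      i <- sp[[ch]]
      out[i] <- clamp_views(track$data[[ch]], set$start[i], set$end[i])[[stat]]
    }
  }
  list(per_interval = out, aggregate = sum(out))
}

#' Query a stranded track over an interval set
#'
#' The per-interval `sum` is the plus-strand sum plus the minus-strand sum
#' (total 3'-end reads on both strands); `max` is the larger of the two
#' strand maxima.
#'
#' @inheritParams track_query
#' @param track a [stranded_track].
#' @return As [track_query()].
#' @export
stranded_query <- function(track, set, stat = c("sum", "max")) {
  stat <- match.arg(stat)
  stopifnot(inherits(track, "stranded_track"))
  p <- track_query(track$plus, set, stat)
  m <- track_query(track$minus, set, stat)
  per <- if (stat == "sum") p$per_interval + m$per_interval
         else pmax(p$per_interval, m$per_interval)
  list(per_interval = per, aggregate = sum(per))
}

query_any <- function(track, set, stat) {
  if (inherits(track, "stranded_track")) stranded_query(track, set, stat)
  else track_query(track, set, stat)
}

#' Replicate correlation at peak calls
#'
#' Reproducibility QC between two biological replicates: per-peak total
#' signal is computed in each replicate and Pearson and Spearman
#' correlations of the two vectors are returned. Zero-variance vectors give
#' `NA` with a warning.
#'
#' @param a,b two [signal_track] or [stranded_track] objects.
#' @param peaks an [interval_set] with at least 3 intervals.
#' @return A list with `pearson`, `spearman` and `n`.
#' @export
replicate_correlation <- function(a, b, peaks) {
  stopifnot(inherits(peaks, "interval_set"))
  if (nrow(peaks) < 3) stop("replicate correlation needs >= 3 peaks")
  va <- query_any(a, peaks, "sum")$per_interval
  vb <- query_any(b, peaks, "sum")$per_interval
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("zero-variance per-peak signal; correlation undefined")
    return(list(pearson = NA_real_, spearman = NA_real_, n = nrow(peaks)))
  }
  list(pearson = stats::cor(va, vb),
       spearman = stats::cor(va, vb, method = "spearman"),
       n = nrow(peaks))
}
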