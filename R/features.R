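#' Read / write a CRM table
#'
#' Tab-separated table of tested cis-regulatory modules with header
#' columns `id`, `chrom`, `start`, `end`, `expr_12h`, `expr_24h` and
#' optionally `orientation` (`concurrent`/`divergent`, for
#' promoter-overlapping CRMs). Expression is in basal-promoter units (1 =
#' the promoter-only construct).
#'
#' @param path file path.
#' @param chrom_sizes optional named numeric vector for bounds validation.
#' @return A data frame of CRM records.
#' @export
read_crm_table <- function(path, chrom_sizes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("id", "chrom", "start", "end", "expr_12h", "expr_24h")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("CRM table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("CRM ids must be unique")
  if (any(df$expr_12h < 0) || any(df$expr_24h < 0))
    stop("reporter expression must be >= 0")
  validate_interval_set(data.frame(chrom = df$chrom, start = df$start,
                                   end = df$end, strand = "*"), chrom_sizes)
  df
}

#' @rdname read_crm_table
#' @param crms a CRM data frame as returned by `read_crm_table`.
#' @export
write_crm_table <- function(crms, path) {
  utils::write.table(crms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a TSS table
#'
#' Tab-separated transcript 5'-end table with header columns `chrom`,
#' `pos` (0-based TSS base), `strand`, `transcript_id`.
#'
#' @param path file path.
#' @return A data frame of TSS records.
#' @export
read_tss_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "transcript_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("TSS table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$pos < 0)) stop("TSS positions must be >= 0")
  df
}

#' @rdname read_tss_table
#' @param tss a TSS data frame.
#' @export
write_tss_table <- function(tss, path) {
  utils::write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

crms_as_interval_set <- function(crms, chrom_sizes = NULL) {
  interval_set(crms$chrom, crms$start, crms$end, name = crms$id,
               chrom_sizes = chrom_sizes)
}

#' Per-CRM signal-quantification windows
#'
#' For each CRM, intersects the peak calls with the CRM span, merges the
#' intersections (correcting for overlapping peaks within the CRM), and
#' extends the merged windows by `flank` bp (50 bp for TRE predictions, to
#' capture pause-associated reads extending beyond the raw prediction; 0
#' for ATAC and Pol II peaks). Extended windows are clamped to chromosome
#' bounds but deliberately not re-clipped to the CRM.
#'
#' @param crms CRM data frame (columns `id`, `chrom`, `start`, `end`).
#' @param peaks an [interval_set] of peak calls.
#' @param flank non-negative extension in bp.
#' @param chrom_sizes optional named numeric vector used for clamping.
#' @return A named list (by CRM id) of [interval_set] window sets; CRMs
#'   overlapping no peak get an empty set.
#' @export
crm_windows <- function(crms, peaks, flank = 0, chrom_sizes = NULL) {
  flat <- crm_windows_flat(crms, peaks, flank, chrom_sizes)
  if (is.null(chrom_sizes)) chrom_sizes <- attr(peaks, "chrom_sizes")
  empty <- interval_set(character(), numeric(), numeric(),
                        chrom_sizes = chrom_sizes)
  out <- stats::setNames(rep(list(empty), nrow(crms)), crms$id)
  for (id in unique(flat$crm_id)) {
    w <- flat[flat$crm_id == id, , drop = FALSE]
    out[[id]] <- interval_set(w$chrom, w$start, w$end,
                              chrom_sizes = chrom_sizes)
  }
  out
}

## Flat (one row per window) variant used by build_features: merged
## peak-by-CRM intersections, per-CRM flank extension with re-merge,
## chromosome-bound clamping. Column crm_id groups windows by CRM.
crm_windows_flat <- function(crms, peaks, flank = 0, chrom_sizes = NULL) {
  stopifnot(inherits(peaks, "interval_set"))
  if (is.null(chrom_sizes)) chrom_sizes <- attr(peaks, "chrom_sizes")
  mp <- merge_intervals(peaks)
  irp <- as_iranges_by_chrom(mp)
  parts <- list()
  crow <- split(seq_len(nrow(crms)), crms$chrom)
  for (ch in names(crow)) {
    ir <- irp[[ch]]
    if (is.null(ir) || length(ir) == 0) next
    i <- crow[[ch]]
    crm_ir <- IRanges::IRanges(start = crms$start[i] + 1L, end = crms$end[i])
    hits <- IRanges::findOverlaps(crm_ir, ir, minoverlap = 1L)
    if (length(hits) == 0) next
    q <- S4Vectors::queryHits(hits)
    clip <- IRanges::pintersect(ir[S4Vectors::subjectHits(hits)], crm_ir[q])
    parts[[ch]] <- data.frame(
      crm_id = crms$id[i][q], chrom = ch,
      start = IRanges::start(clip) - 1, end = IRanges::end(clip),
      stringsAsFactors = FALSE)
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  flat <- if (length(parts)) do.call(rbind, c(parts,
                                              list(make.row.names = FALSE)))
          else NULL
  if (is.null(flat))
    return(data.frame(crm_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  if (flank > 0) {
    start <- pmax(flat$start - flank, 0)
    end <- flat$end + flank
    if (!is.null(chrom_sizes)) end <- pmin(end, chrom_sizes[flat$chrom])
    ## re-merge within each CRM (extension may fuse adjacent windows)
    key <- flat$crm_id
    irl <- IRanges::IRangesList(split(IRanges::IRanges(start + 1L, end), key))
    red <- IRanges::reduce(irl)
    lens <- S4Vectors::elementNROWS(red)
    flatr <- unlist(red, use.names = FALSE)
    ids <- rep(names(red), lens)
    chrom <- flat$chrom[match(ids, flat$crm_id)]
    flat <- data.frame(crm_id = ids, chrom = chrom,
                       start = IRanges::start(flatr) - 1,
                       end = IRanges::end(flatr), stringsAsFactors = FALSE)
  }
  flat
}

#' Build the per-CRM feature table
#'
#' Quantifies each assay's signal inside its peak-by-CRM windows: the
#' `sum` feature is the total per-base signal over all windows (plus +
#' minus strands for stranded tracks), and the `max` feature is the sum of
#' per-window maxima (summit values). CRMs with no overlapping peaks get
#' zeros. Optionally attaches reporter expression, the derived activity
#' label and the promoter-overlap flag.
#'
#' @param crms CRM data frame (columns `id`, `chrom`, `start`, `end`).
#' @param assay_inputs named list, one element per assay (e.g. `ATAC`,
#'   `dREG`, `PolII`), each a list with elements `peaks` (an
#'   [interval_set]), `track` (a [signal_track] or [stranded_track]) and
#'   `flank` (bp; default 0).
#' @param expr optional numeric vector of reporter expression
#'   (basal-promoter units) aligned with `crms` rows; adds `expr` and
#'   `active` columns.
#' @param promoters optional [interval_set] of promoter windows; adds a
#'   `promoter_overlap` column by the >= 1 bp rule.
#' @param stage optional stage tag recorded in a `stage` column.
#' @param threshold activity threshold in basal-promoter units (default 2).
#' @param chrom_sizes optional named numeric vector.
#' @return A data frame (class `crm_features`) with one row per CRM and
#'   columns `<assay>_sum`, `<assay>_max` per assay.
#' @export
build_features <- function(crms, assay_inputs, expr = NULL, promoters = NULL,
                           stage = NULL, threshold = 2,
                           chrom_sizes = NULL) {
  stopifnot(is.list(assay_inputs), !is.null(names(assay_inputs)))
  for (assay in names(assay_inputs)) {
    ai <- assay_inputs[[assay]]
    if (is.null(ai$peaks) || is.null(ai$track))
      stop("assay input incomplete for assay: ", assay)
  }
  out <- data.frame(crm_id = crms$id, stringsAsFactors = FALSE)
  if (!is.null(stage)) out$stage <- stage
  for (assay in names(assay_inputs)) {
    ai <- assay_inputs[[assay]]
    flank <- if (is.null(ai$flank)) 0 else ai$flank
    flat <- crm_windows_flat(crms, ai$peaks, flank = flank,
                             chrom_sizes = chrom_sizes)
    sums <- maxs <- stats::setNames(numeric(nrow(crms)), crms$id)
    if (nrow(flat)) {
      wset <- interval_set(flat$chrom, flat$start, flat$end,
                           name = flat$crm_id, chrom_sizes = chrom_sizes)
      wsum <- query_any(ai$track, wset, "sum")$per_interval
      wmax <- query_any(ai$track, wset, "max")$per_interval
      agg_s <- rowsum(wsum, wset$name)      # sum of per-window sums
      agg_m <- rowsum(wmax, wset$name)      # sum of per-window maxima
      sums[rownames(agg_s)] <- agg_s[, 1]
      maxs[rownames(agg_m)] <- agg_m[, 1]
    }
    out[[paste0(assay, "_sum")]] <- unname(sums)
    out[[paste0(assay, "_max")]] <- unname(maxs)
  }
  if (!is.null(expr)) {
    out$expr <- expr
    out$active <- label_activity(expr, threshold)
  }
  if (!is.null(promoters)) {
    iset <- crms_as_interval_set(crms, chrom_sizes)
    fl <- overlap_flags(iset, promoters)
    out$promoter_overlap <- fl[match(crms$id, iset$name)]
  }
  class(out) <- c("crm_features", "data.frame")
  out
}

#' Promoter windows from a TSS table
#'
#' Promoters are the 200-bp windows centered at transcript 5' ends:
#' `[pos - 100, pos + 100)`, clamped to chromosome bounds. Strand is
#' recorded but does not change the window extent; transcripts sharing a
#' TSS yield duplicate windows.
#'
#' @param tss TSS data frame (columns `chrom`, `pos`, `strand`,
#'   `transcript_id`).
#' @param chrom_sizes optional named numeric vector for clamping.
#' @param half_width half window width in bp (default 100).
#' @return An [interval_set] of promoter windows.
#' @export
promoter_windows <- function(tss, chrom_sizes = NULL, half_width = 100) {
  start <- pmax(tss$pos - half_width, 0)
  end <- tss$pos + half_width
  if (!is.null(chrom_sizes)) end <- pmin(end, chrom_sizes[tss$chrom])
  interval_set(tss$chrom, start, end, strand = tss$strand,
               name = tss$transcript_id, chrom_sizes = chrom_sizes)
}

#' Label CRM activity against the basal-promoter baseline
#'
#' A CRM is active when its reporter expression is at least `threshold`
#' times the basal-promoter construct (default 2; the threshold is
#' inclusive).
#'
#' @param expr numeric vector of reporter expression in basal-promoter
#'   units; must be `>= 0`.
#' @param threshold fold-activity threshold (default 2).
#' @return Logical vector of activity labels.
#' @examples
#' label_activity(c(0.5, 1, 2, 3.7))
#' @export
label_activity <- function(expr, threshold = 2) {
  if (any(is.na(expr)) || any(expr < 0))
    stop("reporter expression must be non-negative")
  expr >= threshold
}

#' Ranked CRM expression
#'
#' Orders CRMs by descending reporter expression (ties broken by id) and
#' annotates the basal (1.0) and activity-threshold reference levels, as
#' in ranked-expression "elbow" plots.
#'
#' @param crms CRM data frame with an `id` column.
#' @param stage which expression column to rank: `"12h"` or `"24h"`
#'   (columns `expr_12h` / `expr_24h`).
#' @param threshold activity threshold (default 2).
#' @return A data frame with columns `rank`, `id`, `expr`, `active`, and
#'   attributes `baseline` (1) and `threshold`.
#' @export
rank_expression <- function(crms, stage = c("12h", "24h"), threshold = 2) {
  stage <- match.arg(stage)
  if (nrow(crms) < 1) stop("need at least one CRM")
  expr <- crms[[paste0("expr_", stage)]]
  o <- order(-expr, crms$id, method = "radix")
  out <- data.frame(rank = seq_along(o), id = crms$id[o], expr = expr[o],
                    active = label_activity(expr[o], threshold),
                    stringsAsFactors = FALSE)
  attr(out, "baseline") <- 1
  attr(out, "threshold") <- threshold
  out
}
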