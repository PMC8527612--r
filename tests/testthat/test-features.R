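test_that("CRM windows follow intersect -> merge -> extend, unclipped to CRM", {
  cs <- c(chr1 = 10000)
  crms <- data.frame(id = "crmA", chrom = "chr1", start = 0, end = 3000)
  # merge of within-CRM intersections
  w <- crm_windows(crms, iset("chr1", c(100, 350), c(400, 700),
                              chrom_sizes = cs), flank = 0)
  expect_equal(as.data.frame(w$crmA)[, 1:3],
               data.frame(chrom = "chr1", start = 100, end = 700))
  # clip to CRM first, then extend beyond the CRM boundary
  w <- crm_windows(crms, iset("chr1", 2990, 3200, chrom_sizes = cs),
                   flank = 50)
  expect_equal(c(w$crmA$start, w$crmA$end), c(2940, 3050))
  # CRM with no peak overlap has an empty window set
  w <- crm_windows(crms, iset("chr1", 5000, 5200, chrom_sizes = cs))
  expect_equal(nrow(w$crmA), 0)
  # extension is clamped at chromosome bounds
  crms2 <- data.frame(id = "edge", chrom = "chr1", start = 9500, end = 10000)
  w <- crm_windows(crms2, iset("chr1", 9900, 10000, chrom_sizes = cs),
                   flank = 200)
  expect_equal(w$edge$end, 10000)
})

test_that("window containment: flank-0 windows lie inside their CRM", {
  set.seed(31)
  cs <- c(chr1 = 20000)
  crms <- data.frame(id = sprintf("c%02d", 1:10), chrom = "chr1",
                     start = seq(0, 18000, by = 2000),
                     end = seq(1500, 19500, by = 2000))
  peaks <- random_interval_set(80, chrom_len = 20000, max_len = 400,
                               chrom_sizes = cs)
  w0 <- crm_windows(crms, peaks, flank = 0)
  for (i in seq_len(nrow(crms))) {
    wi <- w0[[crms$id[i]]]
    if (nrow(wi) == 0) next
    expect_true(all(wi$start >= crms$start[i] & wi$end <= crms$end[i]))
  }
  wf <- crm_windows(crms, peaks, flank = 50)
  for (i in seq_len(nrow(crms))) {
    wi <- wf[[crms$id[i]]]
    if (nrow(wi) == 0) next
    expect_true(all(wi$start >= crms$start[i] - 50 &
                      wi$end <= crms$end[i] + 50))
  }
})

test_that("feature table quantifies windows and matches a per-base oracle", {
  cs <- c(chr1 = 3000)
  crms <- data.frame(id = c("c1", "c2"), chrom = "chr1",
                     start = c(0, 2000), end = c(1000, 2500))
  const2 <- dense_track(list(chr1 = rep(2, 3000)))
  peaks <- iset("chr1", 100, 110, chrom_sizes = cs)
  tab <- build_features(crms, list(ATAC = list(peaks = peaks, track = const2,
                                               flank = 0)),
                        chrom_sizes = cs)
  expect_equal(tab$ATAC_sum, c(20, 0))  # single 10-bp window on constant 2
  expect_equal(tab$ATAC_max, c(2, 0))   # zero row for the window-less CRM

  set.seed(32)
  vals1 <- rpois(3000, 1) * runif(3000)
  tr1 <- dense_track(list(chr1 = vals1))
  plus <- rpois(3000, 1) * runif(3000)
  minus <- rpois(3000, 1) * runif(3000)
  st <- stranded_track(dense_track(list(chr1 = plus)),
                       dense_track(list(chr1 = minus)))
  pk1 <- random_interval_set(25, chrom_len = 3000, max_len = 150,
                             chrom_sizes = cs)
  pk2 <- random_interval_set(25, chrom_len = 3000, max_len = 150,
                             chrom_sizes = cs)
  tab <- build_features(crms,
                        list(ATAC = list(peaks = pk1, track = tr1, flank = 0),
                             dREG = list(peaks = pk2, track = st, flank = 50)),
                        chrom_sizes = cs)
  for (i in 1:2) {
    for (assay in c("ATAC", "dREG")) {
      pk <- if (assay == "ATAC") pk1 else pk2
      fl <- if (assay == "ATAC") 0 else 50
      w <- crm_windows(crms[i, ], pk, flank = fl)[[crms$id[i]]]
      if (nrow(w) == 0) {
        expect_equal(tab[[paste0(assay, "_sum")]][i], 0)
        next
      }
      if (assay == "ATAC") {
        s <- oracle_query(vals1, w$start, w$end, "sum")
        m <- oracle_query(vals1, w$start, w$end, "max")
      } else {
        s <- oracle_query(plus, w$start, w$end, "sum") +
          oracle_query(minus, w$start, w$end, "sum")
        m <- pmax(oracle_query(plus, w$start, w$end, "max"),
                  oracle_query(minus, w$start, w$end, "max"))
      }
      expect_equal(tab[[paste0(assay, "_sum")]][i], sum(s))
      expect_equal(tab[[paste0(assay, "_max")]][i], sum(m))
    }
  }
  expect_error(build_features(crms, list(ATAC = list(peaks = pk1))), "ATAC")
})

test_that("feature monotonicity: adding in-window signal never lowers sums", {
  cs <- c(chr1 = 2000)
  crms <- data.frame(id = "c1", chrom = "chr1", start = 0, end = 1000)
  peaks <- iset("chr1", 100, 300, chrom_sizes = cs)
  base_vals <- runif(2000)
  t1 <- dense_track(list(chr1 = base_vals))
  extra <- numeric(2000); extra[150:250] <- 5
  t2 <- dense_track(list(chr1 = base_vals + extra))
  f1 <- build_features(crms, list(A = list(peaks = peaks, track = t1)),
                       chrom_sizes = cs)
  f2 <- build_features(crms, list(A = list(peaks = peaks, track = t2)),
                       chrom_sizes = cs)
  expect_gt(f2$A_sum, f1$A_sum)
  expect_gte(f2$A_max, f1$A_max)
})

test_that("promoter windows are 200 bp centered on the TSS, clamped", {
  tss <- data.frame(chrom = "chr1", pos = c(1000, 40, 40),
                    strand = c("+", "-", "+"),
                    transcript_id = c("t1", "t2", "t3"))
  w <- promoter_windows(tss, chrom_sizes = c(chr1 = 5000))
  expect_equal(w$start, c(0, 0, 900))
  expect_equal(w$end, c(140, 140, 1100))
  expect_equal(nrow(w), 3)  # shared TSSs keep duplicate windows
})

test_that("activity labels use the inclusive 2x basal threshold", {
  expect_equal(label_activity(c(0.5, 1, 1.999, 2, 3.7)),
               c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_error(label_activity(c(1, -0.1)), "non-negative")
  set.seed(33)
  expr <- c(runif(90, 0, 1.99), runif(10, 2, 8))[sample(100)]
  expect_equal(mean(label_activity(expr)), 0.10)
})

test_that("ranked expression orders by descending value with id tie-break", {
  crms <- data.frame(id = c("b", "a", "c"),
                     expr_12h = c(3, 0.5, 2), expr_24h = c(1, 1, 1))
  r <- rank_expression(crms, "12h")
  expect_equal(r$expr, c(3, 2, 0.5))
  expect_equal(r$active, c(TRUE, TRUE, FALSE))
  r24 <- rank_expression(crms, "24h")
  expect_equal(r24$id, c("a", "b", "c"))  # tie rule
  expect_equal(attr(r, "baseline"), 1)
  set.seed(34)
  crms2 <- data.frame(id = sprintf("x%03d", 1:50), expr_12h = runif(50, 0, 5),
                      expr_24h = 1)
  r2 <- rank_expression(crms2, "12h")
  expect_equal(r2$expr, sort(crms2$expr_12h, decreasing = TRUE))
})

test_that("CRM and TSS tables round-trip and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  crms <- data.frame(id = c("c1", "c2"), chrom = "chr1", start = c(0, 100),
                     end = c(50, 200), expr_12h = c(1, 3), expr_24h = c(2, 0.4),
                     orientation = c(NA, "divergent"))
  write_crm_table(crms, path)
  back <- read_crm_table(path)
  expect_equal(back$expr_24h, crms$expr_24h)
  crms$expr_12h[1] <- -1
  write_crm_table(crms, path)
  expect_error(read_crm_table(path), ">= 0")

  tss <- data.frame(chrom = "chr1", pos = 10L, strand = "+",
                    transcript_id = "t1")
  write_tss_table(tss, path)
  expect_equal(read_tss_table(path), tss)
})

test_that("active CRMs carry higher signal than inactive ones (synthetic)", {
  tab <- bundle_features(get_default_bundle(), "20h")
  expect_true(all(c("ATAC_sum", "dREG_sum", "PolII_sum", "active",
                    "promoter_overlap") %in% names(tab)))
  for (assay in c("ATAC_sum", "dREG_sum", "PolII_sum")) {
    p <- stats::wilcox.test(tab[[assay]][tab$active],
                            tab[[assay]][!tab$active],
                            alternative = "greater")$p.value
    expect_lt(p, 0.01)
  }
})
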