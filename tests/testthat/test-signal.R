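test_that("bedGraph parsing populates per-base values with zero gaps", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t10\t2.0", path)
  tr <- read_bedgraph(path)
  expect_equal(tr$total_signal, 20)
  expect_equal(track_query(tr, iset("chr1", 0, 10))$aggregate, 20)
  expect_equal(track_query(tr, iset("chr1", 3, 5))$per_interval, 4)

  writeLines(character(0), path)
  empty <- read_bedgraph(path, chrom_sizes = c(chr1 = 100))
  expect_equal(empty$total_signal, 0)

  writeLines(c("chr1\t0\t10\t1", "chr1\t5\t15\t2"), path)
  expect_error(read_bedgraph(path), "overlapping")

  # minus-strand dialect: all-non-positive values are negated to magnitudes
  writeLines(c("chr1\t0\t5\t-2", "chr1\t10\t12\t-1"), path)
  neg <- read_bedgraph(path)
  expect_equal(neg$total_signal, 12)
  writeLines(c("chr1\t0\t5\t-2", "chr1\t10\t12\t1"), path)
  expect_error(read_bedgraph(path), "mixes")
})

test_that("bedGraph write/read round-trips values at run boundaries", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  tr <- dense_track(list(chr1 = c(0, 0, 1.5, 1.5, 0, 2, 0.25, 0, 0),
                         chr2 = c(3, 3, 3)))
  write_bedgraph(tr, path)
  back <- read_bedgraph(path, chrom_sizes = c(chr1 = 9, chr2 = 3))
  expect_equal(as.numeric(back$data$chr1), as.numeric(tr$data$chr1))
  expect_equal(as.numeric(back$data$chr2), as.numeric(tr$data$chr2))
  expect_equal(back$total_signal, tr$total_signal)
})

test_that("RPM normalization scales by 1e6 over the library total", {
  tr <- dense_track(list(chr1 = rep(2, 10)))  # total 20
  half <- rpm_normalize(tr, library_total = 2e6)
  expect_equal(as.numeric(half$data$chr1), rep(1, 10))
  ident <- rpm_normalize(tr, library_total = 1e6)
  expect_equal(as.numeric(ident$data$chr1), rep(2, 10))
  expect_true(ident$normalized)
  expect_error(rpm_normalize(tr, library_total = 0), "> 0")
  # relative values conserved
  tr2 <- dense_track(list(chr1 = c(1, 4, 0, 2)))
  nn <- rpm_normalize(tr2)
  v <- as.numeric(nn$data$chr1)
  expect_equal(v[2] / v[1], 4)
})

test_that("stranded RPM uses the combined plus+minus library total", {
  plus <- dense_track(list(chr1 = rep(3, 1000)))   # 3e3
  minus <- dense_track(list(chr1 = rep(1, 1000)))  # 1e3
  st <- stranded_track(plus, minus)
  nn <- rpm_normalize(st)  # combined total 4000 -> factor 250
  expect_equal(as.numeric(nn$plus$data$chr1)[1], 3 * 1e6 / 4000)
  expect_equal(as.numeric(nn$minus$data$chr1)[1], 1 * 1e6 / 4000)
})

test_that("sum and max queries match the per-base loop oracle", {
  expect_equal(track_query(dense_track(list(chr1 = rep(1, 10))),
                           iset("chr1", 2, 5), "sum")$per_interval, 3)
  expect_equal(track_query(dense_track(list(chr1 = rep(1, 10))),
                           iset("chr1", 2, 5), "max")$per_interval, 1)
  empty <- interval_set(character(), numeric(), numeric())
  tr <- dense_track(list(chr1 = rep(1, 10)))
  expect_equal(track_query(tr, empty, "sum")$aggregate, 0)
  expect_equal(track_query(tr, empty, "max")$aggregate, 0)
  expect_error(track_query(tr, iset("chrX", 0, 5)), "unknown")

  set.seed(21)
  vals <- rpois(2000, 0.5) * runif(2000)
  tr <- dense_track(list(chr1 = vals))
  q <- random_interval_set(50, chrom_len = 2000, max_len = 100)
  for (stat in c("sum", "max")) {
    got <- track_query(tr, q, stat)
    expect_equal(got$per_interval, oracle_query(vals, q$start, q$end, stat))
    expect_equal(got$aggregate, sum(got$per_interval))
  }
})

test_that("stranded queries sum strands for sum and take max across strands", {
  plus <- dense_track(list(chr1 = rep(1, 20)))
  minus <- dense_track(list(chr1 = rep(2, 20)))
  st <- stranded_track(plus, minus)
  expect_equal(stranded_query(st, iset("chr1", 0, 10), "sum")$per_interval, 30)
  expect_equal(stranded_query(st, iset("chr1", 0, 10), "max")$per_interval, 2)
  # all-zero minus reduces to the unstranded query
  z <- stranded_track(plus, dense_track(list(chr1 = rep(0, 20))))
  q <- iset("chr1", c(0, 5), c(4, 12))
  expect_equal(stranded_query(z, q, "sum")$per_interval,
               track_query(plus, q, "sum")$per_interval)
  set.seed(22)
  vp <- rpois(1000, 1) * runif(1000)
  vm <- rpois(1000, 1) * runif(1000)
  st <- stranded_track(dense_track(list(chr1 = vp)),
                       dense_track(list(chr1 = vm)))
  q <- random_interval_set(30, chrom_len = 1000, max_len = 60)
  expect_equal(stranded_query(st, q, "sum")$per_interval,
               oracle_query(vp, q$start, q$end, "sum") +
                 oracle_query(vm, q$start, q$end, "sum"))
  expect_equal(stranded_query(st, q, "max")$per_interval,
               pmax(oracle_query(vp, q$start, q$end, "max"),
                    oracle_query(vm, q$start, q$end, "max")))
})

test_that("query invariants: additivity and merge inequality", {
  set.seed(23)
  vals <- runif(1000)
  tr <- dense_track(list(chr1 = vals))
  # additivity over a disjoint partition
  whole <- track_query(tr, iset("chr1", 100, 400), "sum")$per_interval
  parts <- track_query(tr, iset("chr1", c(100, 250), c(250, 400)),
                       "sum")$per_interval
  expect_equal(sum(parts), whole)
  # sum over merge(S) <= sum over S, equality iff disjoint
  s <- iset("chr1", c(0, 50, 200), c(100, 150, 300))
  expect_lt(track_query(tr, merge_intervals(s), "sum")$aggregate,
            track_query(tr, s, "sum")$aggregate)
  d <- iset("chr1", c(0, 200), c(100, 300))
  expect_equal(track_query(tr, merge_intervals(d), "sum")$aggregate,
               track_query(tr, d, "sum")$aggregate)
})

test_that("replicate correlation recovers the generating correlation", {
  peaks <- iset("chr1", seq(0, 4990, by = 10), seq(10, 5000, by = 10))
  v <- runif(5000)
  a <- dense_track(list(chr1 = v))
  expect_equal(replicate_correlation(a, a, peaks)$pearson, 1)
  b2 <- dense_track(list(chr1 = 2 * v))
  expect_equal(replicate_correlation(a, b2, peaks)$pearson, 1)
  expect_error(replicate_correlation(a, a, iset("chr1", 0, 10)), ">= 3")
  expect_warning(
    rc <- replicate_correlation(dense_track(list(chr1 = rep(1, 5000))),
                                a, peaks), "zero-variance")
  expect_true(is.na(rc$pearson))

  # synthetic replicate pair with known per-peak correlation 0.9:
  # per-peak totals X = Z + e1, Y = Z + e2 with var ratio set for rho = 0.9
  set.seed(24)
  n <- 500
  z <- rnorm(n, 10, 3)
  sd_e <- sqrt(9 * (1 - 0.9) / 0.9)
  x <- pmax(z + rnorm(n, 0, sd_e), 0)
  y <- pmax(z + rnorm(n, 0, sd_e), 0)
  peaks <- iset("chr1", seq(0, by = 10, length.out = n) * 2,
                seq(0, by = 10, length.out = n) * 2 + 10)
  # lay each per-peak total uniformly over its 10-bp peak
  mk <- function(tot) {
    vals <- numeric(10000)
    for (i in seq_len(n)) vals[(peaks$start[i] + 1):peaks$end[i]] <- tot[i] / 10
    dense_track(list(chr1 = vals))
  }
  rc <- replicate_correlation(mk(x), mk(y), peaks)
  expect_equal(rc$n, n)
  expect_lt(abs(rc$pearson - 0.9), 0.05)
})
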