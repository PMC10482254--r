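test_that("marker compatibility follows the shared-allele rule", {
  ped <- tiny_ped()
  m <- tibble::tibble(chrom = "1", pos = c(1, 2),
                      A1 = c("A/B", "A/B"), A2 = c("A/B", "B/B"),
                      A3 = c("A/B", "A/B"),
                      U1 = "B/B", U2 = "B/B", U3 = "B/B")
  expect_equal(marker_compatible(m, ped), c(TRUE, FALSE))
  expect_error(marker_compatible(m, tiny_ped(aff = character())), "affected")
})

test_that("marker compatibility matches the brute-force allele loop on random markers", {
  ped <- tiny_ped()
  aff <- affected_ids(ped); unaff <- unaffected_ids(ped)
  set.seed(101)
  for (i in 1:1000) {
    g <- random_marker_genotypes(sample(2:4, 1), aff, unaff)
    m <- tibble::tibble(chrom = "1", pos = 1)
    for (id in names(g)) m[[id]] <- g[[id]]
    expect_equal(marker_compatible(m, ped, "compatible"),
                 oracle_marker_compatible(g, aff, unaff),
                 info = paste("marker", i))
    # under the strict policy any missing genotype vetoes the marker
    expect_equal(marker_compatible(m, ped, "incompatible"),
                 if (anyNA(g)) FALSE else oracle_marker_compatible(g, aff, unaff),
                 info = paste("marker strict", i))
  }
})

test_that("scan regions equal brute-force maximal runs at zero error tolerance", {
  ped <- tiny_ped()
  aff <- affected_ids(ped); unaff <- unaffected_ids(ped)
  set.seed(202)
  for (rep in 1:200) {
    m <- dplyr::bind_rows(lapply(c("1", "2", "3"), function(ch) {
      rows <- lapply(1:50, function(i) {
        g <- random_marker_genotypes(sample(2:4, 1), aff, unaff, miss_rate = 0.05)
        c(list(chrom = ch, pos = i * 1000), as.list(g))
      })
      dplyr::bind_rows(rows)
    }))
    scan <- scan_regions(m, ped, scan_params(max_errors = 0, min_markers = 1))
    compat <- marker_compatible(m, ped, "compatible")
    expected <- dplyr::bind_rows(lapply(c("1", "2", "3"), function(ch) {
      sel <- m$chrom == ch
      runs <- oracle_runs(compat[sel])
      if (!nrow(runs)) return(NULL)
      tibble::tibble(chrom = ch, start = m$pos[sel][runs[, "start"]],
                     end = m$pos[sel][runs[, "end"]])
    }))
    got <- tidy(scan)[, c("chrom", "start", "end")]
    if (is.null(expected) || !nrow(expected)) {
      expect_equal(nrow(got), 0, info = paste("matrix", rep))
    } else {
      expect_equal(as.data.frame(got), as.data.frame(expected),
                   info = paste("matrix", rep))
    }
  }
})

test_that("an all-compatible chromosome yields one region per boundary mode", {
  ped <- tiny_ped()
  m <- tibble::tibble(chrom = "1", pos = c(10, 20, 30, 40),
                      A1 = "A/B", A2 = "A/B", A3 = "A/B",
                      U1 = "B/B", U2 = "B/B", U3 = "B/B")
  inner <- scan_regions(m, ped, scan_params(min_markers = 1, boundary = "inner"))
  expect_equal(nrow(inner), 1)
  expect_equal(c(inner$start, inner$end), c(10, 40))
  outer <- scan_regions(m, ped, scan_params(min_markers = 1, boundary = "outer"))
  expect_equal(c(outer$start, outer$end), c(10, 40))  # no flanking markers

  # flanked run: outer boundaries sit on the incompatible neighbours
  m2 <- m
  m2$A2 <- c("B/B", "A/B", "A/B", "B/B")
  outer2 <- scan_regions(m2, ped, scan_params(min_markers = 1, boundary = "outer"))
  expect_equal(c(outer2$start, outer2$end), c(10, 40))
  inner2 <- scan_regions(m2, ped, scan_params(min_markers = 1, boundary = "inner"))
  expect_equal(c(inner2$start, inner2$end), c(20, 30))
})

test_that("no compatible markers yields an empty region list", {
  ped <- tiny_ped()
  m <- tibble::tibble(chrom = "1", pos = c(10, 20),
                      A1 = "A/B", A2 = "B/B", A3 = "A/B",
                      U1 = "B/B", U2 = "B/B", U3 = "B/B")
  scan <- scan_regions(m, ped, scan_params(min_markers = 1))
  expect_equal(nrow(scan), 0)
  expect_false(evaluate_scan(scan, "1", 15, 1e6)$covered)
  expect_equal(evaluate_scan(scan, "1", 15, 1e6)$genome_fraction_linked, 0)
  expect_error(scan_regions(m[c(2, 1), ], ped, scan_params()), "sorted")
})

test_that("every marker inside a zero-tolerance region re-checks as compatible", {
  set.seed(7)
  sim <- simulate_family(small_sim_config(seed = 7, n_background_variants = 0))
  scan <- scan_regions(sim$markers, sim$pedigree,
                       scan_params(max_errors = 0, min_markers = 1,
                                   missing = "incompatible"))
  compat <- marker_compatible(sim$markers, sim$pedigree, "incompatible")
  for (i in seq_len(nrow(scan))) {
    sel <- sim$markers$chrom == scan$chrom[i] &
      sim$markers$pos >= scan$start[i] & sim$markers$pos <= scan$end[i]
    expect_true(all(compat[sel]))
  }
})

test_that("regions never shrink as the error tolerance grows", {
  ped <- tiny_ped()
  set.seed(303)
  for (rep in 1:20) {
    rows <- lapply(1:60, function(i) {
      g <- random_marker_genotypes(sample(2:4, 1), affected_ids(ped),
                                   unaffected_ids(ped))
      c(list(chrom = "1", pos = i * 100), as.list(g))
    })
    m <- dplyr::bind_rows(rows)
    prev <- scan_regions(m, ped, scan_params(max_errors = 0, min_markers = 1))
    for (k in 1:3) {
      cur <- scan_regions(m, ped, scan_params(max_errors = k, min_markers = 1))
      for (i in seq_len(nrow(prev))) {
        contained <- any(cur$chrom == prev$chrom[i] &
                           cur$start <= prev$start[i] & cur$end >= prev$end[i])
        expect_true(contained, info = paste("rep", rep, "k", k, "region", i))
      }
      prev <- cur
    }
  }
})

test_that("the causal marker always falls inside a reported region on error-free families", {
  for (s in 1:25) {
    sim <- simulate_family(small_sim_config(seed = 1000 + s, n_background_variants = 0))
    scan <- scan_regions(sim$markers, sim$pedigree, scan_params(min_markers = 1))
    ev <- evaluate_scan(scan, sim$truth$causal$chrom, sim$truth$causal$pos,
                        sim$truth$genome_bp)
    expect_true(ev$covered, info = paste("seed", 1000 + s))
  }
})

test_that("more unaffected members shrink the linked genome fraction", {
  frac <- function(drop_unaff) {
    mean(vapply(1:15, function(s) {
      cfg <- small_sim_config(seed = 500 + s, n_background_variants = 0)
      sim <- simulate_family(cfg)
      ped <- sim$pedigree
      if (drop_unaff) ped$sequenced[ped$id %in% c("I-2", "II-2")] <- FALSE
      scan <- scan_regions(sim$markers, pedigree(ped), scan_params(min_markers = 1))
      evaluate_scan(scan, sim$truth$causal$chrom, sim$truth$causal$pos,
                    sim$truth$genome_bp)$genome_fraction_linked
    }, numeric(1)))
  }
  expect_lt(frac(FALSE), frac(TRUE))
})
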