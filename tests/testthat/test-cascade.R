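cfg <- cascade_config()

test_that("genotype QC enforces the published read-support thresholds", {
  calls <- dplyr::bind_rows(
    make_call_row("low_cov", depth = 9, alt_reads = 5, seed_support = 3,
                  clonal_reads = 0),
    make_call_row("clean", depth = 20, alt_reads = 10, seed_support = 3,
                  clonal_reads = 2),
    make_call_row("low_frac", depth = 20, alt_reads = 2, seed_support = 2),
    make_call_row("high_frac", depth = 10, alt_reads = 9, seed_support = 8,
                  clonal_reads = 0)
  )
  qc <- qc_pass(calls, cfg)
  expect_equal(qc$pass, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(qc$reason[c(1, 3, 4)],
               c("coverage", "alt_fraction_low", "alt_fraction_high"))
  # fraction bounds are inclusive
  edge <- qc_pass(dplyr::bind_rows(
    make_call_row("lo", depth = 20, alt_reads = 3, seed_support = 3),   # 15%
    make_call_row("hi", depth = 20, alt_reads = 16, seed_support = 10)  # 80%
  ), cfg)
  expect_true(all(edge$pass))
  expect_error(
    qc_pass(make_call_row("bad", depth = 0, alt_reads = 3), cfg),
    "data error"
  )
})

test_that("clonal pile-ups fail through the clonality-capped depth", {
  call <- make_call_row("clonal", depth = 13, alt_reads = 6, seed_support = 5,
                        clonal_reads = 10)
  qc <- qc_pass(call, cfg)
  expect_equal(qc$eff_depth, 8)  # 13 - (10 - 5)
  expect_false(qc$pass)
  expect_equal(qc$reason, "coverage")
})

test_that("consequence filter keeps the published classes and caps indel length", {
  v <- dplyr::bind_rows(
    make_variant(gene = "GRINA", consequence = "missense"),
    make_variant(pos = 1949897, chrom = "12", gene = "CACNA2D4",
                 consequence = "splice_site"),
    make_variant(pos = 2, gene = "SYN", consequence = "other"),
    make_variant(pos = 3, gene = "LONGDEL", consequence = "frameshift_indel",
                 indel_length = 9),
    make_variant(pos = 4, gene = "OKDEL", consequence = "frameshift_indel",
                 indel_length = 7),
    make_variant(pos = 5, gene = "NOANN", consequence = NA)
  )
  res <- consequence_pass(v, cfg)
  expect_equal(res$pass, c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(res$reason[c(3, 4, 6)],
               c("consequence_class", "indel_length", "unannotated"))
})

test_that("rarity filter applies the strict 0.002 threshold and the in-house cap", {
  v <- dplyr::bind_rows(
    make_variant(gene = "GRINA", ac_gnomad = 2, an_gnomad = 282710),
    make_variant(pos = 2, gene = "MYO15A", ac_gnomad = 513, an_gnomad = 280690),
    make_variant(pos = 3, gene = "COMMON", ac_gnomad = 600, an_gnomad = 280000),
    make_variant(pos = 4, gene = "INHOUSE", inhouse = 3),
    make_variant(pos = 5, gene = "NOFREQ", ac_gnomad = NA, an_gnomad = NA)
  )
  res <- rarity_pass(v, cfg)
  expect_equal(res$pass, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$reason[3:4], c("population_frequency", "inhouse_count"))
  strict <- cascade_config(missing_freq_policy = "fail")
  expect_false(rarity_pass(v[5, ], strict)$pass)
  bad <- make_variant(pos = 6, ac_gnomad = 0, an_gnomad = 0)
  expect_error(rarity_pass(bad, cfg), "AN = 0")
})

test_that("cosegregation requires het in all affected and absence in all unaffected", {
  ped <- fixture_ped()
  ok <- make_variant(ped = ped)
  expect_true(cosegregation_pass(ok, ped, cfg)$pass)

  calls2 <- ok$calls[[1]]
  calls2[calls2$sample_id == "III-1",
         c("gt", "carries_alt", "het_alt", "alt_reads", "seed_support")] <-
    list("0/0", FALSE, FALSE, 0, 0)
  miss_aff <- make_variant(ped = ped, calls = calls2)
  expect_false(cosegregation_pass(miss_aff, ped, cfg)$pass)

  calls3 <- ok$calls[[1]]
  calls3[calls3$sample_id == "III-2",
         c("gt", "carries_alt", "het_alt", "alt_reads", "seed_support")] <-
    list("0/1", TRUE, TRUE, 20, 16)
  carrier_unaff <- make_variant(ped = ped, calls = calls3)
  expect_false(cosegregation_pass(carrier_unaff, ped, cfg)$pass)

  # hom-alt affected members violate the heterozygous dominant model
  calls4 <- ok$calls[[1]]
  calls4[calls4$sample_id == "III-1", c("gt", "het_alt")] <- list("1/1", FALSE)
  expect_false(cosegregation_pass(make_variant(ped = ped, calls = calls4),
                                  ped, cfg)$pass)
})

test_that("missing calls obey the missing-call policy", {
  ped <- fixture_ped()
  v <- make_variant(ped = ped)
  calls <- v$calls[[1]]
  calls[calls$sample_id == "II-2",
        c("gt", "carries_alt", "het_alt", "depth", "alt_reads",
          "seed_support", "clonal_reads")] <-
    list(NA_character_, NA, NA, NA_real_, NA_real_, NA_real_, NA_real_)
  v2 <- make_variant(ped = ped, calls = calls)
  expect_false(cosegregation_pass(v2, ped, cascade_config())$pass)
  expect_true(cosegregation_pass(
    v2, ped, cascade_config(missing_call_policy = "ignore_sample"))$pass)
})

test_that("region membership matches a brute-force interval lookup", {
  regs <- fixture_regions()
  expect_true(region_pass(make_variant(chrom = "2", pos = 150000000), regs))
  expect_false(region_pass(make_variant(chrom = "2", pos = 146360625), regs))
  expect_true(region_pass(make_variant(chrom = "2", pos = 146360626), regs))
  set.seed(404)
  chroms <- sample(unique(regs$chrom), 10000, replace = TRUE)
  pos <- round(runif(10000, 1, 2.3e8))
  got <- in_region(regs, chroms, pos)
  brute <- vapply(seq_along(pos), function(i) {
    hit <- FALSE
    for (j in seq_len(nrow(regs))) {
      if (regs$chrom[j] == chroms[i] && regs$start[j] <= pos[i] &&
          regs$end[j] >= pos[i]) hit <- TRUE
    }
    hit
  }, logical(1))
  expect_equal(got, brute)
})

test_that("the packaged candidates plus decoys funnel as designed", {
  ped <- fixture_ped()
  regs <- fixture_regions()
  v <- fixture_variants(ped)
  decoys <- make_decoy_set(v, ped, regs, n = 20)
  expect_equal(nrow(decoys), 20)
  res <- run_cascade(dplyr::bind_rows(v, decoys), ped, regs)

  # every decoy dies at exactly the stage its construction targets
  stage_of <- c(QC = "qc", CLASS = "class_rarity", ABSENT = "absent_unaffected",
                PRESENT = "present_affected", POPFREQ = "popfreq",
                REGION = "region")
  fails <- dplyr::filter(res$trace, !pass)
  for (i in seq_len(nrow(decoys))) {
    want <- stage_of[[strsplit(decoys$gene[i], "_")[[1]][2]]]
    got <- fails$stage[fails$variant_id == decoys$variant_id[i]]
    expect_equal(got, want, info = decoys$gene[i])
  }
  # candidates survive iff they lie inside a packaged linked region
  in_reg <- v$variant_id[region_pass(v, regs)]
  expect_setequal(res$survivors$variant_id, in_reg)
  # decoys alone leave no survivors
  expect_equal(nrow(run_cascade(decoys, ped, regs)$survivors), 0)
})

test_that("trace counts are non-increasing and stop at the first failure", {
  ped <- fixture_ped()
  regs <- fixture_regions()
  v <- fixture_variants(ped)
  decoys <- make_decoy_set(v, ped, regs, n = 20)
  res <- run_cascade(dplyr::bind_rows(v, decoys), ped, regs)
  expect_true(all(diff(res$counts$n_out) <= 0))
  expect_true(all(res$counts$n_out <= res$counts$n_in))
  per_var <- dplyr::group_by(res$trace, variant_id)
  per_var <- dplyr::summarise(per_var, nfail = sum(!pass),
                              last_is_fail = !pass[dplyr::n()])
  expect_true(all(per_var$nfail <= 1))
  expect_true(all(per_var$last_is_fail | per_var$nfail == 0))
  # empty input: all stage counts zero
  empty <- run_cascade(v[0, ], ped, regs)
  expect_true(all(empty$counts$n_in == 0) && all(empty$counts$n_out == 0))
})

test_that("cascade output is independent of input record order", {
  ped <- fixture_ped()
  regs <- fixture_regions()
  v <- dplyr::bind_rows(fixture_variants(ped),
                        make_decoy_set(fixture_variants(ped), ped, regs, n = 12))
  set.seed(9)
  shuffled <- v[sample(nrow(v)), ]
  r1 <- run_cascade(v, ped, regs)
  r2 <- run_cascade(shuffled, ped, regs)
  expect_equal(r1$survivors$variant_id, r2$survivors$variant_id)
  expect_equal(r1$counts, r2$counts)
})

test_that("tightening any single threshold never enlarges the survivor set", {
  ped <- fixture_ped()
  regs <- fixture_regions()
  v <- dplyr::bind_rows(fixture_variants(ped),
                        make_decoy_set(fixture_variants(ped), ped, regs, n = 16))
  base <- run_cascade(v, ped, regs, cascade_config())$survivors$variant_id
  tighter <- list(
    cascade_config(min_depth = 30),
    cascade_config(min_seed_support = 10),
    cascade_config(min_alt_fraction = 0.4),
    cascade_config(max_alt_fraction = 0.55),
    cascade_config(max_clonal_reads = 0),
    cascade_config(max_indel_nt = 2),
    cascade_config(allowed_consequences = c("nonsense", "missense")),
    cascade_config(max_pop_af = 2e-5),
    cascade_config(max_inhouse = 0)
  )
  for (tcfg in tighter) {
    surv <- run_cascade(v, ped, regs, tcfg)$survivors$variant_id
    expect_true(all(surv %in% base))
  }
})

test_that("the implanted causal variant is recovered and dropout degrades recovery", {
  recover_rate <- function(dropout, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_family(small_sim_config(
        seed = s, genotype_dropout_rate = dropout, n_background_variants = 10))
      scan <- scan_regions(sim$markers, sim$pedigree, scan_params(min_markers = 1))
      res <- run_cascade(sim$variants, sim$pedigree, scan, cascade_config())
      sim$truth$causal$variant_id %in% res$survivors$variant_id
    }, logical(1)))
  }
  expect_equal(recover_rate(0, 1:20), 1)
  expect_lt(recover_rate(0.35, 1:20), 1)
})
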