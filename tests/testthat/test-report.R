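test_that("damage tier is total over the prediction vocabulary", {
  pp <- c("benign", "possibly_damaging", "probably_damaging", NA)
  si <- c("tolerated", "deleterious", NA)
  grid <- expand.grid(pp = pp, si = si, stringsAsFactors = FALSE)
  tiers <- damage_tier(grid$pp, grid$si)
  expect_false(any(is.na(tiers)))
  expect_true(all(tiers %in% c("concordant_damaging", "concordant_benign",
                               "discordant", "undefined")))
  expect_equal(damage_tier("probably_damaging", "deleterious"), "concordant_damaging")
  expect_equal(damage_tier("benign", "tolerated"), "concordant_benign")
  expect_equal(damage_tier(NA_character_, NA_character_), "undefined")
  expect_equal(damage_tier("benign", "deleterious"), "discordant")
  expect_error(damage_tier("awful", "deleterious"), "vocabulary")
})

test_that("packaged annotations give the published concordance calls", {
  ann <- read_annotations(cosegr_example("candidate_annotations.tsv"))
  tiers <- setNames(damage_tier(ann$polyphen_class, ann$sift_class), ann$gene)
  expect_equal(tiers[["GRINA"]], "concordant_damaging")
  expect_equal(tiers[["RABEPK"]], "concordant_damaging")
  expect_equal(tiers[["OR1J1"]], "concordant_benign")
  expect_equal(tiers[["CACNA2D4"]], "undefined")  # splice site, no predictions
  expect_equal(tiers[["MYO15A"]], "undefined")    # SIFT undefined
  expect_equal(tiers[["OR8D4"]], "discordant")
})

test_that("developmental window flag detects elevated early expression, not flat genes", {
  expr <- expression_fixture()
  res <- developmental_window_flag(expr, window = c(0.1, 2.4), z_threshold = 1)
  expect_true(res$flag[res$gene == "DEVUP"])
  expect_false(res$flag[res$gene == "FLAT"])
  expect_equal(res$note[res$gene == "FLAT"], "constant")

  # hand-computed z contrast for the elevated gene
  d <- expr[expr$gene == "DEVUP", ]
  y <- log2(d$value + 1)
  z <- (y - mean(y)) / sd(y)
  win <- d$age >= 0.1 & d$age <= 2.4
  expect_equal(res$contrast[res$gene == "DEVUP"],
               mean(z[win]) - mean(z[!win]), tolerance = 1e-12)

  expect_error(developmental_window_flag(expr, genes = "NOPE"), "absent")
})

test_that("the window contrast is invariant to monotone power-law rescaling", {
  expr <- expression_fixture()
  base <- developmental_window_flag(expr, genes = "DEVUP", pseudocount = 0)
  scaled <- dplyr::mutate(expr, value = 7 * value)
  powered <- dplyr::mutate(expr, value = value^1.8)
  for (tx in list(scaled, powered)) {
    res <- developmental_window_flag(tx, genes = "DEVUP", pseudocount = 0)
    expect_equal(res$contrast, base$contrast, tolerance = 1e-9)
  }
})

test_that("permutation of sample ages calibrates the flag rate", {
  expr <- expression_fixture()
  d <- expr[expr$gene == "NULL1", ]
  set.seed(11)
  contrasts <- vapply(1:400, function(i) {
    perm <- dplyr::mutate(d, age = sample(age))
    developmental_window_flag(perm, genes = "NULL1")$contrast
  }, numeric(1))
  thr <- quantile(contrasts, 0.95)
  flagged <- mean(contrasts > thr)
  expect_lte(flagged, 0.06)
  # at the permutation-calibrated threshold the true signal still flags
  real <- developmental_window_flag(expr, genes = "DEVUP", z_threshold = thr)
  expect_true(real$flag)
})

test_that("the candidate report reproduces the published table structure", {
  ped <- fixture_ped()
  v <- fixture_variants(ped)
  ann <- read_annotations(cosegr_example("candidate_annotations.tsv"))
  rep <- build_report(v, annotations = ann)
  expect_equal(nrow(rep), 11)
  expect_equal(rep$damage_tier[rep$gene == "GRINA"], "concordant_damaging")
  expect_true(all(rep$af_gnomad < 0.002))
  expect_true(all(c("evs", "gonl", "exac") %in% names(rep)))

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, tmp)
  back <- read_report(tmp)
  expect_equal(names(back), names(rep))
  expect_equal(back$gene, rep$gene)
  expect_equal(back$af_gnomad, rep$af_gnomad)

  # empty survivor set: header-only file
  write_report(build_report(v[0, ]), tmp)
  expect_equal(length(readLines(tmp)), 1)

  expect_error(build_report(v, annotations = ann[ann$gene != "GRINA", ]),
               "orphan")
})

test_that("expression flags join the report by gene", {
  ped <- fixture_ped()
  v <- fixture_variants(ped)[1:2, ]  # GRINA, OR1J1
  expr <- dplyr::mutate(expression_fixture(),
                        gene = dplyr::recode(gene, DEVUP = "GRINA",
                                             FLAT = "OR1J1"))
  rep <- build_report(v, expression = expr)
  expect_true(rep$expression_flag[rep$gene == "GRINA"])
  expect_false(rep$expression_flag[rep$gene == "OR1J1"])
})
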