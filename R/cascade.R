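#' Filter cascade configuration
#'
#' Thresholds for the exome filter cascade. Defaults are the published study
#' settings: variants supported by at least two read seeds, a minimum of ten
#' reads of coverage, a non-reference allele fraction between 15% and 80%
#' (inclusive at both ends; the ceiling encodes the heterozygous dominant
#' model), at most five clonal reads counted per site, indels of at most 7 nt,
#' truncating/missense/splice-site consequence classes, a strict population
#' allele-frequency threshold of 0.002, and at most 2 in-house database
#' occurrences.
#'
#' Allele fractions are computed on the clonality-capped depth: reads sharing
#' a start site beyond `max_clonal_reads` are removed from the denominator, so
#' a clonal pile-up fails through the coverage or fraction thresholds.
#'
#' @param min_seed_support Minimum reads whose 25-bp seed supports the variant.
#' @param min_depth Minimum (clonality-capped) coverage.
#' @param min_alt_fraction,max_alt_fraction Inclusive alt-fraction bounds.
#' @param max_clonal_reads Clonal reads counted beyond the first at a start site.
#' @param max_indel_nt Maximum indel length in nucleotides.
#' @param allowed_consequences Retained consequence classes.
#' @param max_pop_af Strict upper bound on AC/AN in every reporting database.
#' @param max_inhouse Maximum in-house occurrence count.
#' @param missing_freq_policy `"pass"` (default): a database with no entry is
#'   no evidence of commonness; `"fail"`: unannotated frequencies fail.
#' @param missing_call_policy `"fail_variant"` (default): a missing genotype
#'   call for a sequenced member fails the variant; `"ignore_sample"`: the
#'   sample is dropped from the cosegregation test.
#' @return A `coseg_config` list.
#' @export
cascade_config <- function(min_seed_support = 2,
                           min_depth = 10,
                           min_alt_fraction = 0.15,
                           max_alt_fraction = 0.80,
                           max_clonal_reads = 5,
                           max_indel_nt = 7,
                           allowed_consequences = c("nonsense", "frameshift_indel",
                                                    "missense", "splice_site"),
                           max_pop_af = 0.002,
                           max_inhouse = 2,
                           missing_freq_policy = c("pass", "fail"),
                           missing_call_policy = c("fail_variant", "ignore_sample")) {
  cfg <- list(
    min_seed_support = min_seed_support,
    min_depth = min_depth,
    min_alt_fraction = min_alt_fraction,
    max_alt_fraction = max_alt_fraction,
    max_clonal_reads = max_clonal_reads,
    max_indel_nt = max_indel_nt,
    allowed_consequences = allowed_consequences,
    max_pop_af = max_pop_af,
    max_inhouse = max_inhouse,
    missing_freq_policy = match.arg(missing_freq_policy),
    missing_call_policy = match.arg(missing_call_policy)
  )
  stopifnot(
    cfg$min_alt_fraction >= 0, cfg$min_alt_fraction < cfg$max_alt_fraction,
    cfg$max_alt_fraction <= 1,
    cfg$min_seed_support >= 0, cfg$min_depth >= 0, cfg$max_clonal_reads >= 0,
    cfg$max_indel_nt >= 0, cfg$max_inhouse >= 0, cfg$max_pop_af > 0,
    all(cfg$allowed_consequences %in% CONSEQUENCES)
  )
  class(cfg) <- "coseg_config"
  cfg
}

CASCADE_STAGES <- c("qc", "class_rarity", "absent_unaffected",
                    "present_affected", "popfreq", "region")

#' Genotype-call quality control
#'
#' Evaluates the per-call QC rule on a calls tibble: seed support, clonality-
#' capped coverage, and the inclusive alt-fraction band (see
#' [cascade_config()]). Missing QC fields fail with reason
#' `"missing_qc_fields"`; a call with `depth == 0` but positive `alt_reads`
#' is a data error.
#'
#' @param calls A calls tibble (see [variant-tables]).
#' @param config A [cascade_config()].
#' @return The calls tibble with added `eff_depth`, `alt_fraction`, `pass`,
#'   `reason` columns.
#' @examples
#' calls <- tibble::tibble(sample_id = "S1", gt = "0/1", carries_alt = TRUE,
#'   het_alt = TRUE, depth = 9, alt_reads = 5, seed_support = 3, clonal_reads = 0)
#' qc_pass(calls, cascade_config())
#' @export
qc_pass <- function(calls, config = cascade_config()) {
  bad <- which(!is.na(calls$depth) & calls$depth == 0 &
                 !is.na(calls$alt_reads) & calls$alt_reads > 0)
  if (length(bad)) {
    abort(paste0("data error: depth 0 with alt reads > 0 for sample ",
                 calls$sample_id[bad[1]]))
  }
  out <- mutate(
    calls,
    eff_depth = .data$depth - pmax(0, .data$clonal_reads - config$max_clonal_reads),
    alt_fraction = ifelse(.data$eff_depth > 0,
                          pmin(.data$alt_reads, .data$eff_depth) / .data$eff_depth,
                          NA_real_)
  )
  reason <- dplyr::case_when(
    is.na(out$depth) | is.na(out$alt_reads) | is.na(out$seed_support) |
      is.na(out$clonal_reads) ~ "missing_qc_fields",
    out$seed_support < config$min_seed_support ~ "seed_support",
    out$eff_depth < config$min_depth ~ "coverage",
    out$alt_fraction < config$min_alt_fraction ~ "alt_fraction_low",
    out$alt_fraction > config$max_alt_fraction ~ "alt_fraction_high",
    TRUE ~ NA_character_
  )
  mutate(out, pass = is.na(reason), reason = reason)
}

#' Consequence-class filter
#'
#' Retains variants whose consequence is in the allowed set and whose indel
#' length does not exceed the caller limit. An unannotated consequence fails
#' with reason `"unannotated"`.
#'
#' @param variants A variants tibble.
#' @param config A [cascade_config()].
#' @return A tibble with `variant_id`, `pass`, `reason`.
#' @export
consequence_pass <- function(variants, config = cascade_config()) {
  reason <- dplyr::case_when(
    is.na(variants$consequence) ~ "unannotated",
    !variants$consequence %in% config$allowed_consequences ~ "consequence_class",
    variants$indel_length > config$max_indel_nt ~ "indel_length",
    TRUE ~ NA_character_
  )
  tibble(variant_id = variants$variant_id, pass = is.na(reason), reason = reason)
}

popfreq_ok <- function(variants, config) {
  # strict AF < max_pop_af in every database with data; missing per policy
  dbs <- popfreq_dbs(variants)
  n <- nrow(variants)
  ok <- rep(TRUE, n)
  seen <- rep(FALSE, n)
  for (db in dbs) {
    ac <- variants[[paste0("ac_", db)]]
    an <- variants[[paste0("an_", db)]]
    has <- !is.na(ac) & !is.na(an)
    if (any(has & an == 0)) {
      abort(paste0("data error: AN = 0 in database ", db))
    }
    seen <- seen | has
    ok <- ok & (!has | ac / an < config$max_pop_af)
  }
  if (config$missing_freq_policy == "fail") ok <- ok & seen
  list(ok = ok, seen = seen)
}

#' Population-rarity filter
#'
#' A variant is retained when its allele frequency `AC/AN` is strictly below
#' `max_pop_af` in every database that reports it and its in-house occurrence
#' count is at most `max_inhouse`. A database with no entry is treated per
#' `missing_freq_policy` (default: absence of evidence of commonness passes).
#'
#' @inheritParams consequence_pass
#' @return A tibble with `variant_id`, `pass`, `reason`.
#' @examples
#' v <- tibble::tibble(variant_id = "x", ac_gnomad = 2, an_gnomad = 282710,
#'                     inhouse = 0)
#' rarity_pass(v)
#' @export
rarity_pass <- function(variants, config = cascade_config()) {
  pf <- popfreq_ok(variants, config)
  inh_ok <- is.na(variants$inhouse) | variants$inhouse <= config$max_inhouse
  reason <- dplyr::case_when(
    !pf$ok & pf$seen ~ "population_frequency",
    !pf$ok ~ "no_frequency_data",
    !inh_ok ~ "inhouse_count",
    TRUE ~ NA_character_
  )
  tibble(variant_id = variants$variant_id, pass = is.na(reason), reason = reason)
}

coseg_one <- function(calls, aff, unaff, config) {
  # returns c(absent_reason, present_reason); NA = pass
  absent_reason <- NA_character_
  present_reason <- NA_character_
  get <- function(ids) calls[match(ids, calls$sample_id), , drop = FALSE]

  u <- get(unaff)
  miss_u <- is.na(u$carries_alt)
  if (any(miss_u, na.rm = TRUE) && config$missing_call_policy == "fail_variant") {
    absent_reason <- "missing_call_unaffected"
  } else if (any(u$carries_alt[!miss_u])) {
    absent_reason <- "carrier_unaffected"
  }

  a <- get(aff)
  miss_a <- is.na(a$carries_alt)
  if (any(miss_a)) {
    if (config$missing_call_policy == "fail_variant") {
      present_reason <- "missing_call_affected"
    }
    a <- a[!miss_a, , drop = FALSE]
  }
  if (is.na(present_reason)) {
    if (!nrow(a) || !all(a$het_alt)) present_reason <- "not_het_all_affected"
  }
  c(absent_reason, present_reason)
}

#' Cosegregation filter under the dominant model
#'
#' A variant cosegregates when every affected sequenced member has a
#' heterozygous, QC-passing call for the alt allele and no unaffected
#' sequenced member carries any copy of it. Missing calls are handled per
#' `missing_call_policy`.
#'
#' @param variants A variants tibble.
#' @param ped A pedigree tibble with at least one affected and one unaffected
#'   sequenced member.
#' @param config A [cascade_config()].
#' @return A tibble with `variant_id`, `pass`, `reason`.
#' @export
cosegregation_pass <- function(variants, ped, config = cascade_config()) {
  aff <- affected_ids(ped)
  unaff <- unaffected_ids(ped)
  if (!length(aff)) abort("cosegregation requires at least one affected sequenced member")
  if (!nrow(variants)) {
    return(tibble(variant_id = character(), pass = logical(), reason = character()))
  }
  res <- map(variants$calls, function(calls) {
    qc <- qc_pass(calls, config)
    carrier_fail <- !is.na(qc$carries_alt) & qc$carries_alt &
      qc$sample_id %in% c(aff, unaff) & !qc$pass
    cs <- coseg_one(calls, aff, unaff, config)
    reason <- dplyr::coalesce(
      cs[2], cs[1],
      ifelse(any(carrier_fail), "carrier_call_fails_qc", NA_character_)
    )
    reason
  })
  reason <- unlist(res)
  tibble(variant_id = variants$variant_id, pass = is.na(reason), reason = reason)
}

#' Linked-region membership filter
#'
#' @param variants A variants tibble.
#' @param regions A regions tibble (1-based inclusive intervals).
#' @return Logical vector: position inside some region on its chromosome.
#' @export
region_pass <- function(variants, regions) {
  in_region(regions, variants$chrom, variants$pos)
}

#' Run the full filter cascade
#'
#' Applies the published stage order with a complete audit trail:
#'
#' 1. `qc` — every sequenced carrier call passes genotype QC;
#' 2. `class_rarity` — allowed consequence class, indel length within the
#'    caller limit, and at most `max_inhouse` in-house occurrences (the
#'    de novo / rare class);
#' 3. `absent_unaffected` — no unaffected sequenced member carries the allele;
#' 4. `present_affected` — every affected sequenced member is heterozygous;
#' 5. `popfreq` — AC/AN strictly below `max_pop_af` in every reporting
#'    population database;
#' 6. `region` — the position lies inside a linked region.
#'
#' A variant failing stage *k* is not evaluated at later stages, so per-stage
#' survivor counts are non-increasing, and the result is independent of input
#' row order.
#'
#' @param variants A variants tibble.
#' @param ped A pedigree tibble.
#' @param regions A regions tibble of linked regions.
#' @param config A [cascade_config()].
#' @return A `coseg_cascade` list with elements `survivors` (variants tibble),
#'   `trace` (tibble `variant_id`, `stage`, `pass`, `reason`) and `counts`
#'   (tibble `stage`, `n_in`, `n_out`). Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
run_cascade <- function(variants, ped, regions, config = cascade_config()) {
  if (!length(affected_ids(ped))) abort("pedigree has no affected sequenced member")
  if (!length(unaffected_ids(ped))) abort("pedigree has no unaffected sequenced member")
  variants <- arrange(as_tibble(variants), .data$chrom, .data$pos, .data$alt)

  active <- variants
  trace <- list()
  counts <- list()
  stage_fns <- list(
    qc = function(v) {
      reason <- map_chr(v$calls, function(calls) {
        qc <- qc_pass(calls, config)
        seqd <- ped$id[ped$sequenced]
        carrier <- !is.na(qc$carries_alt) & qc$carries_alt & qc$sample_id %in% seqd
        bad <- carrier & !qc$pass
        if (any(bad)) paste0("qc:", qc$reason[which(bad)[1]]) else NA_character_
      })
      tibble(variant_id = v$variant_id, pass = is.na(reason), reason = reason)
    },
    class_rarity = function(v) {
      cq <- consequence_pass(v, config)
      inh_ok <- is.na(v$inhouse) | v$inhouse <= config$max_inhouse
      reason <- dplyr::coalesce(cq$reason,
                                ifelse(inh_ok, NA_character_, "inhouse_count"))
      tibble(variant_id = v$variant_id, pass = is.na(reason), reason = reason)
    },
    absent_unaffected = function(v) {
      reason <- map_chr(v$calls, function(calls) {
        coseg_one(calls, affected_ids(ped), unaffected_ids(ped), config)[1]
      })
      tibble(variant_id = v$variant_id, pass = is.na(reason), reason = reason)
    },
    present_affected = function(v) {
      reason <- map_chr(v$calls, function(calls) {
        coseg_one(calls, affected_ids(ped), unaffected_ids(ped), config)[2]
      })
      tibble(variant_id = v$variant_id, pass = is.na(reason), reason = reason)
    },
    popfreq = function(v) {
      pf <- popfreq_ok(v, config)
      reason <- ifelse(pf$ok, NA_character_,
                       ifelse(pf$seen, "population_frequency", "no_frequency_data"))
      tibble(variant_id = v$variant_id, pass = is.na(reason), reason = reason)
    },
    region = function(v) {
      ok <- region_pass(v, regions)
      tibble(variant_id = v$variant_id, pass = ok,
             reason = ifelse(ok, NA_character_, "outside_linked_regions"))
    }
  )

  for (stage in CASCADE_STAGES) {
    n_in <- nrow(active)
    res <- if (n_in) stage_fns[[stage]](active) else
      tibble(variant_id = character(), pass = logical(), reason = character())
    trace[[stage]] <- mutate(res, stage = stage, .after = "variant_id")
    active <- active[res$pass, , drop = FALSE]
    counts[[stage]] <- tibble(stage = stage, n_in = n_in, n_out = nrow(active))
  }

  out <- list(
    survivors = active,
    trace = bind_rows(trace),
    counts = bind_rows(counts),
    config = config
  )
  class(out) <- "coseg_cascade"
  out
}

#' @export
print.coseg_cascade <- function(x, ...) {
  cat("<coseg_cascade>\n")
  cat("Filter funnel (variants in -> out):\n")
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-18s %5d -> %5d\n",
                x$counts$stage[i], x$counts$n_in[i], x$counts$n_out[i]))
  }
  cat(sprintf("Survivors: %d\n", nrow(x$survivors)))
  invisible(x)
}
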