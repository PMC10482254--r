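#' Default six-member pedigree template
#'
#' A three-generation family with three affected members in a
#' grandparent-parent-child chain and three unaffected members (a founder
#' spouse in each generation / an unaffected sib), all sequenced — the
#' affection structure assumed throughout the package's study conditions.
#'
#' @return A `coseg_ped` tibble.
#' @export
default_pedigree_template <- function() {
  pedigree(tibble(
    family = "SIMFAM",
    id = c("I-1", "I-2", "II-1", "II-2", "III-1", "III-2"),
    father = c(NA, NA, "I-2", NA, "II-2", "II-2"),
    mother = c(NA, NA, "I-1", NA, "II-1", "II-1"),
    sex = c("female", "male", "female", "male", "male", "female"),
    affection = c("affected", "unaffected", "affected", "unaffected",
                  "affected", "unaffected"),
    sequenced = TRUE
  ))
}

#' Simulation configuration
#'
#' Parameters of the synthetic-family generator. The defaults emulate the
#' statistical structure the analysis assumes: a six-member dominant pedigree
#' with complete penetrance, SNP markers with Haldane (no-interference)
#' recombination at 1 cM/Mb, and exome-like variant records whose population
#' allele frequencies straddle the 0.002 rarity threshold and whose read
#' support is drawn around the QC cut-offs.
#'
#' @param pedigree Pedigree template ([default_pedigree_template()]); its
#'   affection pattern defines which members must (not) inherit the causal
#'   allele.
#' @param chromosomes Tibble with `label`, `length_bp`, `map_cM`.
#' @param marker_count Markers per chromosome.
#' @param causal_locus `"random"` or a `list(chrom =, pos =)`.
#' @param n_background_variants Background exome variants.
#' @param rare_weight Mixture weight of the rare component of background
#'   allele frequencies (rare: AF ~ U(0, 0.002); common: AF ~ U(0.01, 0.5)).
#' @param depth_mean Poisson mean of per-call read depth.
#' @param het_alt_fraction Binomial success probability for alt reads of a
#'   heterozygote.
#' @param error_rate Per-read error rate generating alt reads on non-carrier
#'   calls.
#' @param seed_fraction Fraction of alt reads whose 25-bp seed supports the
#'   variant.
#' @param clonal_rate Binomial rate of clonal reads per call.
#' @param genotype_dropout_rate Probability that any single genotype (marker
#'   or variant call) is missing.
#' @param database_an Allele number used for the simulated population
#'   database annotation (AC is rounded from the true AF).
#' @param database Name of the simulated population database.
#' @param seed Integer seed governing all randomness.
#' @return A `coseg_sim_config` list.
#' @export
sim_config <- function(pedigree = default_pedigree_template(),
                       chromosomes = tibble(label = c("1", "2", "3"),
                                            length_bp = c(150e6, 130e6, 110e6),
                                            map_cM = c(150, 130, 110)),
                       marker_count = 120,
                       causal_locus = "random",
                       n_background_variants = 150,
                       rare_weight = 0.5,
                       depth_mean = 40,
                       het_alt_fraction = 0.5,
                       error_rate = 0.001,
                       seed_fraction = 0.8,
                       clonal_rate = 0.02,
                       genotype_dropout_rate = 0,
                       database_an = 280000,
                       database = "gnomad",
                       seed = 1L) {
  cfg <- list(
    pedigree = pedigree(pedigree), chromosomes = as_tibble(chromosomes),
    marker_count = marker_count, causal_locus = causal_locus,
    n_background_variants = n_background_variants, rare_weight = rare_weight,
    depth_mean = depth_mean, het_alt_fraction = het_alt_fraction,
    error_rate = error_rate, seed_fraction = seed_fraction,
    clonal_rate = clonal_rate, genotype_dropout_rate = genotype_dropout_rate,
    database_an = database_an, database = tolower(database), seed = as.integer(seed)
  )
  stopifnot(
    all(cfg$chromosomes$length_bp > 0), all(cfg$chromosomes$map_cM > 0),
    cfg$marker_count >= 1, cfg$n_background_variants >= 0,
    cfg$rare_weight >= 0, cfg$rare_weight <= 1,
    cfg$depth_mean > 0, cfg$het_alt_fraction > 0, cfg$het_alt_fraction < 1,
    cfg$error_rate >= 0, cfg$error_rate < 1,
    cfg$seed_fraction > 0, cfg$seed_fraction <= 1,
    cfg$clonal_rate >= 0, cfg$clonal_rate < 1,
    cfg$genotype_dropout_rate >= 0, cfg$genotype_dropout_rate < 1,
    cfg$database_an > 0
  )
  class(cfg) <- "coseg_sim_config"
  cfg
}

# crossover positions under the Haldane model: count ~ Poisson(map length in
# Morgans), placement uniform in bp (linear bp <-> cM map)
draw_crossovers <- function(length_bp, map_cM) {
  k <- rpois(1, map_cM / 100)
  sort(runif(k, 0, length_bp))
}

meiosis_chrom <- function(hap1, hap2, pos, length_bp, map_cM) {
  xo <- draw_crossovers(length_bp, map_cM)
  phase <- sample(c(1L, 2L), 1)
  seg <- (findInterval(pos, xo) + phase) %% 2L
  ifelse(seg == 0L, hap1, hap2)
}

founder_hap <- function(af) {
  as.integer(runif(length(af)) < af)
}

#' Simulate a family with markers and exome variants
#'
#' Draws founder haplotypes from configured allele frequencies, implants a
#' heterozygous causal allele in the founding affected member, transmits
#' haplotypes through the pedigree with Haldane recombination, and emits
#' marker genotypes and exome variant records with read-support noise. Each
#' meiosis from a carrier parent is conditioned (by resampling the gamete) on
#' the template affection of the child, so carrier status equals affection —
#' the complete-penetrance dominant model the analysis assumes.
#'
#' @param config A [sim_config()].
#' @return A `coseg_sim` list: `pedigree`, `markers` (marker tibble),
#'   `variants` (variants tibble, causal included), `truth` (causal locus,
#'   carrier ids, seed).
#' @export
simulate_family <- function(config = sim_config()) {
  set.seed(config$seed)
  ped <- config$pedigree
  chroms <- config$chromosomes

  # --- loci ---------------------------------------------------------------
  mk <- bind_rows(lapply(seq_len(nrow(chroms)), function(ci) {
    tibble(chrom = chroms$label[ci],
           pos = sort(round(runif(config$marker_count, 1, chroms$length_bp[ci]))),
           type = "marker",
           af = runif(config$marker_count, 0.2, 0.8))
  }))
  nbg <- config$n_background_variants
  bg_chrom <- sample(chroms$label, nbg, replace = TRUE, prob = chroms$length_bp)
  bg <- tibble(
    chrom = bg_chrom,
    pos = round(runif(nbg, 1, chroms$length_bp[match(bg_chrom, chroms$label)])),
    type = "background",
    af = ifelse(runif(nbg) < config$rare_weight,
                runif(nbg, 0, 0.002), runif(nbg, 0.01, 0.5))
  )
  if (identical(config$causal_locus, "random")) {
    cc <- sample(chroms$label, 1, prob = chroms$length_bp)
    cp <- round(runif(1, 1, chroms$length_bp[match(cc, chroms$label)]))
  } else {
    cc <- as.character(config$causal_locus$chrom)
    cp <- config$causal_locus$pos
    ci <- match(cc, chroms$label)
    if (is.na(ci) || cp < 1 || cp > chroms$length_bp[ci]) {
      abort("causal locus outside the declared chromosomes")
    }
  }
  loci <- bind_rows(mk, bg, tibble(chrom = cc, pos = cp, type = "causal", af = 0)) |>
    arrange(match(.data$chrom, chroms$label), .data$pos, .data$type) |>
    mutate(locus_id = row_number())

  # --- founder haplotypes and transmission --------------------------------
  founders <- ped$id[is.na(ped$father) & is.na(ped$mother)]
  aff_founders <- intersect(founders, ped$id[ped$affection == "affected"])
  if (!length(aff_founders)) {
    abort("pedigree template needs an affected founder to carry the causal allele")
  }
  carrier_founder <- aff_founders[1]

  haps <- list()
  for (f in founders) {
    haps[[f]] <- list(founder_hap(loci$af), founder_hap(loci$af))
    haps[[f]][[1]][loci$type == "causal"] <- 0L
    haps[[f]][[2]][loci$type == "causal"] <- 0L
  }
  causal_idx <- which(loci$type == "causal")
  haps[[carrier_founder]][[1]][causal_idx] <- 1L

  carries_causal <- function(hap) hap[causal_idx] == 1L
  is_carrier <- function(id) {
    carries_causal(haps[[id]][[1]]) || carries_causal(haps[[id]][[2]])
  }

  gamete <- function(parent_id) {
    unlist(lapply(seq_len(nrow(chroms)), function(ci) {
      sel <- loci$chrom == chroms$label[ci]
      meiosis_chrom(haps[[parent_id]][[1]][sel], haps[[parent_id]][[2]][sel],
                    loci$pos[sel], chroms$length_bp[ci], chroms$map_cM[ci])
    }))
  }
  conditioned_gamete <- function(parent_id, need_causal) {
    # resample until the causal allele matches the template affection;
    # non-carrier parents never transmit it, so only carriers loop
    for (try in 1:10000) {
      g <- gamete(parent_id)
      if (is.na(need_causal) || carries_causal(g) == need_causal) return(g)
    }
    abort("failed to condition a gamete on the template affection")
  }

  remaining <- setdiff(ped$id, founders)
  while (length(remaining)) {
    ready <- remaining[map_lgl(remaining, function(id) {
      row <- ped[ped$id == id, ]
      all(c(row$father, row$mother) %in% names(haps))
    })]
    if (!length(ready)) abort("unresolvable pedigree ordering (cycle?)")
    for (id in ready) {
      row <- ped[ped$id == id, ]
      need <- switch(row$affection, affected = TRUE, unaffected = FALSE, NA)
      from <- function(parent) {
        if (is_carrier(parent)) conditioned_gamete(parent, need) else gamete(parent)
      }
      haps[[id]] <- list(from(row$father), from(row$mother))
      if (!is.na(need) && is_carrier(id) != need) {
        abort("affection/carrier mismatch after conditioning")  # unreachable guard
      }
    }
    remaining <- setdiff(remaining, ready)
  }

  # --- genotype tables -----------------------------------------------------
  seqd <- ped$id[ped$sequenced]
  geno_count <- sapply(seqd, function(id) {
    haps[[id]][[1]] + haps[[id]][[2]]
  })  # loci x samples matrix of alt-allele counts

  dropout <- function(n) runif(n) < config$genotype_dropout_rate

  mk_idx <- which(loci$type == "marker")
  markers <- tibble(
    chrom = loci$chrom[mk_idx],
    pos = loci$pos[mk_idx],
    cM = round(loci$pos[mk_idx] /
                 chroms$length_bp[match(loci$chrom[mk_idx], chroms$label)] *
                 chroms$map_cM[match(loci$chrom[mk_idx], chroms$label)], 4)
  )
  for (id in seqd) {
    g1 <- haps[[id]][[1]][mk_idx]
    g2 <- haps[[id]][[2]][mk_idx]
    gstr <- paste(ifelse(pmin(g1, g2) == 1, "B", "A"),
                  ifelse(pmax(g1, g2) == 1, "B", "A"), sep = "/")
    gstr[dropout(length(gstr))] <- NA_character_
    markers[[id]] <- gstr
  }
  # the causal site itself is carried as a (perfectly informative) marker row,
  # so error-free runs always contain a compatible marker at the true locus
  causal_marker <- tibble(
    chrom = cc,
    pos = cp,
    cM = round(cp / chroms$length_bp[match(cc, chroms$label)] *
                 chroms$map_cM[match(cc, chroms$label)], 4)
  )
  for (id in seqd) {
    nalt <- geno_count[causal_idx, id]
    causal_marker[[id]] <- c("A/A", "A/B", "B/B")[nalt + 1]
  }
  markers <- arrange(bind_rows(markers, causal_marker), .data$chrom, .data$pos)

  var_idx <- which(loci$type != "marker")
  acdb <- paste0("ac_", config$database)
  andb <- paste0("an_", config$database)
  vrows <- lapply(var_idx, function(li) {
    is_causal <- loci$type[li] == "causal"
    ns <- length(seqd)
    nalt <- geno_count[li, seqd]
    depth <- rpois(ns, config$depth_mean)
    alt <- ifelse(nalt == 1L, rbinom(ns, depth, config$het_alt_fraction),
                  rbinom(ns, depth, config$error_rate))
    alt <- ifelse(nalt == 2L, depth - alt, alt)
    clonal <- rbinom(ns, depth, config$clonal_rate)
    miss <- dropout(ns)
    calls <- tibble(
      sample_id = seqd,
      gt = ifelse(miss, NA_character_, c("0/0", "0/1", "1/1")[nalt + 1L]),
      carries_alt = ifelse(miss, NA, nalt > 0L),
      het_alt = ifelse(miss, NA, nalt == 1L),
      depth = ifelse(miss, NA_real_, depth),
      alt_reads = ifelse(miss, NA_real_, alt),
      seed_support = ifelse(miss, NA_real_, ceiling(alt * config$seed_fraction)),
      clonal_reads = ifelse(miss, NA_real_, clonal)
    )
    af <- loci$af[li]
    conseq <- if (is_causal) "missense" else
      sample(CONSEQUENCES, 1, prob = c(0.06, 0.07, 0.5, 0.07, 0.3))
    row <- tibble(
      variant_id = paste(loci$chrom[li], loci$pos[li], "A", "G", sep = "_"),
      chrom = loci$chrom[li], pos = loci$pos[li], ref = "A", alt = "G",
      gene = if (is_causal) "CAUSAL" else paste0("GENE", loci$locus_id[li]),
      rsid = NA_character_,
      consequence = conseq,
      indel_length = if (conseq == "frameshift_indel") sample(1:9, 1) else 0,
      inhouse = if (is_causal) 0 else sample(0:4, 1, prob = c(.55, .2, .12, .08, .05)),
      polyphen_score = NA_real_, polyphen_class = NA_character_,
      sift_score = NA_real_, sift_class = NA_character_,
      cond_nt = NA_character_, cond_aa = NA_character_,
      calls = list(calls)
    )
    row[[acdb]] <- round(af * config$database_an)
    row[[andb]] <- config$database_an
    row
  })
  variants <- bind_rows(vrows)
  class(variants) <- unique(c("coseg_variants", class(tibble())))

  causal_id <- variants$variant_id[variants$gene == "CAUSAL"]
  out <- list(
    pedigree = ped,
    markers = markers,
    variants = variants,
    truth = list(
      causal = tibble(chrom = cc, pos = cp, variant_id = causal_id),
      carriers = ped$id[map_lgl(ped$id, is_carrier)],
      genome_bp = sum(chroms$length_bp),
      seed = config$seed
    )
  )
  class(out) <- "coseg_sim"
  out
}

#' Build a single-violation decoy set
#'
#' For each cascade stage, constructs decoy variants that violate exactly that
#' stage and pass all others: low (clonality-capped) coverage, out-of-band
#' allele fraction, insufficient seed support, a clonal pile-up, a disallowed
#' consequence class, an over-long indel, an in-house count above threshold, a
#' carrier among the unaffected, a non-heterozygous affected member, a common
#' population allele, and a position outside every linked region. Decoys are
#' deterministic functions of the inputs (no randomness): in-region decoys are
#' placed at distinct offsets inside the provided regions, the region decoy
#' beyond the last region of its chromosome.
#'
#' @param base_variants A variants tibble supplying ref/alt templates.
#' @param ped A pedigree tibble (affected/unaffected sets).
#' @param regions A regions tibble the in-region decoys must fall inside.
#' @param config A [cascade_config()] the decoys are calibrated against.
#' @param n Number of decoys (cycled over the violation types), >= one per type.
#' @return A variants tibble of `n` decoys.
#' @export
make_decoy_set <- function(base_variants, ped, regions,
                           config = cascade_config(), n = 20) {
  aff <- affected_ids(ped)
  unaff <- unaffected_ids(ped)
  if (!nrow(regions)) abort("decoy construction needs at least one region")
  types <- c("qc_low_depth", "qc_alt_fraction_low", "qc_alt_fraction_high",
             "qc_low_seed", "qc_clonal", "class_consequence", "class_long_indel",
             "class_inhouse", "absent_unaffected", "present_affected",
             "popfreq_common", "region_outside")
  n <- max(n, length(types))

  clean_call <- function(id, het) {
    if (het) {
      tibble(sample_id = id, gt = "0/1", carries_alt = TRUE, het_alt = TRUE,
             depth = 40, alt_reads = 20, seed_support = 16, clonal_reads = 1)
    } else {
      tibble(sample_id = id, gt = "0/0", carries_alt = FALSE, het_alt = FALSE,
             depth = 40, alt_reads = 0, seed_support = 0, clonal_reads = 1)
    }
  }
  clean_calls <- bind_rows(
    lapply(aff, clean_call, het = TRUE),
    lapply(unaff, clean_call, het = FALSE)
  )
  patch_call <- function(calls, id, ...) {
    repl <- list(...)
    i <- match(id, calls$sample_id)
    for (k in names(repl)) calls[[k]][i] <- repl[[k]]
    calls
  }

  out_chrom <- regions$chrom[1]
  out_pos <- max(regions$end[regions$chrom == out_chrom]) + 5e6

  rows <- lapply(seq_len(n), function(i) {
    type <- types[(i - 1) %% length(types) + 1]
    base <- base_variants[(i - 1) %% nrow(base_variants) + 1, ]
    reg <- regions[(i - 1) %% nrow(regions) + 1, ]
    span <- max(1, reg$end - reg$start - 1)
    pos <- reg$start + 1 + ((i * 97L) %% span)
    chrom <- reg$chrom
    if (type == "region_outside") {
      chrom <- out_chrom
      pos <- out_pos + i
    }
    calls <- clean_calls
    v <- tibble(
      variant_id = paste(chrom, pos, base$ref, base$alt, sep = "_"),
      chrom = chrom, pos = pos, ref = base$ref, alt = base$alt,
      gene = paste0("DECOY_", toupper(type), "_", i), rsid = NA_character_,
      consequence = "missense", indel_length = 0, inhouse = 0,
      polyphen_score = NA_real_, polyphen_class = NA_character_,
      sift_score = NA_real_, sift_class = NA_character_,
      cond_nt = NA_character_, cond_aa = NA_character_,
      ac_gnomad = 0, an_gnomad = 280000
    )
    calls <- switch(
      type,
      qc_low_depth = patch_call(calls, aff[1], depth = 9, alt_reads = 4,
                                seed_support = 3, clonal_reads = 0),
      qc_alt_fraction_low = patch_call(calls, aff[1], depth = 40, alt_reads = 4,
                                       seed_support = 3),
      qc_alt_fraction_high = patch_call(calls, aff[1], depth = 40, alt_reads = 36,
                                        seed_support = 16),
      qc_low_seed = patch_call(calls, aff[1], seed_support = 1),
      qc_clonal = patch_call(calls, aff[1], depth = 13, alt_reads = 6,
                             seed_support = 5, clonal_reads = 10),
      absent_unaffected = patch_call(calls, unaff[1], gt = "0/1",
                                     carries_alt = TRUE, het_alt = TRUE,
                                     alt_reads = 20, seed_support = 16),
      present_affected = patch_call(calls, aff[1], gt = "0/0",
                                    carries_alt = FALSE, het_alt = FALSE,
                                    alt_reads = 0, seed_support = 0),
      calls
    )
    if (type == "class_consequence") v$consequence <- "other"
    if (type == "class_long_indel") {
      v$consequence <- "frameshift_indel"
      v$indel_length <- config$max_indel_nt + 2
    }
    if (type == "class_inhouse") v$inhouse <- config$max_inhouse + 1
    if (type == "popfreq_common") v$ac_gnomad <- ceiling(config$max_pop_af * 5 * 280000)
    v$calls <- list(calls)
    v
  })
  out <- bind_rows(rows)
  class(out) <- unique(c("coseg_variants", class(tibble())))
  out
}
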