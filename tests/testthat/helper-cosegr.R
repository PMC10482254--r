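# shared builders and independent oracles

tiny_ped <- function(aff = c("A1", "A2", "A3"), unaff = c("U1", "U2", "U3")) {
  pedigree(tibble::tibble(
    id = c(aff, unaff),
    father = NA_character_, mother = NA_character_,
    sex = "unknown",
    affection = rep(c("affected", "unaffected"), c(length(aff), length(unaff)))
  ))
}

fixture_ped <- function() read_ped(cosegr_example("family_synthetic.ped"))
fixture_regions <- function() read_regions(cosegr_example("linked_regions.tsv"))
fixture_variants <- function(ped = fixture_ped()) {
  read_vcf(cosegr_example("candidate_variants.vcf"), ped)
}

# one-variant builder with clean calls (het in affected, ref in unaffected)
make_call_row <- function(sample_id, gt = "0/1", depth = 40, alt_reads = 20,
                          seed_support = 16, clonal_reads = 1) {
  al <- if (is.na(gt)) c(NA_integer_, NA_integer_) else
    as.integer(strsplit(gt, "/")[[1]])
  tibble::tibble(
    sample_id = sample_id, gt = gt,
    carries_alt = if (anyNA(al)) NA else any(al == 1L),
    het_alt = if (anyNA(al)) NA else sum(al == 1L) == 1L,
    depth = depth, alt_reads = alt_reads,
    seed_support = seed_support, clonal_reads = clonal_reads
  )
}

make_variant <- function(chrom = "2", pos = 150000000, ref = "G", alt = "A",
                         gene = "TEST", consequence = "missense",
                         indel_length = 0, inhouse = 0,
                         ac_gnomad = 0, an_gnomad = 280000,
                         ped = fixture_ped(), calls = NULL) {
  if (is.null(calls)) {
    calls <- dplyr::bind_rows(
      lapply(affected_ids(ped), make_call_row),
      lapply(unaffected_ids(ped), make_call_row, gt = "0/0", alt_reads = 0,
             seed_support = 0)
    )
  }
  tibble::tibble(
    variant_id = paste(chrom, pos, ref, alt, sep = "_"),
    chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
    rsid = NA_character_, consequence = consequence,
    indel_length = indel_length, inhouse = inhouse,
    polyphen_score = NA_real_, polyphen_class = NA_character_,
    sift_score = NA_real_, sift_class = NA_character_,
    cond_nt = NA_character_, cond_aa = NA_character_,
    ac_gnomad = ac_gnomad, an_gnomad = an_gnomad,
    calls = list(calls)
  )
}

# brute-force oracle: loop over every allele observed at the marker
oracle_marker_compatible <- function(geno, aff, unaff) {
  split1 <- function(g) if (is.na(g) || g == ".") character() else
    strsplit(g, "/", fixed = TRUE)[[1]]
  ga <- lapply(geno[aff], split1)
  gu <- lapply(geno[unaff], split1)
  ga <- ga[lengths(ga) > 0]
  gu <- gu[lengths(gu) > 0]
  alleles <- unique(unlist(c(ga, gu)))
  for (a in alleles) {
    in_all_aff <- all(vapply(ga, function(g) a %in% g, logical(1)))
    in_no_unaff <- !any(vapply(gu, function(g) a %in% g, logical(1)))
    if (in_all_aff && in_no_unaff) return(TRUE)
  }
  FALSE
}

# brute-force oracle: maximal runs of TRUE (zero error tolerance)
oracle_runs <- function(compat) {
  r <- rle(compat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- cbind(start = starts[r$values], end = ends[r$values])
  out[out[, 1] <= out[, 2], , drop = FALSE]
}

# brute-force oracle over all 2^n carrier assignments matching the phenotype
oracle_dominant <- function(ped) {
  n <- nrow(ped)
  best <- Inf
  for (mask in 0:(2^n - 1)) {
    carrier <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    names(carrier) <- ped$id
    pheno_known <- ped$affection != "unknown"
    if (!all(carrier[pheno_known] == (ped$affection[pheno_known] == "affected"))) next
    dn <- 0
    for (i in seq_len(n)) {
      if (!carrier[i]) next
      f <- ped$father[i]; m <- ped$mother[i]
      if (is.na(f) && is.na(m)) next
      pc <- function(p) is.na(p) || !p %in% ped$id || carrier[[p]]
      if (!(pc(f) || pc(m))) dn <- dn + 1
    }
    best <- min(best, dn)
  }
  if (best == 0) "consistent" else "de_novo_required"
}

small_sim_config <- function(seed, n_background_variants = 30, ...) {
  sim_config(
    chromosomes = tibble::tibble(label = c("1", "2"),
                                 length_bp = c(8e7, 6e7), map_cM = c(80, 60)),
    marker_count = 40, n_background_variants = n_background_variants,
    seed = seed, ...
  )
}

random_marker_genotypes <- function(n_alleles, aff, unaff, miss_rate = 0.1) {
  ids <- c(aff, unaff)
  g <- vapply(ids, function(i) {
    if (runif(1) < miss_rate) return(NA_character_)
    paste(sort(sample(LETTERS[seq_len(n_alleles)], 2, replace = TRUE)),
          collapse = "/")
  }, character(1))
  names(g) <- ids
  g
}

expression_fixture <- function() {
  # 17 prefrontal-cortex-like samples spanning 0.1-83 years; one flat gene,
  # one gene 4x elevated inside the early window, one noisy null gene
  ages <- c(0.1, 0.3, 0.5, 1, 1.5, 2, 2.4, 3, 5, 8, 12, 20, 30, 40, 55, 70, 83)
  set.seed(42)
  tibble::tibble(
    gene = rep(c("FLAT", "DEVUP", "NULL1"), each = length(ages)),
    sample = rep(paste0("S", seq_along(ages)), 3),
    age = rep(ages, 3),
    value = c(rep(100, length(ages)),
              ifelse(ages <= 2.4, 400, 100) * exp(rnorm(length(ages), 0, 0.05)),
              100 * exp(rnorm(length(ages), 0, 0.3)))
  )
}
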