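#' Exome variant tables and the package VCF dialect
#'
#' Variants are tibbles with one row per (site, ALT allele) pair —
#' multi-allelic sites are decomposed on read — and columns:
#' `variant_id` (`chrom_pos_ref_alt`), `chrom`, `pos` (1-based), `ref`, `alt`,
#' `gene`, `rsid`, `consequence` (one of `nonsense`, `frameshift_indel`,
#' `missense`, `splice_site`, `other`, or `NA` when unannotated),
#' `indel_length` (0 for SNVs), `inhouse` (in-house database occurrence
#' count), one `ac_<db>`/`an_<db>` numeric pair per population database seen
#' in the file, prediction columns (`polyphen_score`, `polyphen_class`,
#' `sift_score`, `sift_class`, `cond_nt`, `cond_aa`) and a `calls`
#' list-column. Each element of `calls` is a tibble with one row per sample:
#' `sample_id`, `gt`, `carries_alt`, `het_alt`, `depth`, `alt_reads`,
#' `seed_support` (reads whose first-25-bp seed supports the variant) and
#' `clonal_reads` (reads sharing an identical start site beyond the first).
#'
#' The on-disk dialect is VCF 4.2 with FORMAT fields `GT`, `DP`, `AD` and the
#' custom `SS` (seed support) and `CL` (clonal reads), and INFO keys `GENE`,
#' `CONSEQ`, `AC_<DB>`/`AN_<DB>`, `INHOUSE`, `PPH_S`, `PPH_C`, `SIFT_S`,
#' `SIFT_C`, `COND_NT`, `COND_AA`. Missing annotations stay missing (`NA`),
#' never defaults.
#'
#' @name variant-tables
NULL

CONSEQUENCES <- c("nonsense", "frameshift_indel", "missense", "splice_site", "other")

info_keys <- function(info) {
  unique(unlist(stringr::str_extract_all(info, "(?<=^|;)[A-Za-z0-9_]+(?==)")))
}

split_nth <- function(x, j) {
  # j-th comma-separated element (Number=A INFO fields), NA-safe
  vapply(seq_along(x), function(i) {
    if (is.na(x[i])) return(NA_character_)
    parts <- strsplit(x[i], ",", fixed = TRUE)[[1]]
    if (j[i] <= length(parts)) parts[j[i]] else NA_character_
  }, character(1))
}

parse_gt_alleles <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(c(NA_integer_, NA_integer_))
  a <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
  if (length(a) != 2 || anyNA(a)) return(c(NA_integer_, NA_integer_))
  a
}

#' Read exome variants from a VCF file
#'
#' Reads the package VCF dialect (see [variant-tables]) via `vcfR`, decomposes
#' multi-allelic sites into one record per ALT allele, and checks every sample
#' against the pedigree.
#'
#' @param path VCF file path (4.2+, plain text).
#' @param ped A pedigree tibble; every VCF sample must be a pedigree member.
#' @return A variants tibble, one row per (site, alt) pair.
#' @export
read_vcf <- function(path, ped) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("malformed VCF ", path, ": ", conditionMessage(e)))
  )
  if (!nrow(vcf@fix)) abort(paste0("VCF has no variant records: ", path))
  samples <- colnames(vcf@gt)[-1]
  unmatched <- setdiff(samples, ped$id)
  if (length(unmatched)) {
    abort(paste0("VCF samples absent from pedigree: ", paste(unmatched, collapse = ", ")))
  }

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info <- fix$INFO
  keys <- info_keys(info)
  info_val <- lapply(setNames(keys, keys), function(k) {
    as.character(vcfR::extract.info(vcf, element = k))
  })

  gt_m <- vcfR::extract.gt(vcf, element = "GT")
  dp_m <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  ad_m <- vcfR::extract.gt(vcf, element = "AD")
  ss_m <- suppressWarnings(vcfR::extract.gt(vcf, element = "SS", as.numeric = TRUE))
  cl_m <- suppressWarnings(vcfR::extract.gt(vcf, element = "CL", as.numeric = TRUE))

  db_names <- sort(unique(sub("^AC_", "", grep("^AC_", keys, value = TRUE))))

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (j in seq_along(alts)) {
      alt <- alts[j]
      get1 <- function(key) if (key %in% keys) info_val[[key]][i] else NA_character_
      getA <- function(key) if (key %in% keys) split_nth(info_val[[key]][i], j) else NA_character_

      conseq <- getA("CONSEQ")
      if (!is.na(conseq) && !conseq %in% CONSEQUENCES) {
        abort(paste0("consequence '", conseq, "' outside the closed vocabulary at ",
                     fix$CHROM[i], ":", fix$POS[i]))
      }

      calls <- map(samples, function(s) {
        gt <- gt_m[i, s]
        al <- parse_gt_alleles(gt)
        depth <- dp_m[i, s]
        ad <- ad_m[i, s]
        alt_reads <- NA_real_
        if (!is.na(ad)) {
          adp <- suppressWarnings(as.numeric(strsplit(ad, ",", fixed = TRUE)[[1]]))
          if (j + 1 <= length(adp)) alt_reads <- adp[j + 1]
        }
        tibble(
          sample_id = s,
          gt = if (anyNA(al)) NA_character_ else paste(sort(al), collapse = "/"),
          carries_alt = if (anyNA(al)) NA else any(al == j),
          het_alt = if (anyNA(al)) NA else sum(al == j) == 1L,
          depth = depth,
          alt_reads = alt_reads,
          seed_support = ss_m[i, s],
          clonal_reads = cl_m[i, s]
        )
      })
      calls <- bind_rows(calls)
      bad <- which(!is.na(calls$alt_reads) & !is.na(calls$depth) &
                     calls$alt_reads > calls$depth)
      if (length(bad)) {
        abort(paste0("alt_reads > depth for sample ", calls$sample_id[bad[1]],
                     " at ", fix$CHROM[i], ":", fix$POS[i]))
      }

      row <- tibble(
        variant_id = paste(fix$CHROM[i], fix$POS[i], fix$REF[i], alt, sep = "_"),
        chrom = fix$CHROM[i],
        pos = as.numeric(fix$POS[i]),
        ref = fix$REF[i],
        alt = alt,
        gene = get1("GENE"),
        rsid = ifelse(fix$ID[i] %in% c(".", ""), NA_character_, fix$ID[i]),
        consequence = conseq,
        indel_length = abs(nchar(alt) - nchar(fix$REF[i])),
        inhouse = as.numeric(get1("INHOUSE")),
        polyphen_score = as.numeric(get1("PPH_S")),
        polyphen_class = get1("PPH_C"),
        sift_score = as.numeric(get1("SIFT_S")),
        sift_class = get1("SIFT_C"),
        cond_nt = get1("COND_NT"),
        cond_aa = get1("COND_AA"),
        calls = list(calls)
      )
      for (db in db_names) {
        ac <- as.numeric(getA(paste0("AC_", db)))
        an <- as.numeric(get1(paste0("AN_", db)))
        if (!is.na(ac) && !is.na(an) && ac > an) {
          abort(paste0("AC > AN for database ", db, " at ", row$variant_id))
        }
        row[[paste0("ac_", tolower(db))]] <- ac
        row[[paste0("an_", tolower(db))]] <- an
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- bind_rows(rows)
  class(out) <- unique(c("coseg_variants", class(tibble())))
  out
}

#' Database names annotated on a variants tibble
#'
#' @param variants A variants tibble.
#' @return Lower-case database names for which `ac_`/`an_` columns exist.
#' @export
popfreq_dbs <- function(variants) {
  sub("^ac_", "", grep("^ac_", names(variants), value = TRUE))
}

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, format(x, scientific = FALSE, trim = TRUE))
}

#' Write exome variants in the package VCF dialect
#'
#' Emits one VCF record per row (records are already one-per-ALT); reading the
#' file back with [read_vcf()] reproduces every stored field.
#'
#' @param variants A variants tibble.
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_vcf <- function(variants, path) {
  dbs <- popfreq_dbs(variants)
  samples <- if (nrow(variants)) variants$calls[[1]]$sample_id else character()
  meta <- c(
    "##fileformat=VCFv4.2",
    "##reference=GRCh37/hg19",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CONSEQ,Number=A,Type=String,Description=\"Consequence class\">",
    unlist(lapply(toupper(dbs), function(db) c(
      sprintf("##INFO=<ID=AC_%s,Number=A,Type=Integer,Description=\"Alt allele count in %s\">", db, db),
      sprintf("##INFO=<ID=AN_%s,Number=1,Type=Integer,Description=\"Allele number in %s\">", db, db)
    ))),
    "##INFO=<ID=INHOUSE,Number=1,Type=Integer,Description=\"In-house database occurrence count\">",
    "##INFO=<ID=PPH_S,Number=1,Type=Float,Description=\"Polyphen score\">",
    "##INFO=<ID=PPH_C,Number=1,Type=String,Description=\"Polyphen class\">",
    "##INFO=<ID=SIFT_S,Number=1,Type=Float,Description=\"SIFT score\">",
    "##INFO=<ID=SIFT_C,Number=1,Type=String,Description=\"SIFT class\">",
    "##INFO=<ID=COND_NT,Number=1,Type=String,Description=\"Condel nucleotide conservation\">",
    "##INFO=<ID=COND_AA,Number=1,Type=String,Description=\"Condel amino-acid conservation\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=SS,Number=1,Type=Integer,Description=\"Reads with a supporting 25-bp seed\">",
    "##FORMAT=<ID=CL,Number=1,Type=Integer,Description=\"Clonal reads beyond the first at the start site\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    kv <- c(
      GENE = v$gene, CONSEQ = v$consequence,
      unlist(lapply(dbs, function(db) {
        setNames(fmt_num(c(v[[paste0("ac_", db)]], v[[paste0("an_", db)]])),
                 paste0(c("AC_", "AN_"), toupper(db)))
      })),
      INHOUSE = fmt_num(v$inhouse),
      PPH_S = fmt_num(v$polyphen_score), PPH_C = v$polyphen_class,
      SIFT_S = fmt_num(v$sift_score), SIFT_C = v$sift_class,
      COND_NT = v$cond_nt, COND_AA = v$cond_aa
    )
    kv <- kv[!is.na(kv)]
    info <- if (length(kv)) paste(names(kv), kv, sep = "=", collapse = ";") else "."
    calls <- v$calls[[1]]
    gtcol <- vapply(seq_len(nrow(calls)), function(k) {
      cc <- calls[k, ]
      if (is.na(cc$gt)) return("./.:.:.:.:.")
      paste(cc$gt,
            fmt_num(cc$depth),
            paste(fmt_num(c(cc$depth - cc$alt_reads, cc$alt_reads)), collapse = ","),
            fmt_num(cc$seed_support),
            fmt_num(cc$clonal_reads), sep = ":")
    }, character(1))
    paste(c(v$chrom, fmt_num(v$pos), ifelse(is.na(v$rsid), ".", v$rsid),
            v$ref, v$alt, ".", "PASS", info, "GT:DP:AD:SS:CL", gtcol),
          collapse = "\t")
  }, character(1))
  write_lines(c(meta, body), path)
  invisible(variants)
}
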