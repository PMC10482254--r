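#' Damage-prediction concordance tier
#'
#' Collapses the Polyphen/SIFT class pair into one tier:
#' `concordant_damaging` (Polyphen not benign AND SIFT deleterious),
#' `concordant_benign` (benign AND tolerated), `undefined` (either class
#' missing, e.g. splice-site variants), otherwise `discordant`. Total over the
#' class vocabulary.
#'
#' @param polyphen_class `"benign"`, `"possibly_damaging"`,
#'   `"probably_damaging"` or `NA`.
#' @param sift_class `"tolerated"`, `"deleterious"` or `NA`.
#' @return Character vector of tiers.
#' @examples
#' damage_tier("probably_damaging", "deleterious")
#' damage_tier("benign", "tolerated")
#' damage_tier(NA, NA)
#' @export
damage_tier <- function(polyphen_class, sift_class) {
  pp_ok <- is.na(polyphen_class) |
    polyphen_class %in% c("benign", "possibly_damaging", "probably_damaging")
  si_ok <- is.na(sift_class) | sift_class %in% c("tolerated", "deleterious")
  if (!all(pp_ok) || !all(si_ok)) {
    abort("prediction classes outside the closed vocabulary")
  }
  dplyr::case_when(
    is.na(polyphen_class) | is.na(sift_class) ~ "undefined",
    polyphen_class != "benign" & sift_class == "deleterious" ~ "concordant_damaging",
    polyphen_class == "benign" & sift_class == "tolerated" ~ "concordant_benign",
    TRUE ~ "discordant"
  )
}

#' Read a gene-keyed annotation table
#'
#' TSV with one row per gene: `gene`, optional population-frequency strings
#' (`evs`, `gonl`, `exac`, carried through verbatim), `polyphen_score`,
#' `polyphen_class`, `sift_score`, `sift_class`, `cond_nt`, `cond_aa`
#' (`undef`/`na` values become `NA`).
#'
#' @param path File path.
#' @return A tibble keyed by `gene`.
#' @export
read_annotations <- function(path) {
  x <- read_tsv(path, show_col_types = FALSE, na = c("", "NA", "undef", "na"))
  if (!"gene" %in% names(x)) abort(paste0("annotation table needs a gene column: ", path))
  x
}

#' Read a gene-by-sample expression matrix with sample ages
#'
#' Expects a TSV whose header row holds sample ids (first column `gene`) and
#' whose first data row, keyed `age`, holds each sample's age in years; the
#' remaining rows are non-negative expression values.
#'
#' @param path File path.
#' @return A long tibble: `gene`, `sample`, `age`, `value`.
#' @export
read_expression <- function(path) {
  x <- read_tsv(path, show_col_types = FALSE)
  if (names(x)[1] != "gene" || x$gene[1] != "age") {
    abort(paste0("expression table needs a 'gene' column with an 'age' first row: ", path))
  }
  ages <- as.numeric(x[1, -1])
  expr <- x[-1, ]
  long <- pivot_longer(expr, -"gene", names_to = "sample", values_to = "value")
  long$age <- ages[match(long$sample, names(x)[-1])]
  if (any(long$age < 0, na.rm = TRUE)) abort("sample ages must be non-negative")
  select(long, "gene", "sample", "age", "value")
}

#' Flag elevated expression in a developmental age window
#'
#' Log2-transforms expression (with a pseudocount), z-scores each gene across
#' samples, and flags the gene when the mean z inside the age window exceeds
#' the mean z outside by more than `z_threshold`. A zero-variance gene is
#' never flagged (summary `"constant"`). The statistic is invariant to any
#' positive power-law rescaling of a gene's values (affine maps after log).
#'
#' @param expr A long expression tibble from [read_expression()].
#' @param genes Genes to test (default: all). A requested gene absent from
#'   the matrix is an error.
#' @param window Age window in years, default `c(0.1, 2.4)` — the early
#'   postnatal maturation window the report targets.
#' @param z_threshold Contrast threshold in z units (default 1.0; calibrate
#'   by permutation for a formal null, see the vignette).
#' @param pseudocount Added before log2.
#' @return A tibble: `gene`, `flag`, `contrast` (mean z in − mean z out),
#'   `mean_z_in`, `mean_z_out`, `n_in`, `n_out`, `note`.
#' @export
developmental_window_flag <- function(expr, genes = NULL, window = c(0.1, 2.4),
                                      z_threshold = 1, pseudocount = 1) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  genes <- genes %||% unique(expr$gene)
  missing_genes <- setdiff(genes, expr$gene)
  if (length(missing_genes)) {
    abort(paste0("genes absent from the expression matrix: ",
                 paste(missing_genes, collapse = ", ")))
  }
  samples <- distinct(expr, .data$sample, .data$age)
  inside <- samples$age >= window[1] & samples$age <= window[2]
  if (sum(inside) < 2 || sum(!inside) < 2) {
    abort("the age window needs at least 2 samples inside and 2 outside")
  }
  expr |>
    filter(.data$gene %in% genes) |>
    group_by(.data$gene) |>
    summarise(
      {
        y <- log2(.data$value + pseudocount)
        s <- sd(y)
        win <- .data$age >= window[1] & .data$age <= window[2]
        if (is.na(s) || s == 0) {
          tibble(flag = FALSE, contrast = 0, mean_z_in = NA_real_,
                 mean_z_out = NA_real_, n_in = sum(win), n_out = sum(!win),
                 note = "constant")
        } else {
          z <- (y - mean(y)) / s
          zi <- mean(z[win])
          zo <- mean(z[!win])
          tibble(flag = (zi - zo) > z_threshold, contrast = zi - zo,
                 mean_z_in = zi, mean_z_out = zo,
                 n_in = sum(win), n_out = sum(!win), note = NA_character_)
        }
      },
      .groups = "drop"
    )
}

#' Assemble the candidate report
#'
#' One row per surviving variant: locus, gene, consequence, per-database
#' allele frequency, damage-concordance tier, developmental-expression flag
#' and a trace summary. Prediction classes come from the variants themselves
#' unless a gene-keyed annotation table is supplied, in which case it must
#' cover every surviving gene (a survivor with no annotation row is a key
#' error naming the orphans; unused annotation rows are ignored).
#'
#' @param survivors A variants tibble (e.g. `run_cascade(...)$survivors`).
#' @param annotations Optional tibble from [read_annotations()].
#' @param expression Optional long tibble from [read_expression()].
#' @param window,z_threshold Passed to [developmental_window_flag()].
#' @param trace Optional cascade trace used for the `stages_passed` summary.
#' @return A report tibble.
#' @export
build_report <- function(survivors, annotations = NULL, expression = NULL,
                         window = c(0.1, 2.4), z_threshold = 1, trace = NULL) {
  v <- as_tibble(survivors)
  if (!nrow(v)) {
    return(tibble(gene = character(), variant_id = character(), chrom = character(),
                  pos = numeric(), ref = character(), alt = character(),
                  consequence = character(), damage_tier = character(),
                  expression_flag = logical(), stages_passed = character()))
  }
  if (!is.null(annotations)) {
    if (anyDuplicated(annotations$gene)) {
      abort("annotation table has duplicated gene keys")
    }
    orphans_v <- setdiff(v$gene, annotations$gene)
    if (length(orphans_v)) {
      abort(paste0("survivors with no annotation row (orphans): ",
                   paste(orphans_v, collapse = ", ")))
    }
    ann <- annotations
    v$polyphen_class <- ann$polyphen_class[match(v$gene, ann$gene)]
    v$sift_class <- ann$sift_class[match(v$gene, ann$gene)]
    for (col in intersect(c("polyphen_score", "sift_score", "cond_nt", "cond_aa",
                            "evs", "gonl", "exac"), names(ann))) {
      v[[col]] <- ann[[col]][match(v$gene, ann$gene)]
    }
  }
  out <- select(v, "gene", "variant_id", "chrom", "pos", "ref", "alt",
                "consequence", dplyr::any_of(c("polyphen_score", "polyphen_class",
                                               "sift_score", "sift_class",
                                               "cond_nt", "cond_aa",
                                               "evs", "gonl", "exac")))
  for (db in popfreq_dbs(v)) {
    out[[paste0("af_", db)]] <- v[[paste0("ac_", db)]] / v[[paste0("an_", db)]]
  }
  out$damage_tier <- damage_tier(v$polyphen_class, v$sift_class)
  if (!is.null(expression)) {
    have <- intersect(unique(v$gene), unique(expression$gene))
    flags <- developmental_window_flag(expression, have, window, z_threshold)
    out$expression_flag <- flags$flag[match(v$gene, flags$gene)]
  } else {
    out$expression_flag <- NA
  }
  out$stages_passed <- if (!is.null(trace)) {
    vapply(v$variant_id, function(id) {
      tr <- trace[trace$variant_id == id & trace$pass, ]
      paste(tr$stage, collapse = ",")
    }, character(1))
  } else {
    "not_traced"
  }
  out
}

#' Write / read the candidate report
#'
#' Plain TSV, column-faithful on a round trip; an empty survivor set writes a
#' header-only file.
#'
#' @param report A report tibble from [build_report()].
#' @param path File path.
#' @return `write_report()` the input invisibly; `read_report()` a tibble.
#' @export
write_report <- function(report, path) {
  write_tsv(report, path, na = "NA")
  invisible(report)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  read_tsv(path, show_col_types = FALSE)
}
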