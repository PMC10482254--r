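#' Marker genotype matrices
#'
#' A marker matrix is a tibble with columns `chrom`, `pos` (bp), optional
#' `cM` (genetic-map position) and one character column per genotyped
#' individual holding unordered allele pairs as `"A/B"` strings (`NA` or `"."`
#' for missing). Rows must be sorted by `(chrom, pos)`. Genetic-map positions
#' are used only by the simulator; the scan itself works on marker order.
#'
#' @param path TSV file with a header row.
#' @return A marker tibble.
#' @export
read_markers <- function(path) {
  x <- read_tsv(path, show_col_types = FALSE, na = c("", "NA", "."))
  if (!all(c("chrom", "pos") %in% names(x))) {
    abort(paste0("marker file must have chrom and pos columns: ", path))
  }
  x$chrom <- as.character(x$chrom)
  x
}

#' @rdname read_markers
#' @param markers A marker tibble.
#' @return `write_markers()` returns the input, invisibly.
#' @export
write_markers <- function(markers, path) {
  write_tsv(markers, path, na = ".")
  invisible(markers)
}

marker_sample_cols <- function(markers) {
  setdiff(names(markers), c("chrom", "pos", "cM"))
}

#' Region scan parameters
#'
#' @param max_errors Incompatible markers tolerated inside a region (>= 0).
#' @param min_markers Minimum compatible markers per reported region (>= 1).
#' @param boundary `"inner"`: region endpoints are the first/last compatible
#'   marker; `"outer"`: the flanking incompatible markers (or the chromosome's
#'   terminal markers).
#' @param missing `"compatible"` (default): a missing genotype cannot disprove
#'   sharing and is ignored; `"incompatible"`: any missing genotype among
#'   sequenced members makes the marker incompatible.
#' @return A `coseg_scan_params` list.
#' @export
scan_params <- function(max_errors = 0, min_markers = 3,
                        boundary = c("inner", "outer"),
                        missing = c("compatible", "incompatible")) {
  stopifnot(max_errors >= 0, min_markers >= 1)
  p <- list(max_errors = as.integer(max_errors),
            min_markers = as.integer(min_markers),
            boundary = match.arg(boundary),
            missing = match.arg(missing))
  class(p) <- "coseg_scan_params"
  p
}

split_alleles <- function(g) {
  if (is.na(g) || g == ".") return(character())
  strsplit(g, "/", fixed = TRUE)[[1]]
}

marker_compatible_one <- function(geno, aff, unaff, missing) {
  ga <- lapply(geno[aff], split_alleles)
  gu <- lapply(geno[unaff], split_alleles)
  if (missing == "incompatible" &&
      (any(!lengths(ga)) || any(!lengths(gu)))) {
    return(FALSE)
  }
  ga <- ga[lengths(ga) > 0]
  gu <- gu[lengths(gu) > 0]
  candidates <- if (length(ga)) {
    Reduce(intersect, lapply(ga, unique))
  } else {
    unique(unlist(c(ga, gu)))  # no affected data observed: any seen allele
  }
  if (!length(candidates)) return(FALSE)
  blocked <- unique(unlist(gu))
  length(setdiff(candidates, blocked)) > 0
}

#' Dominant-model marker compatibility
#'
#' A marker is compatible with cosegregation when some allele is carried by
#' every affected sequenced member and by no unaffected sequenced member.
#' Missing genotypes are resolved by the missing policy.
#'
#' @param markers A marker tibble.
#' @param ped A pedigree tibble; every genotyped column must be a pedigree
#'   member and the affected set must be non-empty.
#' @param missing `"compatible"` or `"incompatible"`, see [scan_params()].
#' @return Logical vector, one element per marker row.
#' @examples
#' m <- tibble::tibble(chrom = "1", pos = 1,
#'   A1 = "A/B", A2 = "A/B", A3 = "A/B", U1 = "B/B", U2 = "B/B", U3 = "B/B")
#' @export
marker_compatible <- function(markers, ped, missing = c("compatible", "incompatible")) {
  missing <- match.arg(missing)
  aff <- affected_ids(ped)
  unaff <- unaffected_ids(ped)
  if (!length(aff)) abort("marker compatibility requires an affected set")
  cols <- marker_sample_cols(markers)
  unknown <- setdiff(cols, ped$id)
  if (length(unknown)) {
    abort(paste0("genotyped individuals absent from pedigree: ",
                 paste(unknown, collapse = ", ")))
  }
  aff <- intersect(aff, cols)
  unaff <- intersect(unaff, cols)
  geno_m <- as.matrix(markers[, cols, drop = FALSE])
  vapply(seq_len(nrow(markers)), function(i) {
    marker_compatible_one(geno_m[i, ], aff, unaff, missing)
  }, logical(1))
}

scan_one_chrom <- function(pos, compat, params) {
  # every maximal window [s, e] with compatible endpoints and at most
  # max_errors interior incompatible markers (two-pointer, O(n)), then
  # overlapping windows are merged; this keeps the output sorted and
  # non-overlapping and makes reported regions monotone in the tolerance
  idx <- which(compat)
  if (!length(idx)) return(list())
  k <- params$max_errors
  n <- length(idx)
  ends <- integer(n)
  j <- 1L
  for (a in seq_len(n)) {
    if (j < a) j <- a
    while (j < n) {
      err <- (idx[j + 1L] - idx[a] + 1L) - (j + 2L - a)
      if (err <= k) j <- j + 1L else break
    }
    ends[a] <- j
  }
  keep <- which(c(TRUE, diff(ends) > 0))  # left-maximal windows only
  runs <- list()
  cur_s <- keep[1]
  cur_e <- ends[keep[1]]
  for (a in keep[-1]) {
    if (a <= cur_e) {
      cur_e <- max(cur_e, ends[a])
    } else {
      runs[[length(runs) + 1]] <- c(start = idx[cur_s], end = idx[cur_e])
      cur_s <- a
      cur_e <- ends[a]
    }
  }
  runs[[length(runs) + 1]] <- c(start = idx[cur_s], end = idx[cur_e])
  lapply(runs, function(r) {
    c(r, errors = (r[["end"]] - r[["start"]] + 1L) -
        sum(idx >= r[["start"]] & idx <= r[["end"]]))
  })
}

#' Scan a genome for dominant-cosegregation regions
#'
#' Finds, per chromosome, maximal runs of consecutive compatible markers
#' (see [marker_compatible()]) containing at least `min_markers` compatible
#' markers and tolerating at most `max_errors` incompatible markers inside the
#' run. Every maximal such window is enumerated and overlapping windows are
#' merged, so output regions are sorted and non-overlapping within a
#' chromosome, and never shrink when the error tolerance grows.
#'
#' @param markers A marker tibble sorted by `(chrom, pos)`.
#' @param ped A pedigree tibble.
#' @param params A [scan_params()].
#' @return A `coseg_scan` regions tibble (`chrom`, `start`, `end`, `label`,
#'   `n_markers` = compatible markers in the run, `n_errors`).
#' @export
scan_regions <- function(markers, ped, params = scan_params()) {
  ord <- order(markers$chrom, markers$pos)
  if (!identical(ord, seq_len(nrow(markers)))) {
    abort("marker matrix must be sorted by (chrom, pos)")
  }
  compat <- marker_compatible(markers, ped, params$missing)
  out <- list()
  for (ch in unique(markers$chrom)) {
    sel <- which(markers$chrom == ch)
    pos <- markers$pos[sel]
    runs <- scan_one_chrom(pos, compat[sel], params)
    for (r in runs) {
      n_comp <- sum(compat[sel][r["start"]:r["end"]])
      if (n_comp < params$min_markers) next
      if (params$boundary == "inner") {
        start <- pos[r["start"]]
        end <- pos[r["end"]]
      } else {
        start <- if (r["start"] > 1) pos[r["start"] - 1] else pos[1]
        end <- if (r["end"] < length(pos)) pos[r["end"] + 1] else pos[length(pos)]
      }
      out[[length(out) + 1]] <- tibble(
        chrom = ch, start = start, end = end, label = NA_character_,
        n_markers = n_comp, n_errors = unname(r["errors"])
      )
    }
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(chrom = character(), start = numeric(), end = numeric(),
           label = character(), n_markers = integer(), n_errors = integer())
  res <- arrange(res, .data$chrom, .data$start)
  attr(res, "params") <- params
  class(res) <- unique(c("coseg_scan", "coseg_regions", class(tibble())))
  res
}

#' Recovery metrics for a region scan
#'
#' @param scan_result Regions from [scan_regions()].
#' @param true_chrom,true_pos The implanted causal locus.
#' @param genome_bp Total simulated genome length in bp (denominator of the
#'   linked fraction).
#' @return A one-row tibble: `covered` (causal locus inside some region) and
#'   `genome_fraction_linked` (sum of region lengths over `genome_bp`).
#' @export
evaluate_scan <- function(scan_result, true_chrom, true_pos, genome_bp) {
  covered <- isTRUE(any(in_region(scan_result, true_chrom, true_pos)))
  frac <- if (nrow(scan_result)) sum(scan_result$end - scan_result$start) / genome_bp else 0
  tibble(covered = covered, genome_fraction_linked = frac)
}
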