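#' Genomic interval tables
#'
#' Regions are plain tibbles with columns `chrom` (character), `start` and
#' `end` (1-based inclusive positions, numeric) and an optional `label`
#' (cytoband or free text). Coordinates follow the convention of the published
#' linked-region table: 1-based inclusive, with the reported length of an
#' interval defined as `end - start` (NOT `end - start + 1`). This is
#' deliberate — it reproduces every printed length of the transcribed region
#' table — and is used consistently by [region_length()] and the `table_tsv`
#' writer. BED export converts to 0-based half-open coordinates.
#'
#' @param chrom Character vector of chromosome labels.
#' @param start,end 1-based inclusive interval bounds, `start <= end`.
#' @param label Optional character labels.
#' @return A `coseg_regions` tibble.
#' @examples
#' regions("2", 146360626, 221800201, "2q22.3-35")
#' @export
regions <- function(chrom, start, end, label = NA_character_) {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    label = as.character(label)
  )
  validate_regions(x)
}

validate_regions <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (!"label" %in% names(x)) x$label <- NA_character_
  bad <- which(x$end < x$start)
  if (length(bad)) {
    abort(paste0("regions with end < start at rows: ", paste(bad, collapse = ", ")))
  }
  class(x) <- unique(c("coseg_regions", class(tibble())))
  x
}

#' Interval length under the end − start convention
#'
#' @param x A regions tibble.
#' @return Numeric vector of `end - start` values.
#' @export
region_length <- function(x) {
  x$end - x$start
}

#' Read a region table
#'
#' Two dialects are supported. `table_tsv` is a 1-based TSV with columns
#' `Chr`, `Locus`, `Start`, `End`, `Length` (the layout of the published
#' linked-region table; `Length` is checked against `end - start` and a
#' mismatch is an error). `bed` is standard 0-based half-open BED with an
#' optional fourth name column; positions are converted to 1-based inclusive
#' on read.
#'
#' @param path File path.
#' @param dialect `"table_tsv"` (default) or `"bed"`.
#' @return A `coseg_regions` tibble sorted by `(chrom, start)`.
#' @export
read_regions <- function(path, dialect = c("table_tsv", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "table_tsv") {
    raw <- read_tsv(path, show_col_types = FALSE,
                    col_types = cols(.default = "c"))
    names(raw) <- tolower(names(raw))
    need <- c("chr", "start", "end")
    if (!all(need %in% names(raw))) {
      abort(paste0("table_tsv region file must have columns Chr/Start/End: ", path))
    }
    x <- tibble(
      chrom = raw$chr,
      start = as.numeric(raw$start),
      end = as.numeric(raw$end),
      label = raw[["locus"]] %||% NA_character_
    )
    if ("length" %in% names(raw)) {
      printed <- as.numeric(raw$length)
      off <- which(printed != x$end - x$start)
      if (length(off)) {
        abort(paste0(
          "printed Length disagrees with end - start at rows: ",
          paste(off, collapse = ", ")
        ))
      }
    }
  } else {
    raw <- read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                    col_types = cols(.default = "c"))
    x <- tibble(
      chrom = raw$X1,
      start = as.numeric(raw$X2) + 1,
      end = as.numeric(raw$X3),
      label = if (ncol(raw) >= 4) raw$X4 else NA_character_
    )
  }
  x <- arrange(x, .data$chrom, .data$start)
  validate_regions(x)
}

#' Write a region table
#'
#' @inheritParams read_regions
#' @param x A regions tibble.
#' @return The input, invisibly.
#' @export
write_regions <- function(x, path, dialect = c("bed", "table_tsv")) {
  dialect <- match.arg(dialect)
  x <- validate_regions(as_tibble(x))
  if (dialect == "bed") {
    out <- tibble(
      chrom = x$chrom,
      start = format(x$start - 1, scientific = FALSE, trim = TRUE),
      end = format(x$end, scientific = FALSE, trim = TRUE),
      name = ifelse(is.na(x$label), ".", x$label)
    )
    write_tsv(out, path, col_names = FALSE)
  } else {
    out <- tibble(
      Chr = x$chrom,
      Locus = ifelse(is.na(x$label), ".", x$label),
      Start = format(x$start, scientific = FALSE, trim = TRUE),
      End = format(x$end, scientific = FALSE, trim = TRUE),
      Length = format(x$end - x$start, scientific = FALSE, trim = TRUE)
    )
    write_tsv(out, path)
  }
  invisible(x)
}

#' Test positions for linked-region membership
#'
#' A position is inside a region when it lies within `[start, end]`
#' (1-based inclusive) of some interval on the same chromosome.
#'
#' @param regions A regions tibble.
#' @param chrom,pos Equal-length vectors of positions to test.
#' @return Logical vector.
#' @examples
#' r <- regions("2", 146360626, 221800201)
#' in_region(r, c("2", "2"), c(150000000, 146360625))
#' @export
in_region <- function(regions, chrom, pos) {
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  map2_lgl_ <- function(ch, p) {
    any(regions$chrom == ch & regions$start <= p & regions$end >= p)
  }
  if (!nrow(regions)) return(rep(FALSE, length(pos)))
  mapply(map2_lgl_, chrom, pos, USE.NAMES = FALSE)
}
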