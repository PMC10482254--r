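#' Pedigree tables
#'
#' A pedigree is a tibble with one row per individual: `family`, `id`,
#' `father`, `mother` (`NA` for founders), `sex` (`"male"`, `"female"`,
#' `"unknown"`), `affection` (`"affected"`, `"unaffected"`, `"unknown"`) and
#' `sequenced` (logical). The affected/unaffected partitions used by every
#' cosegregation filter contain only sequenced members with known affection;
#' unknown-affection individuals constrain nothing.
#'
#' @param df A data frame with at least `id`, `father`, `mother`, `sex`,
#'   `affection`; `family` defaults to `"FAM"`, `sequenced` to `TRUE`.
#' @return A `coseg_ped` tibble.
#' @export
pedigree <- function(df) {
  df <- as_tibble(df)
  if (!"family" %in% names(df)) df$family <- "FAM"
  if (!"sequenced" %in% names(df)) df$sequenced <- TRUE
  need <- c("family", "id", "father", "mother", "sex", "affection", "sequenced")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("pedigree is missing columns: ", paste(miss, collapse = ", ")))
  df <- select(df, all_of(need))
  if (anyDuplicated(df$id)) {
    abort(paste0("duplicate individual ids: ",
                 paste(unique(df$id[duplicated(df$id)]), collapse = ", ")))
  }
  bad_sex <- setdiff(unique(df$sex), c("male", "female", "unknown"))
  if (length(bad_sex)) abort(paste0("unknown sex codes: ", paste(bad_sex, collapse = ", ")))
  bad_aff <- setdiff(unique(df$affection), c("affected", "unaffected", "unknown"))
  if (length(bad_aff)) abort(paste0("unknown affection codes: ", paste(bad_aff, collapse = ", ")))
  class(df) <- unique(c("coseg_ped", class(tibble())))
  df
}

#' Read a PED/FAM pedigree file
#'
#' Whitespace-delimited six-column format: family, individual, father, mother,
#' sex (1 = male, 2 = female, 0 = unknown), phenotype (1 = unaffected,
#' 2 = affected, 0 or -9 = unknown). `"0"` parent codes mark founders. All
#' listed individuals are taken as sequenced (the file is expected to describe
#' the genotyped members; set the `sequenced` column afterwards if not).
#'
#' @param path File path.
#' @return A `coseg_ped` tibble.
#' @export
read_ped <- function(path) {
  raw <- tryCatch(
    read.table(path, header = FALSE, colClasses = "character",
               comment.char = "#", blank.lines.skip = TRUE),
    error = function(e) abort(paste0("cannot parse PED file ", path, ": ", conditionMessage(e)))
  )
  if (!nrow(raw)) abort(paste0("empty PED file: ", path))
  if (ncol(raw) < 6) abort(paste0("PED file must have 6 columns, found ", ncol(raw), ": ", path))
  pheno <- raw[[6]]
  bad <- setdiff(unique(pheno), c("1", "2", "0", "-9"))
  if (length(bad)) {
    abort(paste0("phenotype codes outside {1,2,0,-9}: ", paste(bad, collapse = ", ")))
  }
  ped <- pedigree(tibble(
    family = raw[[1]],
    id = raw[[2]],
    father = ifelse(raw[[3]] == "0", NA_character_, raw[[3]]),
    mother = ifelse(raw[[4]] == "0", NA_character_, raw[[4]]),
    sex = c("0" = "unknown", "1" = "male", "2" = "female")[raw[[5]]],
    affection = c("1" = "unaffected", "2" = "affected", "0" = "unknown",
                  "-9" = "unknown")[pheno],
    sequenced = TRUE
  ))
  self <- ped$id[!is.na(ped$father) & ped$father == ped$id |
                   !is.na(ped$mother) & ped$mother == ped$id]
  if (length(self)) {
    abort(paste0("pedigree cycle: individual is its own parent: ",
                 paste(self, collapse = ", ")))
  }
  cyc <- pedigree_cycles(ped)
  if (length(cyc)) {
    abort(paste0("pedigree cycle involving: ", paste(cyc, collapse = ", ")))
  }
  ped
}

#' Write a PED/FAM pedigree file
#'
#' @param ped A pedigree tibble.
#' @param path File path.
#' @return The pedigree, invisibly.
#' @export
write_ped <- function(ped, path) {
  out <- tibble(
    family = ped$family,
    id = ped$id,
    father = ifelse(is.na(ped$father), "0", ped$father),
    mother = ifelse(is.na(ped$mother), "0", ped$mother),
    sex = c(male = "1", female = "2", unknown = "0")[ped$sex],
    phenotype = c(unaffected = "1", affected = "2", unknown = "0")[ped$affection]
  )
  write_tsv(out, path, col_names = FALSE)
  invisible(ped)
}

# ids left after repeatedly deleting individuals with no (remaining) children:
# non-empty result means a parentage cycle
pedigree_cycles <- function(ped) {
  ids <- ped$id
  repeat {
    is_parent <- ids %in% c(ped$father[ped$id %in% ids], ped$mother[ped$id %in% ids])
    if (all(is_parent) || !length(ids)) break
    ids <- ids[is_parent]
  }
  ids
}

#' Sequenced affected / unaffected member ids
#'
#' @param ped A pedigree tibble.
#' @return Character vector of individual ids.
#' @export
affected_ids <- function(ped) {
  ped$id[ped$sequenced & ped$affection == "affected"]
}

#' @rdname affected_ids
#' @export
unaffected_ids <- function(ped) {
  ped$id[ped$sequenced & ped$affection == "unaffected"]
}

#' Structural validation of a pedigree
#'
#' Checks parent references, parentage cycles, sex-consistent parentage
#' (listed fathers male-or-unknown, mothers female-or-unknown), half-founders
#' (exactly one missing parent) and sequenced members with unknown affection.
#' Always returns a report; an empty report means the pedigree is valid.
#'
#' @param ped A pedigree tibble.
#' @return A tibble with columns `check`, `id`, `message`; zero rows iff valid.
#' @export
validate_pedigree <- function(ped) {
  ped <- pedigree(ped)
  out <- list()
  note <- function(check, id, message) {
    out[[length(out) + 1]] <<- tibble(check = check, id = id, message = message)
  }
  for (i in seq_len(nrow(ped))) {
    row <- ped[i, ]
    for (side in c("father", "mother")) {
      pid <- row[[side]]
      if (is.na(pid)) next
      j <- match(pid, ped$id)
      if (is.na(j)) {
        note("unresolved_parent", row$id,
             paste0(side, " '", pid, "' is not in the pedigree"))
      } else {
        want <- if (side == "father") "male" else "female"
        if (!ped$sex[j] %in% c(want, "unknown")) {
          note("sex_inconsistent", row$id,
               paste0(side, " '", pid, "' is listed as ", ped$sex[j]))
        }
      }
    }
    if (xor(is.na(row$father), is.na(row$mother))) {
      note("half_founder", row$id, "exactly one parent is missing")
    }
    if (isTRUE(row$sequenced) && row$affection == "unknown") {
      note("unknown_affection", row$id,
           "sequenced member with unknown affection is excluded from filters")
    }
  }
  cyc <- pedigree_cycles(ped)
  for (id in cyc) note("cycle", id, "individual participates in a parentage cycle")
  if (length(out)) bind_rows(out) else tibble(check = character(), id = character(),
                                              message = character())
}

#' Dominant-inheritance consistency of an affection pattern
#'
#' Checks whether the observed affection pattern can arise under a fully
#' penetrant autosomal-dominant model in which carrier status and affection
#' coincide (carrier iff affected) for every phenotyped individual.
#' Unknown-affection individuals are free to be carriers or not; the check
#' enumerates their assignments and asks for the minimum number of de novo
#' events (a carrier non-founder with no carrier parent; a parent absent from
#' the table counts as unknown).
#'
#' @param ped A pedigree tibble with at least one affected member.
#' @param allow_de_novo If `TRUE` (default), a pattern that is only explicable
#'   by de novo mutation is labelled `"de_novo_required"`; if `FALSE` it is
#'   labelled `"inconsistent"`.
#' @return One of `"consistent"`, `"de_novo_required"`, `"inconsistent"`.
#' @examples
#' ped <- pedigree(tibble::tibble(
#'   id = c("gm", "gf", "m", "f", "kid"),
#'   father = c(NA, NA, "gf", NA, "f"),
#'   mother = c(NA, NA, "gm", NA, "m"),
#'   sex = c("female", "male", "female", "male", "male"),
#'   affection = c("affected", "unaffected", "affected", "unaffected", "affected")
#' ))
#' dominant_consistency(ped)
#' @export
dominant_consistency <- function(ped, allow_de_novo = TRUE) {
  ped <- pedigree(ped)
  if (!any(ped$affection == "affected")) {
    abort("dominant_consistency requires at least one affected member")
  }
  unknown <- ped$id[ped$affection == "unknown"]
  if (length(unknown) > 20) {
    abort("too many unknown-affection individuals to enumerate (> 20)")
  }
  base <- setNames(ped$affection == "affected", ped$id)

  de_novo_count <- function(carrier) {
    n <- 0L
    for (i in seq_len(nrow(ped))) {
      if (!carrier[[ped$id[i]]]) next
      f <- ped$father[i]
      m <- ped$mother[i]
      if (is.na(f) && is.na(m)) next  # founder carrier needs no source
      parent_possible <- function(p) {
        if (is.na(p)) return(TRUE)            # unrecorded parent: unconstrained
        if (!p %in% ped$id) return(TRUE)      # external parent: unconstrained
        carrier[[p]]
      }
      if (!(parent_possible(f) || parent_possible(m))) n <- n + 1L
    }
    n
  }

  best <- Inf
  grid <- if (length(unknown)) {
    expand.grid(rep(list(c(FALSE, TRUE)), length(unknown)))
  } else {
    data.frame(row.names = 1)
  }
  for (g in seq_len(max(1L, nrow(grid)))) {
    carrier <- base
    if (length(unknown)) carrier[unknown] <- as.logical(grid[g, ])
    best <- min(best, de_novo_count(carrier))
    if (best == 0L) break
  }
  if (best == 0L) return("consistent")
  if (allow_de_novo) "de_novo_required" else "inconsistent"
}
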