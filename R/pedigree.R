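#' Nuclear F0--F2 families
#'
#' The unit of marker selection and imputation is the nuclear family: one
#' F2 offspring, its two F1 parents and the four line-labelled F0
#' grandparents (two from the high line H, two from the low line L). The F1
#' generation is heterozygous at every informative marker and never needs
#' to be sequenced.
#'
#' @param f2,f1_sire,f1_dam individual ids.
#' @param f0_h,f0_l character vectors of length 2: the F0 grandparents from
#'   the H and L line respectively.
#' @return A `nuclear_family` list.
#' @export
nuclear_family <- function(f2, f1_sire, f1_dam, f0_h, f0_l) {
  stopifnot(length(f0_h) == 2, length(f0_l) == 2)
  if (f1_sire == f1_dam) stop("F1 parents of ", f2, " are not distinct")
  f0 <- c(f0_h, f0_l)
  if (anyDuplicated(f0)) {
    stop("family of ", f2, " does not have 4 distinct F0 grandparents")
  }
  structure(list(family_id = as.character(f2), f2 = as.character(f2),
                 f1_sire = as.character(f1_sire),
                 f1_dam = as.character(f1_dam),
                 f0_h = as.character(f0_h), f0_l = as.character(f0_l)),
            class = "nuclear_family")
}

#' @export
print.nuclear_family <- function(x, ...) {
  cat("Nuclear family for F2 ", x$f2, "\n",
      "  F1: ", x$f1_sire, " x ", x$f1_dam, "\n",
      "  F0 (H line): ", paste(x$f0_h, collapse = ", "), "\n",
      "  F0 (L line): ", paste(x$f0_l, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Build nuclear families from a pedigree table
#'
#' The pedigree is a table with columns `id`, `generation` (`F0`, `F1`,
#' `F2`), `line` (`H`/`L` for F0, `NA` otherwise), `sire`, `dam` (`NA` for
#' founders). One family is built per F2 by resolving its two F1 parents
#' and, through them, the four F0 grandparents. F1 parents may be shared
#' between families (many-to-many F1 matings), so families may share
#' founders.
#'
#' Structural problems that concern a single F2 (an `NA` parent link, a
#' grandparent set that is not 2 H + 2 L, identical F1 parents) do not
#' abort the run: the F2 is reported in the `problems` table instead.
#' Referencing a parent id that is absent from the table, or an F0 without
#' a line label, is a hard error.
#'
#' @param x a data.frame or the path to a tab-separated file with header
#'   `id generation line sire dam` (`NA` for unknown).
#' @return A `pedigree` list with elements `families` (named list of
#'   [nuclear_family()], one per conforming F2) and `problems` (data.frame
#'   `f2`, `reason`).
#' @examples
#' ped <- data.frame(
#'   id = c("H1", "H2", "L1", "L2", "S1", "D1", "X1"),
#'   generation = c("F0", "F0", "F0", "F0", "F1", "F1", "F2"),
#'   line = c("H", "H", "L", "L", NA, NA, NA),
#'   sire = c(NA, NA, NA, NA, "H1", "H2", "S1"),
#'   dam = c(NA, NA, NA, NA, "L1", "L2", "D1"))
#' load_pedigree(ped)$families[["X1"]]
#' @export
load_pedigree <- function(x) {
  ped <- if (is.character(x) && length(x) == 1) {
    utils::read.delim(x, stringsAsFactors = FALSE, comment.char = "#",
                      na.strings = c("NA", ""))
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  need <- c("id", "generation", "line", "sire", "dam")
  if (!all(need %in% names(ped))) {
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  }
  ped$id <- as.character(ped$id)
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  rownames(ped) <- ped$id
  ped$line[ped$line %in% c("", "NA")] <- NA

  f0 <- ped$id[ped$generation == "F0"]
  bad_line <- f0[!(ped[f0, "line"] %in% c("H", "L"))]
  if (length(bad_line)) {
    stop("F0 individual(s) without H/L line label: ",
         paste(bad_line, collapse = ", "))
  }
  # every referenced parent must exist
  refs <- stats::na.omit(unique(c(ped$sire, ped$dam)))
  missing_ref <- setdiff(refs, ped$id)
  if (length(missing_ref)) {
    who <- ped$id[ped$sire %in% missing_ref | ped$dam %in% missing_ref]
    stop("parent id(s) not present in pedigree: ",
         paste(missing_ref, collapse = ", "),
         " (referenced by ", paste(who, collapse = ", "), ")")
  }

  f2s <- sort(ped$id[ped$generation == "F2"])
  families <- list()
  problems <- list()
  note <- function(f2, why) problems[[length(problems) + 1]] <<-
    data.frame(f2 = f2, reason = why, stringsAsFactors = FALSE)

  for (f2 in f2s) {
    sire <- ped[f2, "sire"]; dam <- ped[f2, "dam"]
    if (is.na(sire) || is.na(dam)) { note(f2, "F2 has an NA parent link"); next }
    if (sire == dam) { note(f2, "F1 parents are identical"); next }
    if (!all(ped[c(sire, dam), "generation"] == "F1")) {
      note(f2, "a parent of the F2 is not generation F1"); next
    }
    gp <- c(ped[sire, "sire"], ped[sire, "dam"],
            ped[dam, "sire"], ped[dam, "dam"])
    if (anyNA(gp)) { note(f2, "an F1 parent has an NA parent link"); next }
    if (!all(ped[gp, "generation"] == "F0")) {
      note(f2, "a grandparent is not generation F0"); next
    }
    if (anyDuplicated(gp)) { note(f2, "fewer than 4 distinct F0 grandparents"); next }
    lines <- ped[gp, "line"]
    if (sum(lines == "H") != 2 || sum(lines == "L") != 2) {
      note(f2, "F0 grandparents are not 2 H + 2 L"); next
    }
    families[[f2]] <- nuclear_family(f2, sire, dam,
                                     f0_h = gp[lines == "H"],
                                     f0_l = gp[lines == "L"])
  }
  problems <- if (length(problems)) do.call(rbind, problems) else
    data.frame(f2 = character(), reason = character(), stringsAsFactors = FALSE)
  structure(list(families = families, problems = problems),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree: ", length(x$families), " nuclear families",
      if (nrow(x$problems)) paste0(", ", nrow(x$problems),
                                   " non-conforming F2 (see $problems)"),
      "\n", sep = "")
  invisible(x)
}

#' Write a pedigree of nuclear families to TSV
#'
#' Inverse of [load_pedigree()]: emits one row per individual with columns
#' `id generation line sire dam`.
#'
#' @param families list of [nuclear_family()].
#' @param path output file.
#' @param header_lines optional comment lines (without leading `#`).
#' @export
write_pedigree <- function(families, path, header_lines = NULL) {
  rows <- list()
  add <- function(id, gen, line, sire, dam) {
    rows[[id]] <<- data.frame(id = id, generation = gen, line = line,
                              sire = sire, dam = dam,
                              stringsAsFactors = FALSE)
  }
  for (fam in families) {
    add(fam$f0_h[1], "F0", "H", NA, NA); add(fam$f0_h[2], "F0", "H", NA, NA)
    add(fam$f0_l[1], "F0", "L", NA, NA); add(fam$f0_l[2], "F0", "L", NA, NA)
    add(fam$f1_sire, "F1", NA, fam$f0_h[1], fam$f0_l[1])
    add(fam$f1_dam,  "F1", NA, fam$f0_h[2], fam$f0_l[2])
    add(fam$f2, "F2", NA, fam$f1_sire, fam$f1_dam)
  }
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
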